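test_that("define_minor_allele sums generation-0 counts with the tie rule", {
  meta <- data.frame(population = c("C1", "C1"), scheme = "control",
                     replicate = 1L, sex = c("F", "M"), generation = 0L)
  panel <- allele_count_panel(
    sites = data.frame(chrom = "2L", pos = c(100L, 200L, 300L),
                       ref = "A", alt = "T"),
    samples = meta,
    ref_count = matrix(as.integer(c(450, 250, 80, 450, 250, 0)), 3, 2),
    alt_count = matrix(as.integer(c(50, 250, 0, 50, 250, 0)), 3, 2))
  mn <- define_minor_allele(panel, 0)
  expect_true(mn$minor_is_alt[1])          # 100 < 900
  expect_equal(mn$ref_freq[1], 0.10)
  expect_true(mn$minor_is_alt[2])          # 500 = 500, tie -> alt
  expect_true(mn$fixed[3])                 # minor frequency zero at gen 0
  expect_false(any(mn$fixed[1:2]))
  # zero-coverage cell -> NA frequency, zero-read site at gen 0 deferred
  panel$ref_count[3, ] <- 0L
  mn2 <- define_minor_allele(panel, 0)
  expect_true(is.na(mn2$minor_is_alt[3]))
})

test_that("coverage_filter keeps the closed bounds [10, 2000]", {
  freqs <- matrix(0.5, 4, 1)
  panel <- make_counts_panel(freqs, coverage = 2)
  panel$ref_count[, 1] <- c(5L, 5L, 1000L, 1001L)
  panel$alt_count[, 1] <- c(4L, 5L, 1000L, 1000L)
  f <- coverage_filter(panel)
  expect_true(is.na(f$ref_count[1, 1]))    # total 9 removed
  expect_equal(f$ref_count[2, 1], 5L)      # total 10 retained
  expect_equal(f$ref_count[3, 1], 1000L)   # total 2000 retained
  expect_true(is.na(f$ref_count[4, 1]))    # total 2001 removed
})

test_that("allele_hpd_interval matches a grid-search oracle", {
  for (case in list(c(30, 100), c(3, 20), c(180, 200))) {
    got <- allele_hpd_interval(case[1], case[2])
    want <- hpd_oracle(case[1], case[2])
    expect_equal(unname(got), want, tolerance = 2e-4)
    # interval covers the posterior mode
    a <- case[1] + 0.5; b <- case[2] - case[1] + 0.5
    mode <- (a - 1) / (a + b - 2)
    expect_true(got["lower"] <= mode && mode <= got["upper"])
  }
  # boundary modes give one-sided intervals
  expect_equal(unname(allele_hpd_interval(0, 50)["lower"]), 0)
  expect_equal(unname(allele_hpd_interval(50, 50)["upper"]), 1)
  expect_error(allele_hpd_interval(2, 0))
})

test_that("cmh_test agrees with the direct formula and mantelhaen.test", {
  t1 <- matrix(c(10, 50, 90, 50), 2)  # (a, c, b, d) column-major
  res <- cmh_test(list(t1))
  expect_equal(res$statistic, mh_oracle(list(t1)), tolerance = 1e-12)
  # identical columns in every stratum -> statistic 0, P 1
  t0 <- matrix(c(30, 70, 30, 70), 2)
  res0 <- cmh_test(list(t0, t0))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  # doubling all counts doubles evidence
  tabs <- list(matrix(c(12, 40, 30, 44), 2), matrix(c(8, 22, 19, 31), 2))
  expect_gt(cmh_test(lapply(tabs, `*`, 2))$statistic,
            cmh_test(tabs)$statistic)
  # base-R mantelhaen.test as an independent oracle on random tables
  set.seed(5)
  for (k in 1:25) {
    K <- sample(2:4, 1)
    arr <- array(rpois(4 * K, 40) + 1, c(2, 2, K))
    ours <- cmh_test(lapply(seq_len(K), function(i) arr[, , i]))
    ref <- stats::mantelhaen.test(arr, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-10)
  }
  # all-zero stratum dropped
  resz <- cmh_test(list(t1, matrix(0, 2, 2)))
  expect_equal(resz$k_used, 1L)
  expect_equal(resz$statistic, res$statistic)
})

test_that("afc_scan flags a planted jump and respects filter semantics", {
  gens <- c(0, 1)
  meta <- make_design_meta(gens)
  ns <- 20
  freqs <- matrix(0.4, ns, nrow(meta))
  # site 5: frequency 0 at g0, 0.5 at g1 in every population
  freqs[5, ] <- ifelse(meta$generation == 0, 0, 0.5)
  panel <- make_counts_panel(freqs, coverage = 200, meta = meta)
  # minor allele for site 5 is alt (count 0 at gen 0)
  scan <- afc_scan(panel, generation_pairs = list(c(0, 1)), alpha = 2.3e-8)
  for (p in names(scan$significant))
    expect_equal(scan$significant[[p]], 5L)
  # a cell masked by the coverage filter drops out of that pair only
  panel2 <- panel
  g1L1 <- which(meta$population == "L1" & meta$generation == 1)
  panel2$ref_count[5, g1L1] <- NA_integer_
  panel2$alt_count[5, g1L1] <- NA_integer_
  scan2 <- afc_scan(panel2, generation_pairs = list(c(0, 1)), alpha = 2.3e-8)
  expect_length(scan2$significant$L1, 0)
  expect_equal(scan2$significant$S1, 5L)
})

test_that("overlap_filter implements union/intersect/minus set algebra", {
  lng <- list(c(1, 2, 3), c(3, 4))
  sht <- list(c(2, 9), c(4, 7))
  ctl <- list(c(9), integer(0))
  # union(long) = 1..4; union(short) = {2,4,7,9}; minus control {9} -> {2,4}
  expect_equal(overlap_filter(lng, sht, ctl), c(2, 4))
  # control-only site excluded, cross-replicate inclusion works
  expect_equal(overlap_filter(list(5), list(5), list(5)), numeric(0))
  expect_equal(overlap_filter(list(1, 5), list(5, 2), list(integer(0))),
               5)
  # per-replicate intersection variant
  expect_equal(overlap_filter(lng, sht, ctl,
                              per_replicate_intersection = TRUE),
               numeric(0))
})

test_that("logistic_filter passes planted divergence and fails flat sites", {
  gens <- c(0, 1, 2, 5, 8, 10, 12)
  meta <- make_design_meta(gens)
  ns <- 3
  freqs <- matrix(NA_real_, ns, nrow(meta))
  base <- 0.3
  for (j in seq_len(nrow(meta))) {
    g <- meta$generation[j]
    freqs[1, j] <- base                                   # flat everywhere
    # divergent: short sleepers gain the minor allele (towards fixation),
    # long sleepers lose it, with an immediate scheme offset
    freqs[2, j] <- plogis(qlogis(base) +
                          if (meta$scheme[j] == "short") 0.3 + 0.35 * g
                          else -0.35 * g)
    freqs[3, j] <- plogis(qlogis(base) + 0.15 * g)        # parallel trend
  }
  panel <- make_counts_panel(freqs, coverage = 200, meta = meta)
  lf <- logistic_filter(panel, 1:3)
  expect_false(lf$pass[1])
  expect_gt(lf$p_sel[1], 0.05)
  expect_true(lf$pass[2])
  expect_lte(lf$p_sel[2], 0.05)
  expect_lte(lf$p_int[2], 0.05)
  expect_gte(lf$p_lack_of_fit[2], 0.05)
  expect_false(lf$pass[3])   # no scheme contrast
})

test_that("perfect separation triggers the flagged Haldane-Anscombe refit", {
  gens <- c(0, 5, 12)
  meta <- make_design_meta(gens)
  freqs <- matrix(NA_real_, 1, nrow(meta))
  for (j in seq_len(nrow(meta))) {
    g <- meta$generation[j]
    freqs[1, j] <- if (meta$scheme[j] == "short")
      c(`0` = 0.5, `5` = 1, `12` = 1)[as.character(g)]
    else c(`0` = 0.5, `5` = 0, `12` = 0)[as.character(g)]
  }
  panel <- make_counts_panel(freqs, coverage = 100, meta = meta)
  lf <- logistic_filter(panel, 1)
  expect_true(lf$separation[1])
  expect_true(is.finite(lf$b_sel[1]))
})
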