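test_that("founder panels obey the spectrum, determinism and invariants", {
  p1 <- generate_founder_panel(n_lines = 10, n_sites_per_chrom = 25,
                               maf_spectrum = list(dist = "point", value = 0.5),
                               seed = 3)
  expect_true(all(colSums(p1$geno) == 5))          # point mass at 0.5
  expect_true(all(p1$geno %in% c(0L, 1L)))         # fully homozygous lines
  for (ch in unique(p1$sites$chrom))               # strictly increasing pos
    expect_true(all(diff(p1$sites$pos[p1$sites$chrom == ch]) > 0))
  p2 <- generate_founder_panel(n_lines = 10, n_sites_per_chrom = 25,
                               maf_spectrum = list(dist = "point", value = 0.5),
                               seed = 3)
  expect_identical(p1, p2)                         # determinism
  expect_error(generate_founder_panel(
    maf_spectrum = list(dist = "uniform", min = 0.9, max = 0.1)), "invalid")
  expect_error(generate_founder_panel(
    maf_spectrum = list(dist = "wat")), "unknown")
})

test_that("sample_pool_reads is a clean binomial sampler", {
  expect_equal(sample_pool_reads(0, rep(50, 5))$alt_count, rep(0, 5))
  expect_equal(sample_pool_reads(1, rep(30, 5))$alt_count, rep(30, 5))
  set.seed(8)
  draws <- sample_pool_reads(rep(0.3, 10000), 100)$alt_count
  se <- sqrt(100 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(draws) - 30), 3 * se)
  expect_error(sample_pool_reads(1.2, 10))
})

test_that("compiled and reference gamete kernels are equivalent", {
  set.seed(15)
  H1 <- matrix(rbinom(200, 1, 0.5), 10, 20)
  H2 <- matrix(rbinom(200, 1, 0.5), 10, 20)
  sp <- rep(0.3, 20); sp[1] <- 0.5
  xs <- c(rep(FALSE, 15), rep(TRUE, 5))
  idx <- sample(1:10, 30, replace = TRUE)
  male <- rep(c(TRUE, FALSE), 15)
  set.seed(99)
  g_cpp <- sleepsweep:::.make_gametes(H1, H2, idx, sp, xs, male)
  set.seed(99)
  g_r <- sleepsweep:::make_gametes_r(H1, H2, idx, sp, xs, male)
  expect_identical(g_cpp, g_r)
  # male gametes always carry H1 at X sites
  expect_true(all(g_cpp[male, 16:20] == H1[idx[male], 16:20]))
})

test_that("simulated experiments respond to selection in the right direction", {
  panel <- generate_founder_panel(n_lines = 10, n_sites_per_chrom = 4,
                                  chrom_labels = c("2L", "3R"), seed = 41)
  eff <- numeric(8); eff[3] <- 60   # one strong sleep-lengthening locus
  p0 <- mean(panel$geno[, 3])
  cfg <- experiment_config(n_generations = 8, n_measured_per_sex = 60,
                           qtl_effects = eff, env_sd = 60,
                           burnin_generations = 4, burnin_census = 200,
                           sequenced_generations = c(0, 4, 8), seed = 1)
  # average trajectories over independent replicate experiments
  n_exp <- 12
  finals <- t(vapply(seq_len(n_exp), function(k) {
    cfgk <- cfg; cfgk$seed <- 100 + k
    sim <- simulate_experiment(panel, cfgk)
    tr <- sim$trajectory[sim$trajectory$site == 3, ]
    c(long = mean(tr$true_freq[tr$scheme == "long" & tr$generation == 8]),
      short = mean(tr$true_freq[tr$scheme == "short" & tr$generation == 8]),
      ctrl = mean(tr$true_freq[tr$scheme == "control" & tr$generation == 8]))
  }, c(long = 0, short = 0, ctrl = 0)))
  # deterministic single-locus truncation recursion as the oracle
  p_hi <- p_lo <- p0
  for (g in 1:8) {
    p_hi <- truncsel_recursion(p_hi, 60, 60, 0.25, "high")
    p_lo <- truncsel_recursion(p_lo, 60, 60, 0.25, "low")
  }
  expect_gt(mean(finals[, "long"]), p0)
  expect_lt(mean(finals[, "short"]), p0)
  se_l <- sd(finals[, "long"]) / sqrt(n_exp)
  se_s <- sd(finals[, "short"]) / sqrt(n_exp)
  expect_lt(abs(mean(finals[, "long"]) - p_hi), 4 * se_l + 0.05)
  expect_lt(abs(mean(finals[, "short"]) - p_lo), 4 * se_s + 0.05)
})

test_that("no heritable variation means no scheme separation", {
  panel <- generate_founder_panel(n_sites_per_chrom = 3, seed = 6)
  cfg <- experiment_config(n_generations = 5, n_measured_per_sex = 50,
                           qtl_effects = NULL, env_sd = 80,
                           burnin_generations = 2, burnin_census = 120,
                           sequenced_generations = c(0, 5), seed = 9)
  sim <- simulate_experiment(panel, cfg)
  ph <- sim$phenotypes[sim$phenotypes$generation == 5, ]
  fit <- stats::aov(value ~ scheme, ph)
  expect_gt(summary(fit)[[1]][["Pr(>F)"]][1], 0.01)
})

test_that("generation-0 frequencies agree across populations up to founding noise", {
  panel <- generate_founder_panel(n_sites_per_chrom = 10, seed = 13)
  cfg <- experiment_config(n_generations = 1, n_measured_per_sex = 80,
                           burnin_generations = 3, burnin_census = 400,
                           sequenced_generations = c(0, 1), seed = 17)
  sim <- simulate_experiment(panel, cfg)
  tr <- sim$trajectory[sim$trajectory$generation == 0, ]
  wide <- stats::reshape(tr[, c("population", "site", "true_freq")],
                         idvar = "site", timevar = "population",
                         direction = "wide")
  fr <- as.matrix(wide[, -1])
  # across-population SD at a site is founding binomial noise, not more:
  # parents per population = 2 * 20 flies -> SD < ~3 * sqrt(p q / 80)
  pbar <- rowMeans(fr)
  cap <- 3.5 * sqrt(pmax(pbar * (1 - pbar), 0.01) / 80)
  expect_gt(mean(apply(fr, 1, sd) <= cap), 0.9)
})

test_that("pooled counts track true frequencies with unit slope", {
  panel <- generate_founder_panel(n_sites_per_chrom = 60, seed = 23)
  cfg <- experiment_config(n_generations = 1, n_measured_per_sex = 50,
                           coverage_mean = 60, burnin_generations = 2,
                           burnin_census = 150,
                           sequenced_generations = c(0, 1), seed = 29)
  sim <- simulate_experiment(panel, cfg)
  tr <- sim$trajectory[sim$trajectory$generation == 0 &
                       sim$trajectory$population == "L1", ]
  cols <- which(sim$panel$samples$population == "L1" &
                sim$panel$samples$generation == 0)
  obs <- rowSums(sim$panel$alt_count[, cols]) /
    rowSums(sim$panel$alt_count[, cols] + sim$panel$ref_count[, cols])
  truef <- tr$true_freq[order(tr$site)]
  keep <- truef > 0 & truef < 1
  slope <- coef(lm(obs[keep] ~ truef[keep]))[2]
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("selection_fraction 1 reduces to random mating", {
  panel <- generate_founder_panel(n_sites_per_chrom = 4, seed = 2)
  cfg <- experiment_config(n_generations = 3, n_measured_per_sex = 30,
                           selection_fraction = 1,
                           qtl_effects = c(numeric(19), 50),
                           burnin_generations = 2, burnin_census = 100,
                           sequenced_generations = c(0, 3), seed = 4)
  sim <- simulate_experiment(panel, cfg)
  ph <- sim$phenotypes
  gs <- generation_summary(ph[ph$population == "L1", ], 1, "high")
  # with everyone selected the differential is identically zero
  expect_true(all(abs(gs$parent_mean - gs$mean) < 1e-9))
})

test_that("simulate_experiment is reproducible and validates config", {
  panel <- generate_founder_panel(n_sites_per_chrom = 3, seed = 1)
  cfg <- experiment_config(n_generations = 2, n_measured_per_sex = 20,
                           burnin_generations = 1, burnin_census = 60,
                           sequenced_generations = c(0, 2), seed = 77)
  s1 <- simulate_experiment(panel, cfg)
  s2 <- simulate_experiment(panel, cfg)
  expect_identical(s1$panel$alt_count, s2$panel$alt_count)
  expect_identical(s1$phenotypes$value, s2$phenotypes$value)
  expect_error(experiment_config(selection_fraction = 0), "selection_fraction")
  expect_error(experiment_config(coverage_mean = -1), "coverage_mean")
  expect_error(experiment_config(n_measured_per_sex = 2,
                                 selection_fraction = 0.1), "census")
  expect_error(simulate_experiment(panel,
    experiment_config(qtl_effects = c(1, 2))), "per panel site")
})
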