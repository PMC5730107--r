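# Shared fixture builders. Everything is generated in code; no stored data.

# deterministic allele-count panel from a sites x samples frequency matrix
make_counts_panel <- function(freqs, coverage = 200,
                              meta = NULL, chrom = "2L") {
  ns <- nrow(freqs); np <- ncol(freqs)
  if (is.null(meta)) {
    meta <- data.frame(population = paste0("P", seq_len(np)),
                       scheme = "control", replicate = 1L, sex = "F",
                       generation = seq_len(np) - 1L)
  }
  alt <- round(freqs * coverage)
  allele_count_panel(
    sites = data.frame(chrom = rep(chrom, ns), pos = seq_len(ns) * 100L,
                       ref = "A", alt = "T"),
    samples = meta,
    ref_count = matrix(as.integer(coverage - alt), ns, np),
    alt_count = matrix(as.integer(alt), ns, np))
}

# sample metadata for a long/short/control two-replicate two-sex design
make_design_meta <- function(generations) {
  pops <- data.frame(
    population = c("L1", "L2", "S1", "S2", "C1", "C2"),
    scheme = rep(c("long", "short", "control"), each = 2),
    replicate = rep(1:2, 3))
  out <- merge(merge(pops, data.frame(sex = c("F", "M"))),
               data.frame(generation = generations))
  out[order(out$population, out$generation, out$sex), ]
}

# direct Mantel-Haenszel formula, independent of the package implementation
mh_oracle <- function(tabs) {
  a <- vapply(tabs, function(t) t[1, 1], 0)
  b <- vapply(tabs, function(t) t[1, 2], 0)
  c_ <- vapply(tabs, function(t) t[2, 1], 0)
  d <- vapply(tabs, function(t) t[2, 2], 0)
  n <- a + b + c_ + d
  keep <- n >= 2 & (a + b) > 0 & (c_ + d) > 0 & (a + c_) > 0 & (b + d) > 0
  a <- a[keep]; b <- b[keep]; c_ <- c_[keep]; d <- d[keep]; n <- n[keep]
  E <- (a + b) * (a + c_) / n
  V <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  sum(a - E)^2 / sum(V)
}

# brute-force grid search for the shortest mass-covering Beta interval
hpd_oracle <- function(x, n, mass = 0.95, prior = c(0.5, 0.5),
                       grid_n = 20000) {
  a <- x + prior[1]; b <- n - x + prior[2]
  lo_candidates <- seq(0, 1 - mass, length.out = grid_n)
  lows <- qbeta(lo_candidates, a, b)
  highs <- qbeta(lo_candidates + mass, a, b)
  i <- which.min(highs - lows)
  c(lows[i], highs[i])
}

# deterministic single-locus truncation-selection recursion: expected
# next-generation allele frequency for an additive diploid locus under
# top-fraction selection on phenotype = a * dose + N(0, sd)
truncsel_recursion <- function(p, a, env_sd, fraction, direction = "high") {
  geno_p <- c(p^2, 2 * p * (1 - p), (1 - p)^2)   # dose 2, 1, 0
  mu <- a * c(2, 1, 0)
  # truncation threshold of the phenotype mixture
  cdf <- function(x) sum(geno_p * pnorm(x, mu, env_sd))
  target <- if (direction == "high") 1 - fraction else fraction
  thr <- uniroot(function(x) cdf(x) - target, c(-10 * env_sd + min(mu),
                                                10 * env_sd + max(mu)))$root
  tail_p <- if (direction == "high")
    geno_p * pnorm(thr, mu, env_sd, lower.tail = FALSE)
  else geno_p * pnorm(thr, mu, env_sd)
  sel <- tail_p / sum(tail_p)
  sum(sel * c(2, 1, 0)) / 2
}
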