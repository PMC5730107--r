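# Drift machinery: variance effective population size from control-line
# frequency dispersion, forward Wright-Fisher simulation, and the
# 99.9%-quantile thresholds that separate selection candidates from drift.

#' Variance effective population size
#'
#' \eqn{N_e = -t / (2 \ln(1 - \sigma^2 / (q_0 (1 - q_0))))}: the size of an
#' idealized Wright-Fisher population whose allele-frequency variance after
#' t generations matches the observed dispersion \eqn{\sigma^2} of sites
#' starting at frequency \eqn{q_0}.
#'
#' @param q0 starting allele frequency, in (0, 1)
#' @param var_qt across-site variance of frequency at generation t
#' @param t generations elapsed
#' @return Ne in diploids; NA when var_qt is 0 (infinite Ne) or at/above
#'   the binomial ceiling q0(1-q0) (complete dispersal)
#' @export
estimate_ne <- function(q0, var_qt, t) {
  stopifnot(length(q0) == length(var_qt), t > 0)
  out <- rep(NA_real_, length(q0))
  ceiling_ <- q0 * (1 - q0)
  ok <- q0 > 0 & q0 < 1 & var_qt > 0 & var_qt < ceiling_
  out[ok] <- -t / (2 * log(1 - var_qt[ok] / ceiling_[ok]))
  out
}

#' Binned Ne estimate from control-population frequency trajectories
#'
#' Sites are binned by their generation-0 minor-allele frequency; within
#' each bin the variance of the generation-t frequencies yields a per-bin
#' Ne, and the median across bins is the headline estimate.
#'
#' @param q0 per-site frequencies at generation 0 (used both for binning,
#'   after folding to minor orientation, and as the conditional mean)
#' @param qt per-site frequencies of the same allele at generation t; sites
#'   whose q0 is folded have qt flipped to match
#' @param t generations elapsed
#' @param bins bin labels over the folded frequency, default
#'   \code{seq(0.05, 0.50, 0.05)} (bin width 0.05)
#' @param min_sites minimum sites per usable bin (default 2)
#' @return list of class \code{ne_estimate}: per-bin data.frame (bin label,
#'   mean q0, variance, n, ne) and median_ne
#' @details The per-bin dispersion is the variance of the frequency change
#'   \eqn{q_t - q_0} across sites, i.e. the drift variance conditional on
#'   the start, so unchanged frequencies give zero dispersion regardless
#'   of the within-bin spread of starting values.
#' @export
binned_ne <- function(q0, qt, t, bins = seq(0.05, 0.50, by = 0.05),
                      min_sites = 2) {
  stopifnot(length(q0) == length(qt))
  width <- bins[2L] - bins[1L]
  lab <- fold_bin(q0, width)
  flip <- !is.na(q0) & q0 > 0.5
  q0f <- ifelse(flip, 1 - q0, q0)
  qtf <- ifelse(flip, 1 - qt, qt)
  keep <- !is.na(lab) & lab %in% round(bins, 10) & !is.na(qtf)
  rows <- lapply(bins, function(b) {
    idx <- which(keep & abs(lab - b) < 1e-9)
    if (length(idx) < min_sites) return(NULL)
    m0 <- mean(q0f[idx])
    v <- var(qtf[idx] - q0f[idx])
    data.frame(bin = b, mean_q0 = m0, var_qt = v, n = length(idx),
               ne = estimate_ne(m0, v, t))
  })
  per_bin <- do.call(rbind, rows)
  med <- if (is.null(per_bin) || all(is.na(per_bin$ne))) NA_real_
         else median(per_bin$ne, na.rm = TRUE)
  structure(list(per_bin = per_bin, median_ne = med, t = t),
            class = "ne_estimate")
}

# one Wright-Fisher trajectory set: matrix reps x t of binomial updates
wf_final_freq <- function(q0, n_copies, t, n_reps) {
  q <- rep(q0, n_reps)
  for (g in seq_len(t)) q <- rbinom(n_reps, n_copies, q) / n_copies
  q
}

#' Pure-drift threshold on the long-short frequency divergence
#'
#' Simulates, per replicate, four independent Wright-Fisher populations
#' (two "long", two "short") from the same starting minor-allele frequency
#' and returns the requested quantile of
#' \eqn{|\bar q_{short} - \bar q_{long}|} at the final generation. Copy
#' number is \code{2 * ne_diploids} for autosomes and
#' \code{round(1.5 * ne_diploids)} for the X (two female plus one male X
#' per breeding pair).
#'
#' @param q0 starting minor-allele frequency, in [0, 0.5]
#' @param ne_diploids effective number of diploids (default 42: 21 males +
#'   21 females)
#' @param t generations (default 12)
#' @param n_reps simulation replicates (default 10000)
#' @param quantile upper quantile reported (default 0.999)
#' @param chrom_mode "autosome" or "X"
#' @param seed integer seed
#' @return the threshold (a single frequency difference)
#' @export
simulate_drift_bound <- function(q0, ne_diploids = 42, t = 12,
                                 n_reps = 10000, quantile = 0.999,
                                 chrom_mode = c("autosome", "X"),
                                 seed = NULL) {
  chrom_mode <- match.arg(chrom_mode)
  stopifnot(q0 >= 0, q0 <= 0.5, ne_diploids >= 1)
  if (q0 == 0) return(0)
  n_copies <- if (chrom_mode == "autosome") 2L * ne_diploids
              else as.integer(round(1.5 * ne_diploids))
  with_seed(seed, {
    finals <- replicate(4L, wf_final_freq(q0, n_copies, t, n_reps))
    stat <- abs((finals[, 3L] + finals[, 4L]) / 2 -
                (finals[, 1L] + finals[, 2L]) / 2)
    unname(stats::quantile(stat, quantile, type = 7))
  })
}

#' Drift-threshold table over the 0.01-binned starting frequencies
#'
#' @param ne_diploids,t,n_reps,quantile,chrom_mode,seed passed to
#'   \code{\link{simulate_drift_bound}}; each bin draws a sub-stream seed
#'   so the table is reproducible bin-by-bin
#' @param bins starting minor-allele frequencies (default 0.01..0.50)
#' @return data.frame of class \code{drift_threshold_table}: q0 bin,
#'   threshold, chrom_mode, n_reps
#' @export
drift_threshold_table <- function(ne_diploids = 42, t = 12, n_reps = 10000,
                                  quantile = 0.999,
                                  chrom_mode = c("autosome", "X"),
                                  bins = seq(0.01, 0.50, by = 0.01),
                                  seed = 1L) {
  chrom_mode <- match.arg(chrom_mode)
  thr <- vapply(bins, function(b) {
    simulate_drift_bound(b, ne_diploids, t, n_reps, quantile, chrom_mode,
                         seed = substream_seed(seed, paste0("driftbin", b)))
  }, 0)
  structure(data.frame(q0 = bins, threshold = thr, chrom_mode = chrom_mode,
                       n_reps = n_reps),
            class = c("drift_threshold_table", "data.frame"))
}

#' Verdict: does an observed divergence exceed the drift bound?
#'
#' @param candidates data.frame with columns q0 (generation-0 frequency,
#'   any orientation) and divergence (|mean short - mean long| at the final
#'   generation); optional column chrom_mode
#' @param table a \code{drift_threshold_table} (or a named list of them
#'   keyed by chrom_mode)
#' @return logical vector (NA where divergence or bin is missing)
#' @export
drift_verdict <- function(candidates, table) {
  stopifnot(all(c("q0", "divergence") %in% names(candidates)))
  tables <- if (inherits(table, "drift_threshold_table"))
    list(autosome = table, X = table) else table
  bin <- fold_bin(candidates$q0, width = 0.01)
  mode <- candidates$chrom_mode %||% rep("autosome", nrow(candidates))
  thr <- vapply(seq_len(nrow(candidates)), function(i) {
    if (!is.na(candidates$q0[i]) && candidates$q0[i] %in% c(0, 1))
      return(0)                      # lost/fixed allele cannot drift
    tb <- tables[[mode[i]]]
    j <- which(abs(tb$q0 - bin[i]) < 1e-9)
    if (length(j) != 1L) NA_real_ else tb$threshold[j]
  }, 0)
  ifelse(is.na(candidates$divergence) | is.na(thr), NA,
         candidates$divergence > thr)
}
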