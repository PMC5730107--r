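# Linkage disequilibrium on phased inbred founder lines, and the
# frequency-bound method for tracking LD persistence in pooled data where
# haplotypes are unobservable.

#' Squared allelic correlation between two sites on phased haploid lines
#'
#' Computes \eqn{r^2 = D^2 / (p_a(1-p_a)\,p_b(1-p_b))} with
#' \eqn{D = p_{AB} - p_a p_b} from the 0/1 allele indicators of fully
#' inbred (haploid-coded) lines.
#'
#' @param hap_a,hap_b 0/1 vectors of equal length, one entry per line
#' @return r-squared in [0, 1]; NA if either site is monomorphic
#' @export
r2_phased <- function(hap_a, hap_b) {
  stopifnot(length(hap_a) == length(hap_b), length(hap_a) >= 2)
  if (anyNA(hap_a) || anyNA(hap_b)) return(NA_real_)
  pa <- mean(hap_a)
  pb <- mean(hap_b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  D <- mean(hap_a * hap_b) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Admissible minor-allele frequency range at a partner site under high LD
#'
#' Given the binned minor-allele frequency \code{p_a} at a focal site and a
#' required \code{r2_min}, returns the closed-form lower and upper bounds on
#' the partner site's minor-allele frequency \code{p_b} compatible with
#' \eqn{r^2 \ge} \code{r2_min}: lower \eqn{= r^2 p_a / (1 + r^2 p_a - p_a)},
#' upper \eqn{= \min(p_a / (r^2 - r^2 p_a + p_a),\ 0.5)}.
#'
#' @param p_a focal-site minor allele frequency, in (0, 0.5]
#' @param r2_min LD threshold, default 0.8
#' @return named numeric vector c(lower, upper); vectorised over p_a
#' @export
vanliere_bounds <- function(p_a, r2_min = 0.8) {
  stopifnot(all(p_a > 0), all(p_a <= 0.5), r2_min > 0, r2_min <= 1)
  lower <- r2_min * p_a / (1 + r2_min * p_a - p_a)
  upper <- pmin(p_a / (r2_min - r2_min * p_a + p_a), 0.5)
  if (length(p_a) == 1L) c(lower = lower, upper = upper)
  else cbind(lower = lower, upper = upper)
}

#' Sample SNPs per chromosome and compute all pairwise r-squared values
#'
#' Draws \code{n_per_chrom} polymorphic sites per chromosome from a founder
#' panel and enumerates every unordered pair within the combined sample
#' (including inter-chromosome pairs), attaching the phased r-squared.
#'
#' @param panel a \code{founder_panel}
#' @param n_per_chrom sites sampled per chromosome (default 3600)
#' @param seed integer seed
#' @param max_pairs refuse enumeration beyond this many pairs (guards memory)
#' @return data.frame site_a, site_b (panel site indices, a = lower
#'   position or lower index across chromosomes), chrom_a, chrom_b,
#'   pos_a, pos_b, r2
#' @export
sample_snp_pairs <- function(panel, n_per_chrom = 3600, seed = NULL,
                             max_pairs = 5e6) {
  stopifnot(inherits(panel, "founder_panel"))
  sites <- panel$sites
  poly <- which(colMeans(panel$geno) > 0 & colMeans(panel$geno) < 1)
  picked <- with_seed(seed, {
    unlist(lapply(split(poly, sites$chrom[poly]), function(idx) {
      if (length(idx) < n_per_chrom)
        stop_config("chromosome has %d polymorphic sites, need %d",
                    length(idx), n_per_chrom)
      sort(sample(idx, n_per_chrom))
    }), use.names = FALSE)
  })
  picked <- sort(picked)
  np <- n_pairs(length(picked))
  if (np > max_pairs)
    stop_config("%.0f pairs requested, exceeds max_pairs = %.0f", np, max_pairs)
  G <- panel$geno[, picked, drop = FALSE]
  nl <- nrow(G)
  p <- colMeans(G)
  # r2 for all pairs at once: D = P_AB - pa pb via crossprod
  pab <- crossprod(G) / nl
  D <- pab - tcrossprod(p)
  denom <- tcrossprod(p * (1 - p))
  r2m <- D^2 / denom
  ut <- which(upper.tri(r2m), arr.ind = TRUE)
  data.frame(
    site_a = picked[ut[, 1L]], site_b = picked[ut[, 2L]],
    chrom_a = sites$chrom[picked[ut[, 1L]]],
    chrom_b = sites$chrom[picked[ut[, 2L]]],
    pos_a = sites$pos[picked[ut[, 1L]]],
    pos_b = sites$pos[picked[ut[, 2L]]],
    r2 = r2m[ut]
  )
}

# fold a frequency to minor orientation and assign it to the 0.01 grid;
# exact grid values map to themselves, bin 0 (monomorphic) returns NA
fold_bin <- function(p, width = 0.01) {
  p <- pmin(p, 1 - p)
  b <- ceiling(p / width - 1e-9) * width
  b <- pmin(b, 0.5)
  b[p <= 0] <- NA_real_
  round(b, 10)
}

#' LD persistence of founder high-LD pairs across pooled generations
#'
#' For each population and generation, a founder pair with \eqn{r^2 \ge}
#' \code{r2_min} is considered retained when the partner site's pooled
#' minor-allele frequency lies within the VanLiere bounds computed from the
#' focal site's binned frequency. The site at the lower genomic position
#' plays the focal ("A") role; \code{symmetric = TRUE} additionally accepts
#' pairs passing with the roles swapped.
#'
#' @param pairs data.frame as from \code{\link{sample_snp_pairs}}, already
#'   restricted to founder pairs with high r-squared
#' @param freqs data.frame with columns site (panel site index),
#'   population, generation, freq (minor-allele frequency)
#' @param r2_min LD threshold, default 0.8
#' @param symmetric also test with A and B swapped
#' @return data.frame population, generation, n_retained, n_tested,
#'   mean_distance (intra-chromosome retained pairs only; NA if none)
#' @export
ld_persistence <- function(pairs, freqs, r2_min = 0.8, symmetric = FALSE) {
  stopifnot(all(c("site_a", "site_b") %in% names(pairs)),
            all(c("site", "population", "generation", "freq") %in% names(freqs)))
  out <- list()
  for (grp in split(freqs, list(freqs$population, freqs$generation), drop = TRUE)) {
    f <- grp$freq[match(pairs$site_a, grp$site)]
    g <- grp$freq[match(pairs$site_b, grp$site)]
    ok <- !is.na(f) & !is.na(g)
    pa <- fold_bin(f)
    pb <- pmin(g, 1 - g)
    ret <- retained_at(pa, pb, r2_min)
    if (symmetric) {
      ret <- ret | retained_at(fold_bin(g), pmin(f, 1 - f), r2_min)
    }
    ret <- ret & ok
    intra <- ret & pairs$chrom_a == pairs$chrom_b
    out[[length(out) + 1L]] <- data.frame(
      population = grp$population[1L], generation = grp$generation[1L],
      n_retained = sum(ret, na.rm = TRUE), n_tested = sum(ok),
      mean_distance = if (any(intra, na.rm = TRUE))
        mean(abs(pairs$pos_a - pairs$pos_b)[which(intra)]) else NA_real_
    )
  }
  res <- do.call(rbind, out)
  res[order(res$population, res$generation), , drop = FALSE]
}

retained_at <- function(pa_bin, pb, r2_min) {
  ret <- rep(FALSE, length(pa_bin))
  use <- !is.na(pa_bin) & !is.na(pb) & pb > 0
  if (any(use)) {
    bb <- vanliere_bounds(pa_bin[use], r2_min)
    if (is.null(dim(bb))) bb <- matrix(bb, 1L, 2L)
    ret[use] <- pb[use] >= bb[, 1L] & pb[use] <= bb[, 2L]
  }
  ret
}
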