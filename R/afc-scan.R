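# Pooled allele-frequency change detection: minor-allele definition,
# coverage filtering, Beta-posterior HPD intervals for read proportions,
# sex-stratified Cochran-Mantel-Haenszel scans over generation pairs,
# control-overlap filtering, and the grouped logistic-regression filter
# that selects trajectories diverging between selection schemes.

#' Construct an allele-count panel
#'
#' @param sites data.frame with columns chrom, pos, ref, alt and optional
#'   class ("SNP"/"indel")
#' @param samples data.frame with columns population, scheme ("long",
#'   "short" or "control"), replicate, sex, generation; one row per column
#'   of the count matrices
#' @param ref_count,alt_count integer matrices, sites x samples
#' @return object of class \code{allele_count_panel}
#' @export
allele_count_panel <- function(sites, samples, ref_count, alt_count) {
  stopifnot(nrow(ref_count) == nrow(sites), ncol(ref_count) == nrow(samples),
            all(dim(ref_count) == dim(alt_count)))
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
    stop("negative counts", call. = FALSE)
  if (is.null(sites$class)) sites$class <- "SNP"
  samples$sample_id <- samples$sample_id %||% with(
    samples, paste(population, sex, generation, sep = "."))
  structure(list(sites = sites, samples = samples,
                 ref_count = ref_count, alt_count = alt_count),
            class = "allele_count_panel")
}

#' @export
print.allele_count_panel <- function(x, ...) {
  cat("allele_count_panel:", nrow(x$sites), "sites x",
      nrow(x$samples), "samples\n")
  invisible(x)
}

#' Define minor alleles from summed counts at a reference generation
#'
#' The minor allele at a site is the allele with the lower total read
#' count summed over every sample of the reference generation; ties break
#' toward the alt allele. Sites with zero reads at the reference
#' generation are flagged and left unassigned.
#'
#' @param panel an \code{allele_count_panel}
#' @param reference_generation generation used for the summation (default 0)
#' @return list: minor_is_alt (logical per site, NA where deferred),
#'   minor_freq (matrix sites x samples of minor-allele frequencies, NA
#'   where a cell has zero coverage), ref_freq (per-site minor frequency
#'   at the reference generation), fixed (logical: minor frequency zero in
#'   every sample, the "fixed for the major allele" tally)
#' @export
define_minor_allele <- function(panel, reference_generation = 0) {
  g0 <- panel$samples$generation == reference_generation
  if (!any(g0)) stop("reference generation absent", call. = FALSE)
  ref0 <- rowSums(panel$ref_count[, g0, drop = FALSE], na.rm = TRUE)
  alt0 <- rowSums(panel$alt_count[, g0, drop = FALSE], na.rm = TRUE)
  minor_is_alt <- alt0 <= ref0          # tie -> alt
  minor_is_alt[ref0 + alt0 == 0] <- NA
  minor <- minor_count_matrix(panel, minor_is_alt)
  tot <- panel$ref_count + panel$alt_count
  minor_freq <- ifelse(tot > 0, minor / tot, NA_real_)
  dim(minor_freq) <- dim(tot)
  ref_freq <- ifelse(minor_is_alt, alt0, ref0) / (ref0 + alt0)
  # fixed for the major allele at the reference generation
  fixed <- !is.na(minor_is_alt) & ref_freq == 0
  list(minor_is_alt = minor_is_alt, minor_freq = minor_freq,
       ref_freq = ref_freq, fixed = fixed)
}

#' Coverage filter on per-sample totals
#'
#' Cells whose total read count falls below \code{min_total} or above
#' \code{max_total} are masked (both counts set NA); totals exactly at
#' either bound are retained. Downstream tests drop masked cells.
#'
#' @param panel an \code{allele_count_panel}
#' @param min_total minimum total (default 10)
#' @param max_total maximum total (default 2000)
#' @return the panel with failing cells masked
#' @export
coverage_filter <- function(panel, min_total = 10, max_total = 2000) {
  stopifnot(min_total > 0, max_total > min_total)
  tot <- panel$ref_count + panel$alt_count
  bad <- is.na(tot) | tot < min_total | tot > max_total
  panel$ref_count[bad] <- NA_integer_
  panel$alt_count[bad] <- NA_integer_
  panel
}

#' Highest-posterior-density interval for a read allele proportion
#'
#' Beta posterior for the binomial proportion under the Jeffreys prior
#' Beta(1/2, 1/2); the interval is the shortest one carrying \code{mass}
#' posterior probability. When a posterior shape parameter is <= 1 the
#' density is monotone at that boundary and the interval is one-sided.
#'
#' @param minor_count observed minor-allele reads
#' @param total total reads (>= 1)
#' @param mass posterior mass (default 0.95)
#' @param prior Beta prior shape parameters (default Jeffreys c(0.5, 0.5))
#' @return c(lower, upper)
#' @export
allele_hpd_interval <- function(minor_count, total, mass = 0.95,
                                prior = c(0.5, 0.5)) {
  stopifnot(total >= 1, minor_count >= 0, minor_count <= total,
            mass > 0, mass < 1)
  a <- minor_count + prior[1L]
  b <- total - minor_count + prior[2L]
  if (a <= 1 && b <= 1) {      # U-shaped: fall back to central interval
    return(c(lower = qbeta((1 - mass) / 2, a, b),
             upper = qbeta((1 + mass) / 2, a, b)))
  }
  if (a <= 1) return(c(lower = 0, upper = qbeta(mass, a, b)))
  if (b <= 1) return(c(lower = qbeta(1 - mass, a, b), upper = 1))
  width <- function(p_lo) qbeta(p_lo + mass, a, b) - qbeta(p_lo, a, b)
  opt <- optimize(width, c(0, 1 - mass), tol = 1e-10)
  c(lower = qbeta(opt$minimum, a, b), upper = qbeta(opt$minimum + mass, a, b))
}

#' Cochran-Mantel-Haenszel test for stratified 2x2 tables
#'
#' Mantel-Haenszel chi-square without continuity correction:
#' \eqn{(\sum_k a_k - \sum_k E_k)^2 / \sum_k V_k} with the usual
#' hypergeometric expectation and variance per stratum; P from a 1-df
#' chi-square. All-zero (or single-margin) strata are dropped.
#'
#' @param tables a 2x2xK array, or a list of 2x2 matrices; rows = allele
#'   (minor, major), columns = generation (g1, g2)
#' @return list(statistic, p.value, df = 1, k_used)
#' @export
cmh_test <- function(tables) {
  if (is.list(tables)) tables <- simplify2array(tables)
  if (length(dim(tables)) == 2L) dim(tables) <- c(dim(tables), 1L)
  stopifnot(dim(tables)[1L] == 2, dim(tables)[2L] == 2)
  a <- tables[1, 1, ]; b <- tables[1, 2, ]
  c_ <- tables[2, 1, ]; d <- tables[2, 2, ]
  comp <- cmh_components(a, b, c_, d)
  stat <- comp$num^2 / comp$den
  if (!is.finite(stat)) stat <- NA_real_
  list(statistic = stat,
       p.value = if (is.na(stat)) NA_real_ else pchisq(stat, 1, lower.tail = FALSE),
       df = 1L, k_used = comp$k)
}

# per-sample minor-allele count matrix from the per-site orientation
minor_count_matrix <- function(panel, minor_is_alt) {
  m <- panel$alt_count
  flip <- which(minor_is_alt %in% FALSE)
  m[flip, ] <- panel$ref_count[flip, , drop = FALSE]
  m[is.na(minor_is_alt), ] <- NA_integer_
  m
}

# shared MH arithmetic; inputs are vectors over strata (NA-safe)
cmh_components <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  use <- !is.na(n) & n >= 2 & (a + b) > 0 & (c_ + d) > 0 &
         (a + c_) > 0 & (b + d) > 0
  a <- a[use]; b <- b[use]; c_ <- c_[use]; d <- d[use]; n <- n[use]
  E <- (a + b) * (a + c_) / n
  V <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  list(num = sum(a - E), den = sum(V), k = length(n))
}

# vectorised across sites: each argument is a sites x strata matrix of
# minor (m) and major (M) counts at generations 1 and 2
cmh_stat_matrix <- function(m1, M1, m2, M2) {
  n <- m1 + M1 + m2 + M2
  use <- !is.na(n) & n >= 2 & (m1 + m2) > 0 & (M1 + M2) > 0 &
         (m1 + M1) > 0 & (m2 + M2) > 0
  E <- (m1 + m2) * (m1 + M1) / n
  V <- (m1 + m2) * (M1 + M2) * (m1 + M1) * (m2 + M2) / (n^2 * (n - 1))
  E[!use] <- NA; V[!use] <- NA
  num <- rowSums((m1 - E), na.rm = TRUE)
  den <- rowSums(V, na.rm = TRUE)
  k <- rowSums(use)
  stat <- ifelse(k > 0 & den > 0, num^2 / den, NA_real_)
  list(statistic = stat, p.value = pchisq(stat, 1, lower.tail = FALSE))
}

#' Genome scan: CMH tests per site, population and generation pair
#'
#' For each population (scheme x replicate) and consecutive sequenced
#' generation pair, a stratified 2x2 test of allele (minor/major) against
#' generation with the two sex pools as strata. A site is significant for
#' a population when any generation pair gives P below \code{alpha};
#' cells masked by the coverage filter drop out of the affected pair only.
#'
#' @param panel a coverage-filtered \code{allele_count_panel}
#' @param generation_pairs list of 2-vectors; default consecutive pairs of
#'   the panel's sequenced generations
#' @param alpha significance threshold (default the replayed-design
#'   Bonferroni constant 2.3e-8; pass \code{0.05 / n} for other designs)
#' @param minor result of \code{\link{define_minor_allele}} (computed if
#'   omitted)
#' @return object of class \code{scan_result}: per-population P-value
#'   matrices (sites x pairs), significant-site index sets, alpha, pairs
#' @export
afc_scan <- function(panel, generation_pairs = NULL, alpha = 2.3e-8,
                     minor = NULL) {
  gens <- sort(unique(panel$samples$generation))
  if (is.null(generation_pairs))
    generation_pairs <- Map(c, gens[-length(gens)], gens[-1L])
  if (is.null(minor)) minor <- define_minor_allele(panel, min(gens))
  minor_mat <- minor_count_matrix(panel, minor$minor_is_alt)
  major_mat <- panel$ref_count + panel$alt_count - minor_mat

  pops <- unique(panel$samples$population)
  pvals <- list(); sig <- list()
  pair_names <- vapply(generation_pairs, paste, "", collapse = "-")
  for (pop in pops) {
    P <- matrix(NA_real_, nrow(panel$sites), length(generation_pairs),
                dimnames = list(NULL, pair_names))
    for (j in seq_along(generation_pairs)) {
      gp <- generation_pairs[[j]]
      s1 <- which(panel$samples$population == pop &
                  panel$samples$generation == gp[1L])
      s2 <- which(panel$samples$population == pop &
                  panel$samples$generation == gp[2L])
      if (length(s1) == 0 || length(s2) == 0) {
        warning(sprintf("population %s: generation pair %s missing, skipped",
                        pop, pair_names[j]))
        next
      }
      # strata = sexes: align s1/s2 by sex label
      sex1 <- panel$samples$sex[s1]; sex2 <- panel$samples$sex[s2]
      common <- intersect(sex1, sex2)
      s1 <- s1[match(common, sex1)]; s2 <- s2[match(common, sex2)]
      res <- cmh_stat_matrix(
        minor_mat[, s1, drop = FALSE], major_mat[, s1, drop = FALSE],
        minor_mat[, s2, drop = FALSE], major_mat[, s2, drop = FALSE])
      P[, j] <- res$p.value
    }
    pvals[[pop]] <- P
    sig[[pop]] <- which(apply(P, 1L, function(p) any(p < alpha, na.rm = TRUE)))
  }
  structure(list(p_values = pvals, significant = sig, alpha = alpha,
                 pairs = generation_pairs, minor = minor,
                 samples = panel$samples),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("CMH scan,", length(x$p_values), "populations, alpha =", x$alpha, "\n")
  for (p in names(x$significant))
    cat(" ", p, ":", length(x$significant[[p]]), "significant sites\n")
  invisible(x)
}

#' Control-overlap candidate filter
#'
#' Candidates are the sites significant in at least one long replicate and
#' at least one short replicate and in no control replicate:
#' (union of long) intersect (union of short) minus (union of control).
#' \code{per_replicate_intersection = TRUE} replaces the within-scheme
#' unions with intersections.
#'
#' @param sig_long,sig_short,sig_control lists of site-index vectors, one
#'   entry per replicate population
#' @param per_replicate_intersection alternative within-scheme rule
#' @return sorted candidate site indices
#' @export
overlap_filter <- function(sig_long, sig_short, sig_control,
                           per_replicate_intersection = FALSE) {
  comb <- if (per_replicate_intersection)
    function(l) Reduce(intersect, l) else function(l) Reduce(union, l)
  sort(setdiff(intersect(comb(sig_long), comb(sig_short)),
               Reduce(union, sig_control)))
}

#' Grouped logistic-regression filter on candidate trajectories
#'
#' Per site, fits the grouped binomial model
#' \eqn{logit\,P(minor) = \beta_0 + \beta_1 Gen + \beta_2 Sel +
#' \beta_3 Gen \times Sel} over all long- and short-scheme samples
#' (replicates, sexes and sequenced generations pooled as grouped
#' observations; Gen is the numeric generation index). A site passes when
#' the deviance lack-of-fit P is >= 0.05 and the Sel and Gen x Sel Wald P
#' values are both <= 0.05. Perfect separation triggers a
#' Haldane-Anscombe +0.5 refit, flagged in the output.
#'
#' @param panel an \code{allele_count_panel}
#' @param sites site indices to fit (default all)
#' @param minor result of \code{\link{define_minor_allele}}
#' @return data.frame per site: site, b0, b_gen, b_sel, b_int, p_gen,
#'   p_sel, p_int, p_lack_of_fit, separation, pass
#' @export
logistic_filter <- function(panel, sites = seq_len(nrow(panel$sites)),
                            minor = NULL) {
  if (is.null(minor))
    minor <- define_minor_allele(panel, min(panel$samples$generation))
  sel_cols <- which(panel$samples$scheme %in% c("long", "short"))
  gen <- panel$samples$generation[sel_cols]
  sel <- as.integer(panel$samples$scheme[sel_cols] == "short")
  minor_mat <- minor_count_matrix(panel, minor$minor_is_alt)
  major_mat <- panel$ref_count + panel$alt_count - minor_mat

  rows <- lapply(sites, function(i) {
    y_minor <- minor_mat[i, sel_cols]
    y_major <- major_mat[i, sel_cols]
    ok <- !is.na(y_minor) & !is.na(y_major) & (y_minor + y_major) > 0
    base <- data.frame(site = i, b0 = NA_real_, b_gen = NA_real_,
                       b_sel = NA_real_, b_int = NA_real_, p_gen = NA_real_,
                       p_sel = NA_real_, p_int = NA_real_,
                       p_lack_of_fit = NA_real_, separation = FALSE,
                       pass = FALSE)
    # need both schemes over >= 2 generations each
    if (length(unique(gen[ok & sel == 1])) < 2 ||
        length(unique(gen[ok & sel == 0])) < 2) return(base)
    fit1 <- fit_site_logistic(y_minor[ok], y_major[ok], gen[ok], sel[ok])
    if (fit1$separation) {
      fit1 <- fit_site_logistic(y_minor[ok] + 0.5, y_major[ok] + 0.5,
                                gen[ok], sel[ok])
      fit1$separation <- TRUE
    }
    base[, c("b0", "b_gen", "b_sel", "b_int")] <- fit1$coef
    base[, c("p_gen", "p_sel", "p_int")] <- fit1$p[2:4]
    base$p_lack_of_fit <- fit1$p_lof
    base$separation <- fit1$separation
    base$pass <- !is.na(base$p_lack_of_fit) && base$p_lack_of_fit >= 0.05 &&
      !is.na(base$p_sel) && base$p_sel <= 0.05 &&
      !is.na(base$p_int) && base$p_int <= 0.05
    base
  })
  do.call(rbind, rows)
}

# Covariates are centred before fitting so the Wald tests match the
# classical Type III hypotheses: Sel is the scheme contrast averaged over
# the sequenced generations (not the contrast extrapolated to generation
# 0, which vanishes for symmetric divergence), and Gen is the average
# slope. The interaction test is unaffected by centring. Counts are
# aggregated by covariate profile (Gen x Sel) first — replicates and sex
# pools share a profile — which leaves the likelihood untouched but makes
# the deviance goodness-of-fit the classical covariate-pattern test
# (df = #profiles - 4) rather than a per-pool overdispersion test.
fit_site_logistic <- function(y_minor, y_major, gen, sel) {
  key <- paste(gen, sel)
  y_minor <- as.vector(tapply(y_minor, key, sum))
  y_major <- as.vector(tapply(y_major, key, sum))
  u <- !duplicated(key)
  gen <- gen[u][order(unique(key))]
  sel <- sel[u][order(unique(key))]
  df <- data.frame(gen = gen - mean(gen), sel = sel - mean(sel))
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(cbind(y_minor, y_major) ~ gen * sel, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  full <- matrix(NA_real_, 4, 4,
                 dimnames = list(c("(Intercept)", "gen", "sel", "gen:sel"),
                                 colnames(cf)))
  full[rownames(cf), ] <- cf
  sep <- warned || any(fitted(fit) < 1e-10 | fitted(fit) > 1 - 1e-10)
  df_lof <- fit$df.residual
  p_lof <- if (df_lof > 0) pchisq(deviance(fit), df_lof, lower.tail = FALSE)
           else NA_real_
  list(coef = full[, 1L], p = full[, 4L], p_lof = p_lof, separation = sep)
}
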