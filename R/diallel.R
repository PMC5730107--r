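# Griffing Method 1, Model I decomposition of a full diallel cross
# (all n^2 ordered parental combinations, selfs included) into general
# combining ability (GCA), specific combining ability (SCA) and reciprocal
# (REC) effects, with an orthogonal variance partition and per-effect t
# tests against the pooled cross-by-replicate error.

#' Build a diallel table from replicate-level cross phenotypes
#'
#' @param data data.frame with columns maternal, paternal (parent labels)
#'   and value (trait observation); optional column replicate
#' @return object of class \code{diallel_table}: cell-mean matrix Y
#'   (rows = maternal, cols = paternal), parent labels, replicate data
#' @export
diallel_table <- function(data) {
  stopifnot(all(c("maternal", "paternal", "value") %in% names(data)))
  parents <- sort(unique(c(as.character(data$maternal),
                           as.character(data$paternal))))
  n <- length(parents)
  Y <- matrix(NA_real_, n, n, dimnames = list(parents, parents))
  agg <- tapply(data$value,
                list(factor(data$maternal, parents),
                     factor(data$paternal, parents)), mean)
  Y[] <- agg
  if (anyNA(Y)) stop_config("incomplete diallel: %d of %d cells missing",
                            sum(is.na(Y)), n^2)
  structure(list(Y = Y, parents = parents, n = n, data = data),
            class = "diallel_table")
}

as_diallel <- function(x) {
  if (inherits(x, "diallel_table")) return(x)
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop_config("diallel matrix must be square")
    if (anyNA(x)) stop_config("incomplete diallel table")
    pn <- rownames(x) %||% as.character(seq_len(nrow(x)))
    return(structure(list(Y = x, parents = pn, n = nrow(x), data = NULL),
                     class = "diallel_table"))
  }
  diallel_table(x)
}

#' General combining ability estimates
#'
#' \eqn{\hat g_i = \frac{1}{2n}(X_{i.} + X_{.i}) - \frac{1}{n^2} X_{..}},
#' where \eqn{X_{i.}} and \eqn{X_{.i}} are the row and column sums of the
#' cell-mean table for parent i. Estimates sum to zero.
#'
#' @param table a \code{diallel_table}, square matrix, or replicate data
#' @return named numeric vector of per-parent effects
#' @export
gca <- function(table) {
  d <- as_diallel(table)
  Y <- d$Y; n <- d$n
  g <- (rowSums(Y) + colSums(Y)) / (2 * n) - sum(Y) / n^2
  names(g) <- d$parents
  g
}

#' Specific combining ability estimates
#'
#' \eqn{\hat s_{ij} = \tfrac12(Y_{ij} + Y_{ji})
#'   - \tfrac{1}{2n}(X_{i.} + X_{.i} + X_{j.} + X_{.j})
#'   + \tfrac{1}{n^2} X_{..}}; symmetric by construction.
#'
#' @inheritParams gca
#' @return symmetric n x n matrix
#' @export
sca <- function(table) {
  d <- as_diallel(table)
  Y <- d$Y; n <- d$n
  rc <- rowSums(Y) + colSums(Y)
  s <- (Y + t(Y)) / 2 - outer(rc, rc, `+`) / (2 * n) + sum(Y) / n^2
  dimnames(s) <- list(d$parents, d$parents)
  s
}

#' Reciprocal (parent-of-origin) effect estimates
#'
#' \eqn{\hat r_{ij} = \tfrac12 (Y_{ij} - Y_{ji})}; antisymmetric with zero
#' diagonal.
#'
#' @inheritParams gca
#' @return antisymmetric n x n matrix
#' @export
rec <- function(table) {
  d <- as_diallel(table)
  r <- (d$Y - t(d$Y)) / 2
  dimnames(r) <- list(d$parents, d$parents)
  r
}

#' Full Griffing Method 1 Model I effects
#'
#' @inheritParams gca
#' @return list with mu (grand mean of cell means), gca, sca, rec; the
#'   reconstruction \eqn{\mu + g_i + g_j + s_{ij} + r_{ij}} reproduces the
#'   cell means exactly
#' @export
diallel_effects <- function(table) {
  d <- as_diallel(table)
  list(mu = mean(d$Y), gca = gca(d), sca = sca(d), rec = rec(d))
}

# Exact sampling variance of each effect as a linear functional of the
# cell-mean table: effect = sum(C * Y), Var = sum(C^2) * var(cell mean).
# Avoids transcribing Griffing's printed constants.
effect_coef_norms <- function(n) {
  base <- matrix(0, n, n)
  unit <- function(i, j) { m <- base; m[i, j] <- 1; m }
  coef_norm <- function(extract) {
    # build coefficient matrix by probing with unit tables
    C <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      C[i, j] <- extract(unit(i, j))
    sum(C^2)
  }
  list(
    gca = coef_norm(function(Y) gca(Y)[1L]),
    sca_off = if (n >= 2) coef_norm(function(Y) sca(Y)[1L, 2L]) else NA_real_,
    sca_diag = coef_norm(function(Y) sca(Y)[1L, 1L]),
    rec = if (n >= 2) coef_norm(function(Y) rec(Y)[1L, 2L]) else NA_real_
  )
}

#' Griffing Method 1 Model I analysis of a replicated full diallel
#'
#' Partitions the genotypic (cross) sum of squares into orthogonal GCA,
#' SCA and REC components and the genotype-by-replicate interaction into
#' the matching GCAxR, SCAxR and RECxR terms; each main component is
#' tested against its own interaction mean square. Per-effect standard
#' errors use the pooled interaction mean square (the Model I error) and
#' the exact coefficient norms of each estimator.
#'
#' @param data data.frame with columns maternal, paternal, replicate, value;
#'   every cross must appear in every replicate
#' @return list of class \code{diallel_anova}: effects, anova table
#'   (data.frame), standard errors, t and P values per effect
#' @export
diallel_anova <- function(data) {
  stopifnot(all(c("maternal", "paternal", "value") %in% names(data)))
  if (is.null(data$replicate)) data$replicate <- 1L
  reps <- sort(unique(data$replicate))
  R <- length(reps)
  d <- diallel_table(data)
  n <- d$n
  eff <- diallel_effects(d)

  ss_geno_parts <- function(tab) {
    g <- gca(tab); s <- sca(tab); r <- rec(tab)
    c(GCA = 2 * n * sum(g^2), SCA = sum(s^2), REC = sum(r^2))
  }
  main <- ss_geno_parts(d$Y) * R

  if (R >= 2) {
    per_rep <- lapply(reps, function(rp) {
      sub <- data[data$replicate == rp, , drop = FALSE]
      dr <- diallel_table(sub)
      if (!identical(dr$parents, d$parents))
        stop_config("replicate %s does not cover all crosses", rp)
      dr$Y
    })
    dev_parts <- Reduce(`+`, lapply(per_rep, function(Yr) {
      dev <- Yr - d$Y
      gd <- gca(dev); sd_ <- sca(dev); rd <- rec(dev)
      c(GCAxR = 2 * n * sum(gd^2), SCAxR = sum(sd_^2), RECxR = sum(rd^2))
    }))
    # grand-mean-by-replicate deviations absorb the replicate main effect
    rep_means <- vapply(per_rep, mean, 0)
    ss_rep <- n^2 * sum((rep_means - mean(d$Y))^2)
  } else {
    warning("single replicate: interaction terms inestimable, reduced model")
    dev_parts <- c(GCAxR = NA_real_, SCAxR = NA_real_, RECxR = NA_real_)
    ss_rep <- NA_real_
  }

  df_main <- c(GCA = n - 1, SCA = n * (n - 1) / 2, REC = n * (n - 1) / 2)
  df_int <- df_main * (R - 1)
  ms_main <- main / df_main
  ms_int <- dev_parts / df_int
  Fv <- ms_main / ms_int
  Pv <- pf(Fv, df_main, df_int, lower.tail = FALSE)

  tab <- data.frame(
    term = c("GCA", "SCA", "REC", "Rep", "GCAxR", "SCAxR", "RECxR"),
    df = c(df_main, R - 1, df_int),
    SS = c(main, ss_rep, dev_parts),
    MS = c(ms_main, if (R >= 2) ss_rep / (R - 1) else NA_real_, ms_int),
    F = c(Fv, NA, NA, NA, NA),
    P = c(Pv, NA, NA, NA, NA),
    row.names = NULL
  )

  # pooled Model I error on the cell-mean scale
  if (R >= 2) {
    df_e <- sum(df_int)
    ms_e <- sum(dev_parts) / df_e       # per-observation scale
    var_cellmean <- ms_e / R
  } else {
    df_e <- NA_real_; var_cellmean <- NA_real_
  }
  norms <- effect_coef_norms(n)
  se <- list(
    gca = sqrt(norms$gca * var_cellmean),
    sca_off = sqrt(norms$sca_off * var_cellmean),
    sca_diag = sqrt(norms$sca_diag * var_cellmean),
    rec = sqrt(norms$rec * var_cellmean)
  )
  sca_idx <- which(upper.tri(eff$sca, diag = TRUE), arr.ind = TRUE)
  sca_se <- ifelse(sca_idx[, 1L] == sca_idx[, 2L], se$sca_diag, se$sca_off)
  tests <- list(
    gca = effect_test(eff$gca, se$gca, df_e),
    sca = effect_test(eff$sca[upper.tri(eff$sca, diag = TRUE)], sca_se, df_e),
    rec = effect_test(eff$rec[upper.tri(eff$rec)], se$rec, df_e)
  )
  structure(list(effects = eff, anova = tab, se = se, tests = tests,
                 df_error = df_e, n = n, n_rep = R),
            class = "diallel_anova")
}

effect_test <- function(est, se, df) {
  t <- est / se
  data.frame(estimate = as.vector(est), se = as.vector(se), t = as.vector(t),
             P = 2 * pt(abs(as.vector(t)), df, lower.tail = FALSE))
}

#' @export
print.diallel_anova <- function(x, ...) {
  cat("Griffing Method 1 Model I diallel analysis:",
      x$n, "parents,", x$n_rep, "replicates\n")
  print(x$anova, digits = 4)
  invisible(x)
}
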