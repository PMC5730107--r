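# Quantitative genetics of the selection response: within-population
# variability, cumulative selection differentials and responses, realized
# heritability by the breeder's equation, and scheme divergence.

#' Coefficient of environmental variation
#'
#' \eqn{CV_E = 100\, \sigma_E / \mu} where \eqn{\sigma_E} is the
#' within-population sample standard deviation and \eqn{\mu} the mean.
#'
#' @param values trait measurements (length >= 2)
#' @return percent; NA if the mean is zero
#' @export
cv_e <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * sd(values) / m
}

#' Per-generation summary of one population
#'
#' @param phenos data.frame with columns generation, value and optionally
#'   sex, scheme, replicate; the selected-parent mean is recomputed by
#'   truncating at \code{selection_fraction} per sex in the stated
#'   \code{direction} ("high", "low", or "random" for controls, where the
#'   parent mean is the mean of a uniformly drawn subset)
#' @param selection_fraction proportion kept as parents (default 0.25)
#' @param direction "high", "low" or "random"
#' @param seed used only for \code{direction = "random"}
#' @return data.frame generation, mean, sd, parent_mean, n
#' @export
generation_summary <- function(phenos, selection_fraction = 0.25,
                               direction = c("high", "low", "random"),
                               seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(all(c("generation", "value") %in% names(phenos)),
            selection_fraction > 0, selection_fraction <= 1)
  rows <- lapply(split(phenos, phenos$generation), function(g) {
    sel <- unlist(lapply(split(g$value, g$sex %||% "u"), function(v) {
      k <- max(1L, floor(selection_fraction * length(v)))
      switch(direction,
             high = sort(v, decreasing = TRUE)[seq_len(k)],
             low = sort(v)[seq_len(k)],
             random = with_seed(seed, sample(v, k)))
    }), use.names = FALSE)
    data.frame(generation = g$generation[1L], mean = mean(g$value),
               sd = sd(g$value), parent_mean = mean(sel), n = nrow(g))
  })
  out <- do.call(rbind, rows)
  out[order(out$generation), , drop = FALSE]
}

#' Cumulative selection differentials and responses
#'
#' Per generation t, the selection differential \eqn{S_t} is the selected
#' parents' mean minus the population mean, and the response \eqn{R_{t+1}}
#' is the offspring mean minus the parental-generation mean. The series
#' pairs \eqn{\Sigma S} (summed over the parental generations) with
#' \eqn{\Sigma R} (offspring mean minus the generation-0 mean).
#'
#' @param summaries data.frame as from \code{\link{generation_summary}}:
#'   consecutive generations with columns generation, mean, parent_mean
#' @return data.frame generation, S, R, cumS, cumR (generation 0 rows have
#'   R = cumS = cumR = 0; cumS at generation t sums S over 0..t-1)
#' @export
cumulative_series <- function(summaries) {
  s <- summaries[order(summaries$generation), , drop = FALSE]
  if (any(diff(s$generation) != 1))
    stop("gap in generations", call. = FALSE)
  n <- nrow(s)
  stopifnot(n >= 2)
  S <- s$parent_mean - s$mean
  R <- c(0, diff(s$mean))
  data.frame(generation = s$generation, S = S, R = R,
             cumS = c(0, cumsum(S)[-n]), cumR = s$mean - s$mean[1L])
}

#' Realized heritability from the breeder's equation
#'
#' Fits \eqn{\Sigma R = h^2 \Sigma S} by least squares. The default
#' regression is through the origin (both sums are zero at generation 0 by
#' construction); \code{intercept = TRUE} fits the unconstrained line.
#'
#' @param series data.frame from \code{\link{cumulative_series}}
#' @param intercept fit an intercept (default FALSE)
#' @return list of class \code{h2_estimate}: h2, se, p, df, intercept flag
#' @export
realized_heritability <- function(series, intercept = FALSE) {
  stopifnot(all(c("cumS", "cumR") %in% names(series)))
  d <- series[series$generation != min(series$generation), , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 generations", call. = FALSE)
  if (all(d$cumS == 0)) stop("cumulative differential identically zero",
                             call. = FALSE)
  fit <- if (intercept) lm(cumR ~ cumS, data = d) else lm(cumR ~ cumS + 0, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  row <- sm["cumS", ]
  structure(list(h2 = unname(row["Estimate"]), se = unname(row["Std. Error"]),
                 p = unname(row["Pr(>|t|)"]), df = fit$df.residual,
                 intercept = intercept),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("realized h^2 = %.3f +/- %.3f (P = %.4g)%s\n", x$h2, x$se, x$p,
              if (x$intercept) " [with intercept]" else ""))
  invisible(x)
}

#' Divergence between selection schemes
#'
#' @param long_means per-replicate trait means of the long scheme
#' @param short_means per-replicate trait means of the short scheme
#' @return mean(long) - mean(short)
#' @export
divergence <- function(long_means, short_means) {
  stopifnot(length(long_means) >= 1, length(short_means) >= 1)
  mean(long_means) - mean(short_means)
}
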