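#' @useDynLib sleepsweep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rnorm rpois runif rbeta sd var lm coef pchisq
#'   pt pf qbeta dbeta optimize quantile glm binomial median deviance
#'   fitted setNames
#' @importFrom utils read.table write.table head
NULL

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' All stochastic stages draw their seeds through this helper so that one
#' master seed controls the whole pipeline while stages and replicate
#' populations remain independently reproducible.
#'
#' @param seed master integer seed
#' @param label character tag naming the sub-stream
#' @return an integer seed in [0, 2^31 - 1)
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a local RNG state seeded with `seed` (NULL = use current)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# unordered pair count n(n-1)/2, exact in double for n up to ~9e7
#' Number of unordered pairs among n items
#' @param n item count
#' @return n(n-1)/2
#' @export
n_pairs <- function(n) {
  stopifnot(n >= 0)
  n * (n - 1) / 2
}
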