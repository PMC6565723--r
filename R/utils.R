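#' @useDynLib burstsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rbinom rpois rbeta runif rhyper rmultinom dbeta
#'   dnorm density median quantile sd var acf pbinom wilcox.test ks.test
#'   setNames cor
#' @importFrom utils read.delim write.table head modifyList
NULL

# Internal parameter checks ------------------------------------------------

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(sprintf("'%s' must be strictly positive and finite", name))
  }
  invisible(x)
}

check_range <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(x) | !is.finite(x) |
    (if (lo_open) x <= lo else x < lo) |
    (if (hi_open) x >= hi else x > hi)
  if (any(bad)) {
    stop_domain(sprintf(
      "'%s' must lie in %s%g, %g%s", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  invisible(x)
}

#' Derive a reproducible sub-stream seed for a named simulation stage
#'
#' A single top-level seed is expanded into independent per-stage seeds so
#' that changing the parameters of one pipeline stage does not shift the
#' random draws of another. The derivation is a small deterministic hash of
#' the stage name mixed with the seed, kept within the 32-bit integer range
#' accepted by [set.seed()].
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage name, e.g. `"evf"` or `"capture"`.
#' @return A single integer seed.
#' @examples
#' substream_seed(1, "evf")
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed), length(stage) == 1)
  h <- 0
  for (k in utf8ToInt(as.character(stage))) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 69069 + h) %% 2147483647) + 1L
}

with_stage_seed <- function(seed, stage, expr) {
  if (!is.null(seed)) set.seed(substream_seed(seed, stage))
  expr
}

# rbinom/rpois wrappers that stay safe above integer range -----------------

rbinom_big <- function(size, prob) {
  n <- length(size)
  out <- numeric(n)
  big <- size > 2^30
  if (any(!big)) {
    out[!big] <- rbinom(sum(!big), size[!big], if (length(prob) == 1) prob else prob[!big])
  }
  if (any(big)) {
    p <- if (length(prob) == 1) rep(prob, sum(big)) else prob[big]
    m <- size[big] * p
    out[big] <- pmax(0, round(rnorm(sum(big), m, sqrt(m * (1 - p)))))
  }
  out
}

rpois_big <- function(lambda) {
  n <- length(lambda)
  out <- numeric(n)
  big <- lambda > 2^30
  if (any(!big)) out[!big] <- rpois(sum(!big), lambda[!big])
  if (any(big)) {
    out[big] <- pmax(0, round(rnorm(sum(big), lambda[big], sqrt(lambda[big]))))
  }
  out
}
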