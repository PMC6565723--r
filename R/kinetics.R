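# Two-state promoter model: stationary sampling and its modifiers.
#
# A gene's promoter switches on with rate k_on and off with rate k_off;
# while on, transcripts are produced at rate s and degrade at rate d. All
# rates are expressed relative to d, which is fixed to 1 and never exposed.
# At stationarity the transcript count follows a Beta-Poisson mixture:
# p ~ Beta(k_on, k_off), count ~ Poisson(s * p).

#' Construct a per-gene, per-cell kinetic parameter set
#'
#' Bundles the three kinetic parameters of the two-state promoter model into
#' a validated container. Each component is a genes x cells matrix (scalars
#' and vectors are promoted), strictly positive and finite. The degradation
#' rate is fixed to 1 by convention and is not a field.
#'
#' @param k_on,k_off,s Numeric matrices (or scalars/vectors) of promoter
#'   activation rate, deactivation rate and synthesis rate, relative to the
#'   degradation rate.
#' @return An object of class `kinetic_params`: a list with matrix elements
#'   `k_on`, `k_off`, `s`.
#' @examples
#' kp <- kinetic_params(0.5, 0.5, 10)
#' theoretical_mean(kp$k_on, kp$k_off, kp$s)
#' @export
kinetic_params <- function(k_on, k_off, s) {
  to_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = length(x))
  k_on <- to_mat(k_on); k_off <- to_mat(k_off); s <- to_mat(s)
  if (!all(dim(k_on) == dim(k_off)) || !all(dim(k_on) == dim(s))) {
    stop_domain("k_on, k_off and s must have identical dimensions")
  }
  check_positive(k_on, "k_on")
  check_positive(k_off, "k_off")
  check_positive(s, "s")
  structure(list(k_on = k_on, k_off = k_off, s = s),
            class = "kinetic_params")
}

#' @exportS3Method base::print
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameter set: %d genes x %d cells (d = 1)\n",
              nrow(x$k_on), ncol(x$k_on)))
  out <- attr(x, "outlier_mask")
  if (!is.null(out)) cat(sprintf("  high-expression outlier genes: %d\n", sum(out)))
  invisible(x)
}

#' Sample stationary transcript counts from the two-state promoter model
#'
#' Draws counts from the Beta-Poisson mixture that is the stationary law of
#' the telegraph model with degradation rate 1: the active fraction
#' `p ~ Beta(k_on, k_off)`, then `count ~ Poisson(s * p)`.
#'
#' @param n Number of draws.
#' @param k_on,k_off,s Kinetic parameters, scalars or vectors recycled to
#'   length `n`. All must be strictly positive.
#' @return Integer-valued numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' mean(rbeta_poisson(1e4, 0.5, 0.5, 10))  # ~ s * k_on / (k_on + k_off) = 5
#' @export
rbeta_poisson <- function(n, k_on, k_off, s) {
  stopifnot(n >= 1)
  check_positive(k_on, "k_on")
  check_positive(k_off, "k_off")
  check_positive(s, "s")
  p <- rbeta(n, k_on, k_off)
  # rbeta underflows to 0/1 for extreme shapes; Poisson handles both ends
  rpois(n, rep_len(s, n) * p)
}

#' Expected stationary expression of the two-state model
#'
#' Returns `s * k_on / (k_on + k_off)`, the mean of the Beta-Poisson
#' stationary distribution (synthesis rate times the expected active
#' fraction of the promoter).
#'
#' @inheritParams rbeta_poisson
#' @return Numeric of the common shape of the inputs.
#' @export
theoretical_mean <- function(k_on, k_off, s) {
  check_positive(k_on, "k_on")
  check_positive(k_off, "k_off")
  check_positive(s, "s")
  s * k_on / (k_on + k_off)
}

#' Increase bimodality of expression while preserving mean and burst frequency
#'
#' Divides `k_on` and `k_off` by `10^bimod`, leaving `s` untouched. Slower
#' switching at the same burst frequency `k_on/(k_on+k_off)` stretches the
#' Beta mixing distribution towards its extremes, so counts become more
#' bimodal and the Fano factor rises, while the theoretical mean of every
#' gene is unchanged.
#'
#' @param params A [kinetic_params] object.
#' @param bimod Bimodality knob in \[0, 1\].
#' @return A [kinetic_params] object with scaled switching rates.
#' @export
apply_bimod <- function(params, bimod) {
  stopifnot(inherits(params, "kinetic_params"))
  check_range(bimod, "bimod", 0, 1)
  f <- 10^bimod
  out <- kinetic_params(params$k_on / f, params$k_off / f, params$s)
  attributes(out) <- c(attributes(out),
                       attributes(params)[setdiff(names(attributes(params)),
                                                  c("names", "class"))])
  out
}

#' Designate constitutively-on high-expression outlier genes
#'
#' Flags a random fraction `prop_hge` of genes as high-expression outliers.
#' Flagged genes are treated as always on: their counts are later drawn from
#' `Poisson(s)` without Beta mixing, and their synthesis rate is inflated by
#' `2^(mean_hge - 1 + rank/n)`, where `rank` orders the flagged genes by
#' mean `s` (smallest first, ties broken by gene index) and `n` is the
#' number of flagged genes.
#'
#' @param params A [kinetic_params] object.
#' @param prop_hge Fraction of genes to flag, in \[0, 1).
#' @param mean_hge Inflation scale, > 1.
#' @return A [kinetic_params] object with attribute `outlier_mask`
#'   (logical per gene) and inflated `s` rows for flagged genes.
#' @export
apply_expression_outliers <- function(params, prop_hge, mean_hge) {
  stopifnot(inherits(params, "kinetic_params"))
  check_range(prop_hge, "prop_hge", 0, 1, hi_open = TRUE)
  if (prop_hge > 0 && mean_hge <= 1) stop_domain("'mean_hge' must be > 1")
  n_genes <- nrow(params$s)
  n_out <- round(prop_hge * n_genes)
  mask <- rep(FALSE, n_genes)
  if (n_out >= 1) {
    idx <- sample.int(n_genes, n_out)
    mask[idx] <- TRUE
    mean_s <- rowMeans(params$s)[idx]
    rk <- rank(mean_s, ties.method = "first")
    params$s[idx, ] <- params$s[idx, , drop = FALSE] *
      2^(mean_hge - 1 + rk / n_out)
  }
  attr(params, "outlier_mask") <- mask
  params
}

#' Sample a true-count matrix from a kinetic parameter set
#'
#' One Beta-Poisson draw per gene and cell; genes flagged as high-expression
#' outliers (see [apply_expression_outliers()]) bypass the Beta mixing and
#' are drawn `Poisson(s)`.
#'
#' @param params A [kinetic_params] object.
#' @return Integer-valued genes x cells matrix.
#' @export
sample_kinetic_counts <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  n <- length(params$s)
  counts <- matrix(rbeta_poisson(n, as.vector(params$k_on),
                                 as.vector(params$k_off),
                                 as.vector(params$s)),
                   nrow = nrow(params$s))
  mask <- attr(params, "outlier_mask")
  if (!is.null(mask) && any(mask)) {
    counts[mask, ] <- rpois(sum(mask) * ncol(counts),
                            as.vector(params$s[mask, , drop = FALSE]))
  }
  dimnames(counts) <- dimnames(params$s)
  counts
}

#' Classify the modality of a gene's stationary expression distribution
#'
#' Draws a large fixed-seed Beta-Poisson sample, smooths it with a Gaussian
#' kernel density, and counts well-separated density peaks. Genes whose
#' single peak sits at zero are `"zero-unimodal"`; a single non-zero peak is
#' `"nonzero-unimodal"`; two peaks (typically a zero and a non-zero mode,
#' arising when both switching rates are slow) are `"bimodal"`.
#'
#' The smoothing bandwidth follows the normal-reference rule with a floor of
#' 0.6 count units, and peaks below 5% of the density maximum are ignored;
#' both choices keep labels reproducible but can shift region boundaries
#' slightly, as any density-based rule does.
#'
#' @param k_on,k_off,s Kinetic parameters, vectors recycled to a common
#'   length; one label is produced per triple.
#' @param n_draws Sample size per triple (default 1e4).
#' @param seed Sub-seed for the classification sample (default 7), so labels
#'   do not depend on the caller's RNG position.
#' @return Character vector of labels in
#'   `c("zero-unimodal", "nonzero-unimodal", "bimodal")`.
#' @examples
#' classify_modality(c(0.1, 0.1, 10), c(0.1, 10, 0.1), 10)
#' @export
classify_modality <- function(k_on, k_off, s, n_draws = 1e4, seed = 7) {
  m <- max(length(k_on), length(k_off), length(s))
  k_on <- rep_len(k_on, m); k_off <- rep_len(k_off, m); s <- rep_len(s, m)
  check_positive(k_on, "k_on"); check_positive(k_off, "k_off")
  check_positive(s, "s")
  if (!exists(".Random.seed", envir = .GlobalEnv)) runif(1)
  vapply(seq_len(m), function(i) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
    set.seed(seed)
    x <- rbeta_poisson(n_draws, k_on[i], k_off[i], s[i])
    if (all(x == 0)) return("zero-unimodal")
    bw <- max(stats::bw.nrd0(x), 0.6)
    d <- density(x, bw = bw, n = 512, from = min(x), to = max(x))
    y <- d$y
    is_max <- c(y[1] > y[2], diff(sign(diff(y))) < 0, y[512] > y[511])
    peaks <- which(is_max & y >= 0.05 * max(y))
    if (length(peaks) >= 2) {
      # require a genuine valley between the two tallest peaks
      top <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
      valley <- min(y[seq(min(top), max(top))])
      if (valley < 0.8 * min(y[top])) return("bimodal")
    }
    if (d$x[peaks[which.max(y[peaks])]] <= 1) "zero-unimodal" else "nonzero-unimodal"
  }, character(1))
}
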