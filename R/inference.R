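# Kinetic-parameter inference from count matrices.
#
# Hierarchy per gene: p_c ~ Beta(k_on, k_off) is the promoter's active
# fraction in cell c; the latent transcript count is Poisson(p_c * s); the
# observation is a Binomial(f) downsampling of it. Both latent layers are
# marginalised exactly: Binomial thinning of a Poisson is Poisson, and
# integrating p against the Beta gives the closed-form Beta-Poisson pmf
#
#   P(y) = (se)^y / y! * B(k_on + y, k_off) / B(k_on, k_off)
#          * e^{-se} * 1F1(k_off; k_on + k_off + y; se),   se = s * f,
#
# (Kummer-transformed confluent hypergeometric, evaluated as a log-space
# series). The sampler is therefore plain Metropolis on (k_on, k_off, s):
# log-scale random walks per parameter plus two joint moves along the
# posterior's correlated directions (a joint k_on/k_off scaling, and a
# k_off move that compensates s to preserve the mean s*k_on/(k_on+k_off)).
# Cell-level latents are avoided on purpose: conditional updates of p pin
# s (and vice versa), which in practice freezes single-site Gibbs chains
# at their starting point on the mean ridge.

# log 1F1(k_off; k_on + k_off + y; se) for each y, by direct summation in
# log space; series terms peak near k ~ se and decay super-geometrically.
log_1f1_koff <- function(y, k_on, k_off, se) {
  k_max <- ceiling(se + 10 * sqrt(se) + 30)
  k <- seq_len(k_max)
  # log (k_off)_k and log se^k / k!
  lk <- cumsum(log(k_off + k - 1)) + k * log(se) - lgamma(k + 1)
  a <- k_on + k_off
  # log (a + y)_k = lgamma(a + y + k) - lgamma(a + y), per y
  lp <- outer(y, k, function(yy, kk) lgamma(a + yy + kk)) - lgamma(a + y)
  lt <- sweep(-lp, 2, lk, "+")
  m <- pmax(apply(lt, 1, max), 0)
  m + log(exp(-m) + rowSums(exp(lt - m)))
}

# Beta-Poisson log-pmf at effective synthesis rate se = s * f.
dbetapois_log <- function(y, k_on, k_off, se) {
  y * log(se) - lgamma(y + 1) +
    lgamma(k_on + y) - lgamma(k_on) +
    lgamma(k_on + k_off) - lgamma(k_on + k_off + y) -
    se + log_1f1_koff(y, k_on, k_off, se)
}

mcmc_chain <- function(y, f, n_iter, prior_meanlog, prior_sdlog,
                       proposal_sd) {
  tab <- table(y)
  y_u <- as.numeric(names(tab))
  w <- as.numeric(tab)
  loglik <- function(k_on, k_off, s) {
    if (!all(is.finite(c(k_on, k_off, s))) || min(k_on, k_off, s) < 1e-8 ||
        max(k_on, k_off) > 1e8 || s > 1e7) return(-Inf)
    .betapois_loglik_cpp(y_u, w, k_on, k_off, s * f)
  }
  lprior <- function(x) dnorm(log(x), prior_meanlog, prior_sdlog, log = TRUE)
  k_on <- exp(rnorm(1, 0, 1))
  k_off <- exp(rnorm(1, 0, 1))
  s <- (max(y) + 1) / f * exp(rnorm(1, 0, 0.3))
  ll <- loglik(k_on, k_off, s)
  out <- matrix(NA_real_, n_iter, 3,
                dimnames = list(NULL, c("k_on", "k_off", "s")))
  try_move <- function(k_on2, k_off2, s2) {
    ll2 <- loglik(k_on2, k_off2, s2)
    la <- ll2 - ll +
      lprior(k_on2) + lprior(k_off2) + lprior(s2) -
      lprior(k_on) - lprior(k_off) - lprior(s)
    if (is.finite(la) && log(runif(1)) < la) {
      k_on <<- k_on2; k_off <<- k_off2; s <<- s2; ll <<- ll2
    }
  }
  for (it in seq_len(n_iter)) {
    try_move(k_on * exp(rnorm(1, 0, proposal_sd)), k_off, s)
    try_move(k_on, k_off * exp(rnorm(1, 0, proposal_sd)), s)
    try_move(k_on, k_off, s * exp(rnorm(1, 0, proposal_sd)))
    # joint scaling of both switching rates (Beta concentration move)
    cfac <- exp(rnorm(1, 0, proposal_sd))
    try_move(k_on * cfac, k_off * cfac, s)
    # k_off move compensated in s to preserve the theoretical mean
    cfac <- exp(rnorm(1, 0, proposal_sd))
    try_move(k_on, k_off * cfac, s * (k_on + k_off * cfac) / (k_on + k_off))
    out[it, ] <- c(k_on, k_off, s)
  }
  out
}

#' Fit the Beta-Poisson kinetic model to observed counts by MCMC
#'
#' Estimates per-gene promoter kinetics (`k_on`, `k_off`, `s`, relative to
#' a degradation rate of 1) from a count matrix of a homogeneous population
#' of cells. Counts are modelled as a Binomial(`f`) downsampling of
#' Poisson(`p * s`) with `p ~ Beta(k_on, k_off)`; several independently
#' initialised chains are run per gene so convergence can be diagnosed.
#'
#' @param counts Non-negative integer matrix (genes x cells) or vector
#'   (one gene).
#' @param f Downsampling probability in (0, 1\] (capture/sequencing
#'   efficiency of the protocol that produced `counts`).
#' @param n_iter Iterations per chain (default 2000).
#' @param n_chains Number of chains (default 3).
#' @param burn_frac Fraction of each chain discarded as burn-in
#'   (default 0.5).
#' @param prior_meanlog,prior_sdlog Log-normal prior on all three
#'   parameters (default median 1, log-sd 2).
#' @param proposal_sd Log-scale random-walk SD (default 0.3).
#' @param seed Optional seed; chain c of gene g runs on its own sub-stream.
#' @return An object of class `kinetics_fit`: list with `samples` (per
#'   gene, an `n_iter x 3 x n_chains` array), `degenerate` (logical per
#'   gene: all-zero input), `f`, `n_iter`, `n_chains`, `burn_frac`.
#' @examples
#' set.seed(1)
#' y <- rbeta_poisson(200, 1, 1, 20)
#' fit <- fit_kinetics_mcmc(y, n_iter = 300, n_chains = 2, seed = 1)
#' posterior_medians(fit)
#' @export
fit_kinetics_mcmc <- function(counts, f = 1, n_iter = 2000, n_chains = 3,
                              burn_frac = 0.5, prior_meanlog = 0,
                              prior_sdlog = 2, proposal_sd = 0.3,
                              seed = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("counts must be non-negative integers")
  }
  check_range(f, "f", 0, 1, lo_open = TRUE)
  stopifnot(n_iter >= 10, n_chains >= 1)
  n_genes <- nrow(counts)
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(n_genes))
  samples <- vector("list", n_genes)
  names(samples) <- gene_ids
  degenerate <- rowSums(counts) == 0
  for (g in seq_len(n_genes)) {
    if (degenerate[g]) next
    arr <- array(NA_real_, c(n_iter, 3, n_chains),
                 dimnames = list(NULL, c("k_on", "k_off", "s"), NULL))
    for (ch in seq_len(n_chains)) {
      if (!is.null(seed)) {
        set.seed(substream_seed(seed, sprintf("mcmc_g%d_c%d", g, ch)))
      }
      arr[, , ch] <- mcmc_chain(counts[g, ], f, n_iter, prior_meanlog,
                                prior_sdlog, proposal_sd)
    }
    samples[[g]] <- arr
  }
  structure(list(samples = samples, degenerate = degenerate, f = f,
                 n_iter = n_iter, n_chains = n_chains,
                 burn_frac = burn_frac),
            class = "kinetics_fit")
}

post_burn <- function(fit, g) {
  arr <- fit$samples[[g]]
  keep <- seq(floor(fit$n_iter * fit$burn_frac) + 1, fit$n_iter)
  arr[keep, , , drop = FALSE]
}

#' Posterior medians of a kinetics fit
#'
#' @param fit A [fit_kinetics_mcmc()] result.
#' @param chains Optional list (per gene) of chain indices to include, as
#'   returned in the `accepted` field of [diagnose_chains()]; default all.
#' @return data.frame with columns `gene`, `k_on`, `k_off`, `s` (NA for
#'   degenerate all-zero genes).
#' @export
posterior_medians <- function(fit, chains = NULL) {
  stopifnot(inherits(fit, "kinetics_fit"))
  res <- t(vapply(seq_along(fit$samples), function(g) {
    if (fit$degenerate[g]) return(c(NA_real_, NA_real_, NA_real_))
    arr <- post_burn(fit, g)
    use <- if (is.null(chains)) seq_len(dim(arr)[3]) else chains[[g]]
    apply(arr[, , use, drop = FALSE], 2, median)
  }, numeric(3)))
  data.frame(gene = names(fit$samples), k_on = res[, 1], k_off = res[, 2],
             s = res[, 3], stringsAsFactors = FALSE)
}

#' Convergence diagnostics for a kinetics fit
#'
#' Computes, per gene and parameter, the lag-autocorrelation profile of
#' each chain (well-mixed chains decay with lag) and checks cross-chain
#' agreement: a chain is accepted when each of its post-burn-in parameter
#' medians lies within a factor `agree_tol` of the cross-chain median. A
#' gene passes when at least two chains are accepted.
#'
#' @param fit A [fit_kinetics_mcmc()] result with at least two chains.
#' @param lag_max Maximum autocorrelation lag (default 50).
#' @param agree_tol Multiplicative agreement tolerance (default 3).
#' @return List with `pass` (logical per gene), `accepted` (per gene,
#'   integer vector of accepted chains), `chain_medians` (per gene,
#'   3 x n_chains matrix) and `autocorr` (per gene, lag x 3 matrix averaged
#'   over chains).
#' @export
diagnose_chains <- function(fit, lag_max = 50, agree_tol = 3) {
  stopifnot(inherits(fit, "kinetics_fit"))
  if (fit$n_chains < 2) stop_domain("diagnostics require at least 2 chains")
  n_genes <- length(fit$samples)
  pass <- logical(n_genes); names(pass) <- names(fit$samples)
  accepted <- vector("list", n_genes)
  chain_medians <- vector("list", n_genes)
  autocorr <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    if (fit$degenerate[g]) { accepted[[g]] <- integer(0); next }
    arr <- post_burn(fit, g)
    med <- apply(arr, c(2, 3), median)  # 3 x n_chains
    overall <- apply(med, 1, median)
    ok <- apply(med, 2, function(m) {
      all(m / overall < agree_tol & overall / m < agree_tol)
    })
    accepted[[g]] <- which(ok)
    chain_medians[[g]] <- med
    ac <- 0
    for (ch in seq_len(dim(arr)[3])) {
      ac <- ac + vapply(1:3, function(p) {
        acf(arr[, p, ch], lag.max = lag_max, plot = FALSE)$acf[-1, 1, 1]
      }, numeric(lag_max))
    }
    autocorr[[g]] <- ac / dim(arr)[3]
    pass[g] <- sum(ok) >= 2
  }
  list(pass = pass, accepted = accepted, chain_medians = chain_medians,
       autocorr = autocorr)
}

#' Pool posterior draws into reference kinetic-parameter distributions
#'
#' Merges the post-burn-in draws of all acceptable chains across genes (and
#' across fits, e.g. one per subpopulation) into the three reference sample
#' vectors consumed by [quantile_map()] / [match_kinetic_params()].
#'
#' @param fits A `kinetics_fit` or a list of them.
#' @param diagnostics Optional matching [diagnose_chains()] result (or list
#'   of them); when supplied, only accepted chains of passing genes are
#'   pooled.
#' @return data.frame with columns `k_on`, `k_off`, `s`.
#' @export
aggregate_posteriors <- function(fits, diagnostics = NULL) {
  if (inherits(fits, "kinetics_fit")) fits <- list(fits)
  if (!is.null(diagnostics) && !is.null(diagnostics$pass)) {
    diagnostics <- list(diagnostics)
  }
  pooled <- list()
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    diag <- if (is.null(diagnostics)) NULL else diagnostics[[i]]
    for (g in seq_along(fit$samples)) {
      if (fit$degenerate[g]) next
      arr <- post_burn(fit, g)
      use <- seq_len(dim(arr)[3])
      if (!is.null(diag)) {
        use <- diag$accepted[[g]]
        if (length(use) == 0) next
      }
      d <- do.call(rbind, lapply(use, function(ch) arr[, , ch]))
      pooled[[length(pooled) + 1]] <- as.data.frame(d)
    }
  }
  if (length(pooled) == 0) stop_domain("no accepted chains to aggregate")
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out
}
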