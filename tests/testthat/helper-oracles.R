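# Shared independent oracles and small fixtures, built in code.

# Binomial upper tail by explicit log-space summation (independent of
# detection_probability's pbinom route).
binom_tail_oracle <- function(N, r, x) {
  if (x <= 0) return(1)
  if (x > N) return(0)
  k <- 0:(x - 1)
  1 - sum(exp(lchoose(N, k) + k * log(r) + (N - k) * log(1 - r)))
}

# Closed-form Beta-Poisson mixture moments (verified against numerical
# integration of the mixture density).
bp_moments <- function(k_on, k_off, s) {
  E <- s * k_on / (k_on + k_off)
  V <- E + s^2 * k_on * k_off / ((k_on + k_off)^2 * (k_on + k_off + 1))
  list(mean = E, var = V)
}

# Chi-square goodness-of-fit of integer draws against exact probabilities,
# pooling tail bins so expected counts stay above 5.
chisq_gof_p <- function(x, support, probs) {
  n <- length(x)
  obs <- tabulate(match(x, support), nbins = length(support))
  obs <- c(obs, n - sum(obs))            # everything beyond the support
  probs <- c(probs, max(0, 1 - sum(probs)))
  keep <- probs * n >= 5
  obs <- c(obs[keep], sum(obs[!keep]))
  probs <- c(probs[keep], sum(probs[!keep]))
  nz <- probs > 0
  suppressWarnings(
    chisq.test(obs[nz], p = probs[nz], rescale.p = TRUE)$p.value)
}

# Exact multivariate hypergeometric pmf by enumeration (small pools only).
mvhyper_pmf <- function(pool, k) {
  grids <- lapply(pool, function(m) 0:m)
  states <- expand.grid(grids)
  states <- states[rowSums(states) == k, , drop = FALSE]
  p <- apply(states, 1, function(x) {
    exp(sum(lchoose(pool, x)) - lchoose(sum(pool), k))
  })
  list(states = as.matrix(states), p = p)
}

two_pop_tree <- function() read_state_tree("(A:1,B:1);")
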