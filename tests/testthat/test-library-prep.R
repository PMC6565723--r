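test_that("capture is per-cell Binomial thinning", {
  true <- matrix(20, 4, 3)
  full <- capture_molecules(true, 1, 0)
  expect_identical(full$captured, true)
  expect_true(all(full$alpha == 1))
  # exact binomial law at alpha = 0.2
  set.seed(51)
  big <- matrix(50, 1, 2e4)
  cap <- capture_molecules(big, 0.2, 0)
  support <- 0:50
  expect_gt(chisq_gof_p(as.vector(cap$captured), support,
                        dbinom(support, 50, 0.2)), 0.01)
  # one efficiency per cell, shared by all genes: with a spread of
  # efficiencies, within-cell gene means covary with the cell's alpha
  set.seed(52)
  sp <- capture_molecules(matrix(1000, 50, 40), 0.5, 0.1)
  expect_gt(cor(colMeans(sp$captured) / 1000, sp$alpha), 0.99)
  expect_error(capture_molecules(true, 0, 0), "alpha")
})

test_that("amplification rates implement the binned length-bias model", {
  len <- seq(500, 10000, length.out = 200)
  flat <- amplification_rates(len, 0.7, 0, 0, 20)
  expect_true(all(flat == 0.7))
  set.seed(53)
  r <- amplification_rates(len, rate_2PCR = 0.7, lenslope = 0.023,
                           MaxAmpBias = 0.3, nbins = 20)
  expect_equal(max(abs(attr(r, "B_length"))), 0.023 * 9.5)
  expect_equal(attr(r, "MaxRandBias"), 0.3 - 0.2185)
  expect_true(all(r >= 0 & r <= 1))
  # shorter genes amplify better on average (sign of the bias)
  expect_gt(mean(r[len < 2000]), mean(r[len > 8000]))
  # printed constraint bound is enforced
  expect_error(amplification_rates(len, 0.7, 2 * 0.3 / 19, 0.3, 20),
               "lenslope")
})

test_that("PCR amplification follows the branching-process expectation", {
  x <- c(5, 8, 0)
  expect_identical(amplify_counts(x, c(1, 1, 1), 1), c(10, 16, 0))
  expect_identical(amplify_counts(x, c(0, 0, 0), 7), x)
  set.seed(54)
  n <- 1e4
  amp <- amplify_counts(rep(1, n), rep(0.3, n), 6)
  expected <- (1 + 0.3)^6
  se <- sd(amp) / sqrt(n)
  expect_lt(abs(mean(amp) - expected), 3 * se)
  # linear (IVT) amplification has no exponential compounding
  lin <- amplify_counts(c(2, 3), c(0.5, 0.5), 10, linear = TRUE, rounds = 10)
  expect_identical(lin, c(2, 3) * 5)
})

test_that("fragmentation is calibrated to the 400 bp mean", {
  set.seed(55)
  lengths <- default_gene_lengths()
  copies <- sample(lengths, 2e4, replace = TRUE)
  m <- mean_fragment_length(copies)
  expect_lt(abs(m - 400) / 400, 0.05)
  # short transcript, one fragment, outside the window: nothing retained
  expect_identical(fragment_retention_prob(80), 0)
  expect_identical(fragment_copies(c(100, 399)), c(1, 1))
  # all fragments of an in-window one-piece transcript are retained
  expect_identical(fragment_retention_prob(400), 1)
  # retention probability lies in (0, 1) and every copy yields at most one
  # 3' fragment
  p <- fragment_retention_prob(lengths)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("sequencing follows the multivariate hypergeometric law", {
  pool <- c(5, 3, 2)
  expect_identical(sequence_pool(pool, 100), pool)   # saturating depth
  expect_identical(sequence_pool(pool, 0), c(0, 0, 0))
  set.seed(56)
  draws <- t(replicate(4000, sequence_pool(pool, 4, "hypergeometric")))
  expect_true(all(rowSums(draws) == 4))
  oracle <- mvhyper_pmf(pool, 4)
  key <- apply(oracle$states, 1, paste, collapse = ",")
  obs <- table(factor(apply(draws, 1, paste, collapse = ","), levels = key))
  expect_gt(suppressWarnings(
    chisq.test(as.vector(obs), p = oracle$p, rescale.p = TRUE)$p.value),
    0.01)
  # multinomial path conserves depth too
  mn <- sequence_pool(c(1e6, 2e6), 100, "multinomial")
  expect_equal(sum(mn), 100)
})

test_that("batch effects are multiplicative and recoverable", {
  m <- matrix(100, 20, 40)
  expect_identical(add_batch_effects(m, 1, 0)[, ], m)
  set.seed(57)
  obs <- structure(list(counts = matrix(1000, 50, 400),
                        cell_meta = data.frame(cell_id = 1:400)),
                   class = "observed_counts")
  out <- add_batch_effects(obs, 2, 0.5)
  lr <- log2(rowMeans(out$counts[, out$cell_meta$batch == 1]) /
             rowMeans(out$counts[, out$cell_meta$batch == 2]))
  truth <- log2(out$batch_factors[, 1] / out$batch_factors[, 2])
  expect_lt(max(abs(lr - truth)), 0.01)  # exact up to integer rounding
})

test_that("UMI counts never exceed captured molecules or true counts", {
  tc <- simulate_true_counts(sim_config(n_genes = 60, n_cells = 30,
                                        seed = 58))
  obs <- simulate_observed_counts(
    tc, tech_params("UMI", alpha_mean = 0.2, depth_mean = 1e5,
                    depth_sd = 1e4), seed = 58)
  expect_true(all(obs$counts <= obs$captured))
  expect_true(all(obs$captured <= tc$counts))
  # determinism
  obs2 <- simulate_observed_counts(
    tc, tech_params("UMI", alpha_mean = 0.2, depth_mean = 1e5,
                    depth_sd = 1e4), seed = 58)
  expect_identical(obs$counts, obs2$counts)
})

test_that("with no PCR and saturating depth UMI counts are Binomial(true, alpha)", {
  # transcripts one mean-fragment long survive size selection surely, so
  # the only loss is capture
  true <- matrix(40, 1, 5000)
  tech <- tech_params("UMI", alpha_mean = 0.3, alpha_sd = 0, nPCR1 = 0,
                      nPCR2 = 0, depth_mean = 1e7, depth_sd = 0,
                      lenslope = 0, MaxAmpBias = 0)
  obs <- simulate_observed_counts(true, tech,
                                  gene_lengths = 400, seed = 59)
  support <- 0:40
  expect_gt(chisq_gof_p(as.vector(obs$counts), support,
                        dbinom(support, 40, 0.3)), 0.01)
})

test_that("good technical parameters preserve true counts better than bad", {
  tc <- simulate_true_counts(sim_config(n_genes = 150, n_cells = 40,
                                        seed = 60))
  sp <- function(alpha, bias, depth) {
    # keep the length slope at ~80% of its admissible bound for each bias
    obs <- simulate_observed_counts(
      tc, tech_params("nonUMI", alpha_mean = alpha, alpha_sd = alpha / 20,
                      MaxAmpBias = bias, lenslope = 0.8 * 2 * bias / 19,
                      depth_mean = depth, depth_sd = depth / 100), seed = 61)
    cor(as.vector(tc$counts), as.vector(obs$counts), method = "spearman")
  }
  good <- sp(0.2, 0.1, 1e6)
  bad <- sp(0.05, 0.2, 1e6)
  expect_gt(good, bad)
})

test_that("UMI counting is less noisy than read counting", {
  tc <- simulate_true_counts(sim_config(n_genes = 120, n_cells = 50,
                                        seed = 62))
  cv <- function(protocol, depth) {
    obs <- simulate_observed_counts(
      tc, tech_params(protocol, alpha_mean = 0.2, depth_mean = depth,
                      depth_sd = depth / 50), seed = 63)
    m <- rowMeans(obs$counts); v <- apply(obs$counts, 1, sd)
    mean((v / m)[m > 0.5])
  }
  expect_lt(cv("UMI", 5e5), cv("nonUMI", 1e6))
})
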