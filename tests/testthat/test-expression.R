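test_that("gene effects have the requested sparsity and scale", {
  set.seed(31)
  all_zero <- sample_gene_effects(10, 5, eta = 1)
  expect_true(all(sapply(all_zero[c("k_on", "k_off", "s")],
                         function(m) all(m == 0))))
  dense <- sample_gene_effects(10, 5, eta = 0)
  expect_true(all(sapply(dense[c("k_on", "k_off", "s")],
                         function(m) all(m != 0))))
  # eta = 0.7 zero fraction within the 3-SE binomial band
  big <- sample_gene_effects(2000, 50, eta = 0.7)
  frac <- mean(big$k_on == 0)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 1e5))
  expect_error(sample_gene_effects(10, 5, eta = 2), "eta")
})

test_that("raw parameters are exact EVF/effect dot products", {
  evf <- matrix(c(1, 2), 1, 2)
  eff <- matrix(c(0.5, -1), 1, 2)
  expect_equal(as.vector(raw_params(evf, eff)), -1.5)
  eff0 <- matrix(0, 3, 2)
  expect_true(all(raw_params(matrix(rnorm(8), 4, 2), eff0) == 0))
  # brute-force triple-loop oracle on a random instance
  set.seed(32)
  evf <- matrix(rnorm(5 * 8), 5, 8)
  eff <- matrix(rnorm(10 * 8), 10, 8)
  oracle <- matrix(0, 10, 5)
  for (g in 1:10) for (c in 1:5) for (j in 1:8) {
    oracle[g, c] <- oracle[g, c] + eff[g, j] * evf[c, j]
  }
  expect_equal(unname(raw_params(evf, eff)), oracle, tolerance = 1e-12)
  expect_error(raw_params(matrix(0, 2, 3), matrix(0, 2, 4)), "EVF")
})

test_that("quantile mapping preserves ranks and the reference multiset", {
  set.seed(33)
  raw <- c(3, 1, 2)
  out <- quantile_map(raw, c(10, 20, 30))
  # monotone: the i-th ranked raw value gets the i-th ranked draw
  expect_true(all(diff(out[order(raw)]) >= 0))
  expect_true(all(out %in% c(10, 20, 30)))
  # with a large distinct reference the draws are distinct and ranks match
  out_big <- quantile_map(raw, seq(1, 2, length.out = 1e5))
  expect_identical(rank(out_big), rank(raw))
  # mapping onto the raw values themselves is a rank-preserving rearrangement
  raw2 <- matrix(rnorm(50, 10), 10, 5)
  out2 <- quantile_map(raw2, as.vector(raw2))
  expect_true(all(sort(out2) %in% sort(raw2)))
  expect_true(all(diff(out2[order(raw2)]) >= 0))
  # stable tie-break: tied raw values receive draws in position order
  out3 <- quantile_map(c(2, 2, 1), c(5, 6, 7, 8))
  expect_lte(out3[1], out3[2])
  expect_lte(out3[3], out3[1])
  expect_error(quantile_map(raw, numeric(0)), "empty|reference")
})

test_that("a gene's raw parameters depend only on its non-zero EVF columns", {
  set.seed(34)
  tr <- two_pop_tree()
  ev <- sample_evfs(tr, "discrete", n_cells = 30, sigma = 0.5, n_evf = 6,
                    n_diff_evf = 2)
  eff <- sample_gene_effects(20, 6, eta = 0.5)
  zero_cols <- which(eff$k_on[1, ] == 0)
  skip_if(length(zero_cols) == 0)
  raw1 <- raw_params(ev$evf$k_on, eff$k_on)
  ev2 <- ev$evf$k_on
  ev2[, zero_cols] <- ev2[, zero_cols] + 100
  raw2 <- raw_params(ev2, eff$k_on)
  expect_equal(raw1[1, ], raw2[1, ])
})

test_that("genes untouched by Diff-EVFs have no between-population signal", {
  # with sigma = 0 every non-Diff EVF equals 1 exactly, so genes with zero
  # effects on all Diff-EVF columns get identical parameters in both
  # populations, hence theoretical LFC exactly 0
  set.seed(35)
  tr <- two_pop_tree()
  ev <- sample_evfs(tr, "discrete", cells_per_population = c(10, 10),
                    sigma = 0, n_evf = 6, n_diff_evf = 2)
  eff <- sample_gene_effects(50, 6, eta = 0.7)
  nd <- n_diff_evf_per_gene(eff, ev$diff_mask)
  skip_if(all(nd > 0))
  # raw parameters of zero-Diff genes are bit-identical in every cell
  for (p in c("k_on", "k_off", "s")) {
    raw <- raw_params(ev$evf[[p]], eff[[p]])
    spread <- apply(raw[nd == 0, , drop = FALSE], 1, function(x) diff(range(x)))
    expect_true(all(spread == 0))
  }
  # after global rank-mapping, tied raw values take adjacent reference
  # draws, so the LFC of zero-Diff genes is near (not exactly) zero and
  # far below that of Diff-carrying genes
  kin <- match_kinetic_params(ev, eff, default_kinetic_reference())
  a <- ev$meta$population == "A"
  kin_a <- kinetic_params(kin$k_on[, a], kin$k_off[, a], kin$s[, a])
  kin_b <- kinetic_params(kin$k_on[, !a], kin$k_off[, !a], kin$s[, !a])
  lfc <- theoretical_lfc(kin_a, kin_b)
  expect_lt(max(abs(lfc[nd == 0])), 0.2)
  expect_lt(median(abs(lfc[nd == 0])), median(abs(lfc[nd > 0])))
})

test_that("simulate_true_counts composes the pipeline reproducibly", {
  cfg <- sim_config(n_genes = 80, n_cells = 60, seed = 42)
  tc <- simulate_true_counts(cfg)
  expect_identical(dim(tc$counts), c(80L, 60L))
  expect_true(all(tc$counts >= 0) && all(tc$counts == round(tc$counts)))
  tc2 <- simulate_true_counts(cfg)
  expect_identical(tc$counts, tc2$counts)
  expect_identical(tc$kinetics, tc2$kinetics)
  # changing the seed changes the draw
  expect_false(identical(
    tc$counts, simulate_true_counts(sim_config(n_genes = 80, n_cells = 60,
                                               seed = 43))$counts))
})

test_that("empirical gene means track the theoretical Beta-Poisson means", {
  cfg <- sim_config(n_genes = 400, n_cells = 500, sigma = 0.05,
                    prop_hge = 0, seed = 44)
  tc <- simulate_true_counts(cfg, tree = read_state_tree("(A:1,B:1);"))
  emp <- rowMeans(tc$counts)
  theo <- rowMeans(theoretical_mean(tc$kinetics$k_on, tc$kinetics$k_off,
                                    tc$kinetics$s))
  expect_gt(cor(emp, theo), 0.99)
})
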