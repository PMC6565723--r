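test_that("Newick parsing validates topology and branch lengths", {
  tr <- read_state_tree("(A:1,B:1);")
  expect_s3_class(tr, "state_tree")
  expect_identical(sort(tr$tip.label), c("A", "B"))
  expect_identical(ape::Ntip(tr), 2L)
  expect_identical(ape::Ntip(example_tree()), 5L)
  expect_error(read_state_tree("(A:1,B:-1);"), "non-negative")
  expect_error(read_state_tree("(A:1,B:1"), "Newick|parse")
  expect_error(read_state_tree("(A:1,A:1);"), "unique")
})

test_that("Brownian tip values follow the tree's covariance structure", {
  # zero-length tree: every tip keeps the root value
  tr0 <- read_state_tree("(A:0,B:0);")
  expect_true(all(sample_brownian_tips(tr0, 5) == 1))

  # sibling tips with zero terminal branches share their ancestor's value
  trs <- read_state_tree("((A:0,B:0):1.3,C:1);")
  tips <- sample_brownian_tips(trs, 20)
  expect_equal(tips["A", ], tips["B", ])

  # E|tip_a - tip_b| = sqrt(2 D / pi), D the tree distance (here 3)
  set.seed(21)
  tr <- read_state_tree("(A:1.5,B:1.5);")
  tips <- sample_brownian_tips(tr, 1e4)
  d <- abs(tips["A", ] - tips["B", ])
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - sqrt(2 * 3 / pi)), 3 * se)

  # variance of tip values grows linearly with depth (Brownian law)
  set.seed(22)
  tr2 <- read_state_tree("((A:0.5):0.5,(B:1.5):0.5,C:4);")
  tips2 <- sample_brownian_tips(tr2, 1e4)
  v <- apply(tips2, 1, var)
  depth <- c(A = 1, B = 2, C = 4)
  fit <- coef(lm(v ~ depth[rownames(tips2)]))
  expect_equal(unname(fit[2]), 1, tolerance = 0.1)
})

test_that("discrete-mode EVFs centre on tip means with spread sigma", {
  tr <- two_pop_tree()
  set.seed(23)
  ev0 <- sample_evfs(tr, "discrete", cells_per_population = c(5, 5),
                     sigma = 0, n_evf = 6, n_diff_evf = 2)
  for (m in ev0$evf) {
    for (pop in c("A", "B")) {
      rows <- m[ev0$meta$population == pop, ]
      expect_true(all(apply(rows, 2, function(x) diff(range(x)) == 0)))
    }
  }
  expect_identical(sum(ev0$diff_mask), 2L)

  # per-column sample SD recovers sigma
  set.seed(24)
  tr1 <- read_state_tree("(A:1,B:1);")
  ev <- sample_evfs(tr1, "discrete", cells_per_population = c(5000, 1),
                    sigma = 0.5, n_evf = 8, n_diff_evf = 2)
  sds <- apply(ev$evf$k_on[ev$meta$population == "A", ], 2, sd)
  se <- 0.5 / sqrt(2 * 4999)
  expect_true(all(abs(sds - 0.5) < 4 * se))

  # non-Diff columns are population-free: KS test non-significant
  set.seed(25)
  ev2 <- sample_evfs(tr1, "discrete", cells_per_population = c(1000, 1000),
                     sigma = 0.4, n_evf = 4, n_diff_evf = 1)
  a <- ev2$meta$population == "A"
  p <- suppressWarnings(
    ks.test(ev2$evf$s[a, 3], ev2$evf$s[!a, 3])$p.value)
  expect_gt(p, 0.01)
})

test_that("continuous-mode cells cover the tree and track one Brownian path", {
  tr <- example_tree()
  set.seed(26)
  ev <- sample_evfs(tr, "continuous", n_cells = 400, sigma = 0.1,
                    n_evf = 5, n_diff_evf = 2)
  expect_identical(nrow(ev$meta), 400L)
  expect_true(all(diff(ev$meta$pseudotime) >= 0))
  # pseudotime bounded by the deepest leaf
  expect_lte(max(ev$meta$pseudotime), 4)
  # sigma = 0: cells at the same position get identical Diff-EVF values;
  # near-root cells sit near the root value 1
  set.seed(27)
  ev0 <- sample_evfs(tr, "continuous", n_cells = 300, sigma = 0,
                     n_evf = 3, n_diff_evf = 1)
  near_root <- which(ev0$meta$pseudotime < 0.05)
  if (length(near_root) > 0) {
    expect_true(all(abs(ev0$evf$k_on[near_root, 1] - 1) < 0.8))
  }
  expect_true(all(ev0$evf$k_on[, 2] == 1))  # non-Diff, sigma = 0
})

test_that("impulse mode follows the curve on-path and the MCA value off-path", {
  tr <- example_tree()
  imp <- list(tip = "1", h0 = 1, h1 = 4, h2 = 2, t_on = 0.3, t_off = 0.8,
              slope = 8)
  set.seed(28)
  ev <- sample_evfs(tr, "impulse", n_cells = 500, sigma = 0, n_evf = 3,
                    n_diff_evf = 1, impulse = imp)
  path_depth <- 3  # root -> leaf "1"
  f <- function(t) impulse_function(t, 1, 4, 2, 0.3 * path_depth,
                                    0.8 * path_depth, 8)
  on_path <- ev$meta$branch %in% c("1", "7")  # leaf 1 and its ancestor node
  expect_true(all(abs(ev$evf$k_on[on_path, 1] -
                      f(ev$meta$pseudotime[on_path])) < 1e-9))
  # off-path cells take the impulse value at their MCA with the path
  off <- !on_path
  expect_true(all(ev$evf$k_on[off, 1] %in% c(f(0), f(1))))

  # constant impulse reduces to fixed-mean sampling
  set.seed(29)
  flat <- sample_evfs(tr, "impulse", n_cells = 100, sigma = 0, n_evf = 2,
                      n_diff_evf = 1,
                      impulse = list(h0 = 2, h1 = 2, h2 = 2))
  expect_true(all(abs(flat$evf$s[, 1] - 2) < 1e-9))
})

test_that("EVF sampling is deterministic under a fixed seed", {
  tr <- example_tree()
  set.seed(30); a <- sample_evfs(tr, "discrete", n_cells = 50)
  set.seed(30); b <- sample_evfs(tr, "discrete", n_cells = 50)
  expect_identical(a, b)
  expect_error(sample_evfs(tr, "discrete", n_cells = 50, sigma = -1),
               "sigma")
})
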