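test_that("theoretical LFC follows from the mean identity", {
  kp <- kinetic_params(matrix(1:6 / 2, 3), matrix(1, 3, 2), matrix(4, 3, 2))
  expect_true(all(theoretical_lfc(kp, kp) == 0))
  kp2 <- kinetic_params(kp$k_on, kp$k_off, kp$s * 2)
  expect_equal(theoretical_lfc(kp, kp2), rep(-1, 3))
  # empirical true-count LFC agrees for well-expressed genes
  set.seed(95)
  tc <- simulate_true_counts(
    sim_config(n_genes = 150, n_cells = 2000, sigma = 0.3, prop_hge = 0,
               seed = 95), tree = two_pop_tree())
  a <- tc$meta$population == "A"
  kin <- tc$kinetics
  lfc_theo <- theoretical_lfc(
    kinetic_params(kin$k_on[, a], kin$k_off[, a], kin$s[, a]),
    kinetic_params(kin$k_on[, !a], kin$k_off[, !a], kin$s[, !a]))
  lfc_emp <- log2(rowMeans(tc$counts[, a])) - log2(rowMeans(tc$counts[, !a]))
  ok <- rowMeans(tc$counts) >= 5
  expect_lt(median(abs(lfc_theo[ok] - lfc_emp[ok])), 0.1)
})

test_that("DE labels require both a Diff-EVF effect and a large LFC", {
  eff <- sample_gene_effects(4, 3, eta = 0)
  eff$k_on[1, ] <- 0; eff$k_off[1, ] <- 0; eff$s[1, ] <- 0
  mask <- c(TRUE, FALSE, FALSE)
  kp_a <- kinetic_params(matrix(1, 4, 2), matrix(1, 4, 2),
                         matrix(c(10, 10, 10, 10), 4, 2))
  kp_b <- kinetic_params(matrix(1, 4, 2), matrix(1, 4, 2),
                         matrix(c(40, 40, 12, 40), 4, 2))
  de <- de_ground_truth(eff, mask, kp_a, kp_b, lfc_threshold = 0.8)
  expect_identical(de$n_diff_evf[1], 0L)
  expect_false(de$is_de[1])           # |LFC| = 2 but no Diff-EVF effect
  expect_true(de$is_de[2])            # effect present and |LFC| = 2
  expect_false(de$is_de[3])           # |LFC| = 0.26 < threshold
  expect_error(de_ground_truth(eff, c(TRUE, FALSE), kp_a, kp_b), "EVF")
})

test_that("Wilcoxon p-values are uniform without Diff-EVFs and skew with them", {
  tc <- simulate_true_counts(
    sim_config(n_genes = 1000, n_cells = 600, seed = 96),
    tree = two_pop_tree())
  a <- tc$meta$population == "A"
  pvals <- apply(tc$counts, 1, function(y) {
    suppressWarnings(wilcox.test(y[a], y[!a])$p.value)
  })
  nd <- n_diff_evf_per_gene(tc$effects, tc$evfs$diff_mask)
  p0 <- pvals[nd == 0 & !tc$outlier_mask]
  expect_gt(length(p0), 5)
  expect_gt(suppressWarnings(ks.test(p0, "punif")$p.value), 0.01)
  # divergence from uniformity grows with the number of Diff-EVFs
  med_p <- c(median(p0, na.rm = TRUE),
             median(pvals[nd >= 1 & nd <= 2], na.rm = TRUE),
             median(pvals[nd >= 3], na.rm = TRUE))
  expect_true(all(diff(med_p) < 0))
})

test_that("sibling populations share DE structure against an outgroup", {
  # a three-level hierarchy: populations 2 and 4 are close siblings
  # (distance 0.4) and population 1 is their distant outgroup (distance 4)
  tr <- read_state_tree("((1:2,(2:0.2,4:0.2):1.8):1,(3:1.5,5:1.5):1.5);")
  hits <- 0
  for (i in 1:10) {
    tc <- simulate_true_counts(
      sim_config(n_genes = 300, n_cells = 450, seed = 200 + i,
                 cells_per_population = c("1" = 150, "2" = 150, "3" = 1,
                                          "4" = 150, "5" = 1)),
      tree = tr)
    de12 <- de_truth_between(tc, "1", "2"); n12 <- sum(de12$is_de)
    de14 <- de_truth_between(tc, "1", "4"); n14 <- sum(de14$is_de)
    de24 <- de_truth_between(tc, "2", "4"); n24 <- sum(de24$is_de)
    jac <- function(x, y) {
      length(intersect(which(x), which(y))) / length(union(which(x), which(y)))
    }
    ok <- n24 < min(n12, n14) &&
      jac(de12$is_de, de14$is_de) > jac(de12$is_de, de24$is_de)
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("detection probability equals the exact binomial tail", {
  for (case in list(c(100, 0.5, 50), c(1000, 0.05, 50), c(2000, 0.03, 50),
                    c(500, 0.1, 30))) {
    expect_equal(detection_probability(case[1], case[2], case[3]),
                 binom_tail_oracle(case[1], case[2], case[3]),
                 tolerance = 1e-12)
  }
  expect_equal(detection_probability(100, 0.5, 50), 0.5398, tolerance = 1e-4)
  expect_identical(detection_probability(100, 0.5, 0), 1)
  expect_identical(detection_probability(10, 0.5, 11), 0)
  # monotone in N and r
  expect_true(all(diff(detection_probability(seq(100, 2000, 100), 0.05, 50)) >= 0))
  expect_lt(detection_probability(1000, 0.04, 50),
            detection_probability(1000, 0.06, 50))
  expect_error(detection_probability(100, 1.2, 5), "r")
})

test_that("the minimal-N calculator inverts the detection probability", {
  n <- min_cells_for_success(r = 0.05, x = 50, target_prob = 0.9)
  expect_lt(n, 1200)
  expect_gte(detection_probability(n, 0.05, 50), 0.9)
  expect_lt(detection_probability(n - 1, 0.05, 50), 0.9)
  expect_identical(min_cells_for_success(1 - 1e-12, 50, 0.5), 50L)
  expect_error(min_cells_for_success(0.05, 50, 1), "target_prob")
})

test_that("rare-population detection needs both count and precision", {
  truth <- rep(c("rare", "common"), c(100, 900))
  clus <- c(rep(1, 50), rep(2, 50), rep(1, 20), rep(2, 880))
  expect_true(rare_pop_detected(clus, truth, "rare"))      # 50/70 = 71%
  clus2 <- c(rep(1, 49), rep(2, 51), rep(2, 900))
  expect_false(rare_pop_detected(clus2, truth, "rare"))    # only 49 cells
  clus3 <- c(rep(1, 50), rep(2, 50), rep(1, 50), rep(2, 850))
  expect_false(rare_pop_detected(clus3, truth, "rare"))    # precision 50%
  expect_error(rare_pop_detected(clus, truth, "absent"), "population")
})

test_that("per-gene fractional transcript change is as printed", {
  a <- rbind(c(5, 5), c(3, 3), c(0, 0))
  b <- rbind(c(2, 3), c(0, 0), c(1, 1))
  out <- bimod_expression_change(a, b)
  expect_equal(out[1], 0.5)
  expect_equal(out[2], 1)
  expect_true(is.na(out[3]))
  expect_true(all(bimod_expression_change(a, a) == 0, na.rm = TRUE))
})
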