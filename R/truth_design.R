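# Ground-truth differential expression labels and experimental-design
# calculators.

#' Theoretical log2 fold change between two populations
#'
#' Per gene: `log2(mean over A cells of s*k_on/(k_on+k_off)) - log2(same
#' over B)`, i.e. the LFC of cell-averaged expected expression computed
#' from the kinetic parameters alone, free of sampling noise. A zero mean
#' yields an infinite (not NaN) LFC.
#'
#' @param kin_a,kin_b [kinetic_params] objects for the two populations,
#'   over the same genes.
#' @return Numeric per-gene LFC (A relative to B).
#' @export
theoretical_lfc <- function(kin_a, kin_b) {
  stopifnot(inherits(kin_a, "kinetic_params"),
            inherits(kin_b, "kinetic_params"))
  if (nrow(kin_a$s) != nrow(kin_b$s)) {
    stop_domain("populations must cover the same genes")
  }
  mu_a <- rowMeans(theoretical_mean(kin_a$k_on, kin_a$k_off, kin_a$s))
  mu_b <- rowMeans(theoretical_mean(kin_b$k_on, kin_b$k_off, kin_b$s))
  log2(mu_a) - log2(mu_b)
}

#' Number of Diff-EVFs with a non-zero effect, per gene
#'
#' Counts, across the three kinetic parameters' effect matrices, the
#' Diff-EVF columns in which a gene has a non-zero coefficient. Genes with
#' a zero count are untouched by the between-population factors and cannot
#' be differentially expressed by construction.
#'
#' @param effects A `gene_effects` object.
#' @param diff_mask Logical per EVF column (TRUE = Diff-EVF).
#' @return Integer vector per gene.
#' @export
n_diff_evf_per_gene <- function(effects, diff_mask) {
  stopifnot(inherits(effects, "gene_effects"))
  if (length(diff_mask) != ncol(effects$k_on)) {
    stop_domain("diff_mask length must equal the number of EVFs")
  }
  as.integer(Reduce(`+`, lapply(effects[c("k_on", "k_off", "s")], function(m) {
    rowSums(m[, diff_mask, drop = FALSE] != 0)
  })))
}

#' Ground-truth differential-expression labels
#'
#' A gene is labelled DE between two populations when (i) it has at least
#' one Diff-EVF with a non-zero gene effect (so a between-population factor
#' can reach it) and (ii) its theoretical |LFC| exceeds `lfc_threshold`
#' (effects of different Diff-EVFs can cancel, so the reachable genes are
#' filtered by realised fold change; thresholds of 0.6-1 are customary).
#'
#' @param effects A `gene_effects` object.
#' @param diff_mask Logical Diff-EVF mask per column.
#' @param kin_a,kin_b [kinetic_params] of the two populations.
#' @param lfc_threshold Absolute log2-fold-change threshold (default 0.8).
#' @return data.frame with `gene`, `n_diff_evf`, `lfc`, `is_de`.
#' @export
de_ground_truth <- function(effects, diff_mask, kin_a, kin_b,
                            lfc_threshold = 0.8) {
  nd <- n_diff_evf_per_gene(effects, diff_mask)
  lfc <- theoretical_lfc(kin_a, kin_b)
  gene <- rownames(effects$k_on)
  if (is.null(gene)) gene <- sprintf("gene%d", seq_along(nd))
  data.frame(gene = gene, n_diff_evf = nd, lfc = lfc,
             is_de = nd > 0 & abs(lfc) > lfc_threshold,
             stringsAsFactors = FALSE)
}

#' Ground-truth DE between two populations of a simulation
#'
#' Convenience wrapper around [de_ground_truth()] for a
#' [simulate_true_counts()] result: restricts the kinetic parameters to the
#' cells of two named populations.
#'
#' @param true A `true_counts` object (discrete mode).
#' @param pop_a,pop_b Population labels (tree leaves).
#' @param lfc_threshold Absolute LFC threshold.
#' @return As [de_ground_truth()].
#' @export
de_truth_between <- function(true, pop_a, pop_b, lfc_threshold = 0.8) {
  stopifnot(inherits(true, "true_counts"))
  pick <- function(pop) {
    idx <- which(true$meta$population == pop)
    if (length(idx) == 0) stop_domain("unknown population: ", pop)
    kinetic_params(true$kinetics$k_on[, idx, drop = FALSE],
                   true$kinetics$k_off[, idx, drop = FALSE],
                   true$kinetics$s[, idx, drop = FALSE])
  }
  de_ground_truth(true$effects, true$evfs$diff_mask, pick(pop_a),
                  pick(pop_b), lfc_threshold)
}

#' Probability of sampling at least x cells from a rare population
#'
#' Binomial tail `1 - sum_{k<x} C(N,k) r^k (1-r)^(N-k)`: the chance that a
#' sample of `N` cells contains at least `x` cells of a population of
#' proportion `r`, assuming every sequenced cell is assigned correctly.
#'
#' @param N Total cells sequenced.
#' @param r Population proportion in (0, 1).
#' @param x Minimum number of cells required (default 50).
#' @return Probability; 1 when `x <= 0`, 0 when `x > N`.
#' @export
detection_probability <- function(N, r, x = 50) {
  check_range(r, "r", 0, 1, lo_open = TRUE, hi_open = TRUE)
  stopifnot(N >= 0)
  ifelse(x <= 0, 1, ifelse(x > N, 0, pbinom(x - 1, N, r, lower.tail = FALSE)))
}

#' Minimal number of cells achieving a target detection probability
#'
#' Smallest `N` with `detection_probability(N, r, x) >= target_prob`;
#' the probability is non-decreasing in `N`, so bisection applies.
#'
#' @param r Rare-population proportion in (0, 1).
#' @param x Minimum cells required from the population.
#' @param target_prob Target probability in (0, 1).
#' @return Integer `N`.
#' @examples
#' min_cells_for_success(r = 0.05, x = 50, target_prob = 0.9)
#' @export
min_cells_for_success <- function(r, x, target_prob) {
  check_range(r, "r", 0, 1, lo_open = TRUE, hi_open = TRUE)
  if (target_prob >= 1 || target_prob <= 0) {
    stop_domain("'target_prob' must lie in (0, 1)")
  }
  lo <- x
  hi <- max(x, ceiling(x / r))
  while (detection_probability(hi, r, x) < target_prob) hi <- hi * 2
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (detection_probability(mid, r, x) >= target_prob) hi <- mid
    else lo <- mid + 1
  }
  as.integer(lo)
}

#' Was a rare population detected by a clustering?
#'
#' TRUE when some cluster contains at least `x` cells of the rare
#' population and those cells make up at least `min_precision` of that
#' cluster.
#'
#' @param cluster_labels Cluster assignment per cell.
#' @param true_labels True population per cell (same order).
#' @param rare_id The rare population's label.
#' @param x Minimum rare cells in one cluster (default 50).
#' @param min_precision Minimum fraction of the cluster that is rare
#'   (default 0.7).
#' @return Logical.
#' @export
rare_pop_detected <- function(cluster_labels, true_labels, rare_id, x = 50,
                              min_precision = 0.7) {
  if (length(cluster_labels) != length(true_labels)) {
    stop_domain("label vectors must be aligned")
  }
  if (!rare_id %in% true_labels) stop_domain("unknown population: ", rare_id)
  for (cl in unique(cluster_labels)) {
    in_cl <- cluster_labels == cl
    n_rare <- sum(in_cl & true_labels == rare_id)
    if (n_rare >= x && n_rare / sum(in_cl) >= min_precision) return(TRUE)
  }
  FALSE
}

#' Empirical rare-population detection rate under a clustering method
#'
#' A small harness: for each replicate, simulates true and observed counts
#' with a rare population of proportion `r`, clusters the observed counts
#' with a user-supplied callable, and applies the [rare_pop_detected()]
#' criterion. Any clustering function `f(counts, k)` returning per-cell
#' labels can be plugged in (default: k-means on the top principal
#' components of log counts).
#'
#' @param n_cells Cells per replicate.
#' @param r Rare-population proportion.
#' @param config,tech Simulation settings ([sim_config()], [tech_params()]).
#' @param tree State tree; the rare population is its first leaf unless
#'   `rare_id` is given.
#' @param rare_id Rare population label.
#' @param cluster_fun Clustering callable `function(counts, k)`.
#' @param n_rep Number of replicates.
#' @param x,min_precision Detection criterion (defaults 50 cells, 0.7).
#' @param seed Seed.
#' @return Fraction of replicates in which the population was detected.
#' @export
rare_pop_detection_rate <- function(n_cells, r, config = sim_config(),
                                    tech = tech_params(), tree = NULL,
                                    rare_id = NULL,
                                    cluster_fun = pca_kmeans_cluster,
                                    n_rep = 10, x = 50, min_precision = 0.7,
                                    seed = 1) {
  if (is.null(tree)) tree <- example_tree()
  if (is.null(rare_id)) rare_id <- tree$tip.label[1]
  n_tip <- ape::Ntip(tree)
  n_rare <- round(r * n_cells)
  per_pop <- rep((n_cells - n_rare) %/% (n_tip - 1), n_tip)
  per_pop[match(rare_id, tree$tip.label)] <- n_rare
  hits <- vapply(seq_len(n_rep), function(i) {
    cfg <- config
    cfg$seed <- substream_seed(seed, sprintf("design_rep_%d", i))
    cfg$cells_per_population <- per_pop
    tc <- simulate_true_counts(cfg, tree = tree)
    obs <- simulate_observed_counts(tc, tech, seed = cfg$seed)
    cl <- cluster_fun(obs$counts, n_tip)
    rare_pop_detected(cl, tc$meta$population, rare_id, x, min_precision)
  }, logical(1))
  mean(hits)
}

#' Default clustering callable: k-means on principal components
#'
#' @param counts Genes x cells matrix.
#' @param k Number of clusters.
#' @param n_pc Number of principal components (default 10).
#' @return Integer cluster label per cell.
#' @export
pca_kmeans_cluster <- function(counts, k, n_pc = 10) {
  x <- t(log1p(counts))
  pc <- stats::prcomp(x, rank. = min(n_pc, ncol(x), nrow(x) - 1))$x
  stats::kmeans(pc, centers = k, nstart = 5)$cluster
}

#' Per-gene fractional change in total transcripts between two settings
#'
#' For each gene, `(sum_j x_j - sum_j x'_j) / sum_j x_j` where `x` and `x'`
#' are the gene's counts under two simulations (e.g. bimod = 0 vs 1). A
#' zero denominator yields NA.
#'
#' @param counts_a,counts_b Matched genes x cells matrices.
#' @return Numeric per-gene fractional change.
#' @export
bimod_expression_change <- function(counts_a, counts_b) {
  if (nrow(counts_a) != nrow(counts_b)) {
    stop_domain("gene panels must match")
  }
  tot_a <- rowSums(counts_a); tot_b <- rowSums(counts_b)
  out <- (tot_a - tot_b) / tot_a
  out[tot_a == 0] <- NA_real_
  out
}
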