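# Expression program: EVFs x gene effects -> kinetic parameters -> counts.
#
# Raw per-gene, per-cell parameter values are dot products of the cell's EVF
# vector and the gene's sparse effect vector; they are then rank-mapped onto
# reference distributions of biologically plausible kinetic parameters, so
# only the ordering of the dot products matters, not their scale.

#' Sample sparse gene-effect matrices
#'
#' Draws one genes x n_evf coefficient matrix per kinetic parameter. Entries
#' are iid `N(0, gene_effects_sd)` and are independently zeroed with
#' probability `eta`, so each gene responds to a small subset of EVFs.
#'
#' @param n_genes Number of genes.
#' @param n_evf Number of EVFs per kinetic parameter.
#' @param eta Zeroing probability in \[0, 1\] (default 0.7).
#' @param gene_effects_sd Standard deviation of non-zero entries (default 1).
#' @return An object of class `gene_effects`: list of three matrices named
#'   `k_on`, `k_off`, `s`, with attributes `eta` and `gene_effects_sd`.
#' @export
sample_gene_effects <- function(n_genes, n_evf, eta = 0.7,
                                gene_effects_sd = 1) {
  stopifnot(n_genes >= 1, n_evf >= 1)
  check_range(eta, "eta", 0, 1)
  check_positive(gene_effects_sd, "gene_effects_sd")
  mats <- lapply(1:3, function(param) {
    m <- matrix(rnorm(n_genes * n_evf, 0, gene_effects_sd), n_genes, n_evf)
    m[runif(n_genes * n_evf) < eta] <- 0
    dimnames(m) <- list(sprintf("gene%d", seq_len(n_genes)),
                        sprintf("evf%d", seq_len(n_evf)))
    m
  })
  names(mats) <- c("k_on", "k_off", "s")
  structure(mats, eta = eta, gene_effects_sd = gene_effects_sd,
            class = "gene_effects")
}

#' Raw kinetic-parameter values as EVF/effect dot products
#'
#' `raw[g, c] = sum_j effects[g, j] * evf[c, j]`.
#'
#' @param evf_matrix Cells x n_evf EVF matrix.
#' @param effect_matrix Genes x n_evf gene-effect matrix.
#' @return Genes x cells numeric matrix.
#' @export
raw_params <- function(evf_matrix, effect_matrix) {
  if (ncol(evf_matrix) != ncol(effect_matrix)) {
    stop_domain("EVF and gene-effect matrices must agree on the number of EVFs")
  }
  effect_matrix %*% t(evf_matrix)
}

#' Rank-map raw values onto a reference distribution
#'
#' Draws `length(raw)` values from the reference sample (with replacement),
#' then replaces the i-th ranked raw value with the i-th ranked reference
#' draw. Output values are therefore an exact multiset of reference draws,
#' strictly positive, and in the same rank order as the input (ties broken
#' stably by position, i.e. by gene then cell index for a matrix).
#'
#' @param raw Numeric matrix (or vector) of raw dot-product values.
#' @param reference Numeric vector of strictly positive reference samples.
#' @return Object of the same shape as `raw` with mapped values.
#' @examples
#' quantile_map(c(3, 1, 2), c(10, 20, 30))
#' @export
quantile_map <- function(raw, reference) {
  if (length(reference) == 0) stop_domain("reference sample is empty")
  check_positive(reference, "reference")
  draws <- sort(sample(reference, length(raw), replace = TRUE))
  out <- raw
  out[order(raw)] <- draws  # order() is stable: ties keep position order
  out
}

#' Build matched kinetic parameters from EVFs, effects and references
#'
#' Applies [raw_params()] and [quantile_map()] per kinetic parameter.
#'
#' @param evfs An `evf_set` from [sample_evfs()].
#' @param effects A `gene_effects` object from [sample_gene_effects()].
#' @param reference A data.frame with columns `k_on`, `k_off`, `s`
#'   (see [default_kinetic_reference()]).
#' @return A [kinetic_params] object (genes x cells).
#' @export
match_kinetic_params <- function(evfs, effects, reference) {
  stopifnot(inherits(evfs, "evf_set"), inherits(effects, "gene_effects"))
  ref <- validate_reference(reference)
  mats <- lapply(c("k_on", "k_off", "s"), function(p) {
    quantile_map(raw_params(evfs$evf[[p]], effects[[p]]), ref[[p]])
  })
  kinetic_params(mats[[1]], mats[[2]], mats[[3]])
}

validate_reference <- function(reference) {
  reference <- as.data.frame(reference)
  need <- c("k_on", "k_off", "s")
  if (!all(need %in% names(reference))) {
    stop_domain("reference distributions need columns k_on, k_off, s")
  }
  for (p in need) check_positive(reference[[p]], p)
  if (nrow(reference) < 2) stop_domain("reference sample is too small")
  reference[need]
}

#' Simulate true transcript counts
#'
#' Runs the full generative program for true (pre-library) counts:
#' EVF sampling on the tree, sparse gene effects, dot products, rank-mapping
#' onto the reference kinetic-parameter distributions, cell-size scaling of
#' `s` by `scale_s`, the `bimod` adjustment of the switching rates,
#' high-expression outlier designation, and one Beta-Poisson draw per gene
#' and cell.
#'
#' @param config A [sim_config()] list (only the true-count fields are
#'   used: `n_genes`, `n_cells`, `mode`, `sigma`, `n_evf`, `n_diff_evf`,
#'   `eta`, `gene_effects_sd`, `bimod`, `scale_s`, `prop_hge`, `mean_hge`,
#'   `seed`, `impulse`, `cells_per_population`).
#' @param tree A [read_state_tree()] tree; defaults to the packaged
#'   five-population example tree.
#' @param reference Reference kinetic-parameter samples (data.frame with
#'   columns `k_on`, `k_off`, `s`); defaults to the packaged synthetic set.
#' @return An object of class `true_counts`: list with `counts` (genes x
#'   cells integer matrix), `kinetics` ([kinetic_params]), `evfs`
#'   (`evf_set`), `effects` (`gene_effects`), `meta` (cell metadata),
#'   `outlier_mask` and `config`.
#' @examples
#' cfg <- sim_config(n_genes = 50, n_cells = 40, seed = 1)
#' tc <- simulate_true_counts(cfg)
#' dim(tc$counts)
#' @export
simulate_true_counts <- function(config = sim_config(), tree = NULL,
                                 reference = NULL) {
  config <- validate_config(config)
  if (is.null(tree)) {
    tree <- if (is.null(config$tree_path)) example_tree() else
      read_state_tree(config$tree_path)
  }
  if (is.null(reference)) {
    reference <- if (is.null(config$reference_path))
      default_kinetic_reference() else
      read.delim(config$reference_path)
  }
  reference <- validate_reference(reference)
  seed <- config$seed

  evfs <- with_stage_seed(seed, "evf",
    sample_evfs(tree, mode = config$mode, n_cells = config$n_cells,
                cells_per_population = config$cells_per_population,
                sigma = config$sigma, n_evf = config$n_evf,
                n_diff_evf = config$n_diff_evf, impulse = config$impulse))
  effects <- with_stage_seed(seed, "gene_effects",
    sample_gene_effects(config$n_genes, config$n_evf, eta = config$eta,
                        gene_effects_sd = config$gene_effects_sd))
  kin <- with_stage_seed(seed, "quantile_map",
    match_kinetic_params(evfs, effects, reference))
  kin$s <- kin$s * config$scale_s
  kin <- apply_bimod(kin, config$bimod)
  kin <- with_stage_seed(seed, "outliers",
    apply_expression_outliers(kin, config$prop_hge, config$mean_hge))
  counts <- with_stage_seed(seed, "true_counts", sample_kinetic_counts(kin))
  dimnames(counts) <- list(rownames(effects$k_on), evfs$meta$cell_id)

  structure(list(counts = counts, kinetics = kin, evfs = evfs,
                 effects = effects, meta = evfs$meta,
                 outlier_mask = attr(kin, "outlier_mask"),
                 config = config),
            class = "true_counts")
}

#' @exportS3Method base::print
print.true_counts <- function(x, ...) {
  cat(sprintf("True counts: %d genes x %d cells (%s mode, %d populations)\n",
              nrow(x$counts), ncol(x$counts), x$evfs$mode,
              length(unique(x$meta$population))))
  cat(sprintf("  mean count %.2f, %.1f%% zeros, %d outlier genes\n",
              mean(x$counts), 100 * mean(x$counts == 0),
              sum(x$outlier_mask)))
  invisible(x)
}
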