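# Configuration, file formats and packaged fixtures.

sim_config_defaults <- function() {
  list(n_genes = 500, n_cells = 300,
       mode = "discrete", sigma = 0.5, n_evf = 20, n_diff_evf = 4,
       eta = 0.7, gene_effects_sd = 1, bimod = 0, scale_s = 1,
       prop_hge = 0.015, mean_hge = 5,
       cells_per_population = NULL, impulse = list(), seed = NULL,
       tree_path = NULL, gene_lengths_path = NULL, reference_path = NULL)
}

#' Simulation configuration for true counts
#'
#' Collects and validates the biological knobs of the generative model.
#' Defaults mirror a typical multi-population study: 20 EVFs per kinetic
#' parameter of which 4 are Diff-EVFs, within-population SD `sigma = 0.5`,
#' gene-effect sparsity `eta = 0.7`, and a small fraction (1.5%) of
#' high-expression outlier genes.
#'
#' @param ... Any of: `n_genes`, `n_cells`, `mode`
#'   (`"discrete"`/`"continuous"`/`"impulse"`), `sigma`, `n_evf`,
#'   `n_diff_evf`, `eta`, `gene_effects_sd`, `bimod`, `scale_s`,
#'   `prop_hge`, `mean_hge`, `cells_per_population`, `impulse`, `seed`,
#'   `tree_path`, `gene_lengths_path`, `reference_path`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(...) {
  args <- list(...)
  defaults <- sim_config_defaults()
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) {
    stop_domain("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
  }
  config <- modifyList(defaults, args, keep.null = TRUE)
  validate_config(config)
}

#' @rdname sim_config
#' @param config A list of configuration values to validate.
#' @export
validate_config <- function(config) {
  config <- modifyList(sim_config_defaults(), as.list(config),
                       keep.null = TRUE)
  stopifnot(config$n_genes >= 1, config$n_cells >= 1)
  if (!config$mode %in% c("discrete", "continuous", "impulse")) {
    stop_domain("'mode' must be discrete, continuous or impulse")
  }
  if (config$sigma < 0) stop_domain("'sigma' must be >= 0")
  stopifnot(config$n_evf >= 1)
  if (config$n_diff_evf < 0 || config$n_diff_evf > config$n_evf) {
    stop_domain("'n_diff_evf' must lie in [0, n_evf]")
  }
  check_range(config$eta, "eta", 0, 1)
  check_positive(config$gene_effects_sd, "gene_effects_sd")
  check_range(config$bimod, "bimod", 0, 1)
  check_positive(config$scale_s, "scale_s")
  check_range(config$prop_hge, "prop_hge", 0, 1, hi_open = TRUE)
  if (config$prop_hge > 0 && config$mean_hge <= 1) {
    stop_domain("'mean_hge' must be > 1")
  }
  structure(config, class = "sim_config")
}

tech_param_names <- function() names(formals(tech_params))

#' Load a full simulation configuration from a YAML or JSON file
#'
#' The file may mix biological ([sim_config()]) and technical
#' ([tech_params()]) keys at the top level; unknown keys are rejected by
#' name. Missing keys take their documented defaults, so an empty file
#' yields the default configuration.
#'
#' @param path Path of a `.yaml`/`.yml` or `.json` file.
#' @return List of class `burstsim_config` with elements `sim`
#'   (a `sim_config`) and `tech` (a `tech_params`).
#' @export
load_sim_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sim_keys <- names(sim_config_defaults())
  tech_keys <- setdiff(tech_param_names(), "...")
  unknown <- setdiff(names(raw), c(sim_keys, tech_keys))
  if (length(unknown)) {
    stop_domain("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
  }
  sim <- do.call(sim_config, raw[intersect(names(raw), sim_keys)])
  tech <- do.call(tech_params, raw[intersect(names(raw), tech_keys)])
  structure(list(sim = sim, tech = tech), class = "burstsim_config")
}

#' Save a full simulation configuration
#'
#' @param config A `burstsim_config` (see [load_sim_config()]) or
#'   `sim_config`.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
save_sim_config <- function(config, path) {
  vals <- if (inherits(config, "burstsim_config")) {
    c(unclass(config$sim), unclass(config$tech))
  } else {
    unclass(config)
  }
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write a count matrix with sidecar metadata tables
#'
#' Counts go to Matrix Market (`<prefix>.mtx`, sparse, 1-based indices) or
#' dense TSV (`<prefix>.tsv`); cell and gene metadata go to
#' `<prefix>_cells.tsv` and `<prefix>_genes.tsv`. Integer counts round-trip
#' losslessly through [read_counts()].
#'
#' @param counts Genes x cells matrix.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"counts"`).
#' @param cell_meta,gene_meta Optional data.frames with one row per cell /
#'   gene.
#' @param format `"mtx"` or `"tsv"`.
#' @return The directory, invisibly.
#' @export
write_counts <- function(counts, dir, prefix = "counts", cell_meta = NULL,
                         gene_meta = NULL, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (!is.null(cell_meta) && nrow(cell_meta) != ncol(counts)) {
    stop_domain("cell_meta rows must match the number of cells")
  }
  if (!is.null(gene_meta) && nrow(gene_meta) != nrow(counts)) {
    stop_domain("gene_meta rows must match the number of genes")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                    file.path(dir, paste0(prefix, ".mtx")))
  } else {
    write.table(as.matrix(counts), file.path(dir, paste0(prefix, ".tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(cell_meta)) {
    write.table(cell_meta, file.path(dir, paste0(prefix, "_cells.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(gene_meta)) {
    write.table(gene_meta, file.path(dir, paste0(prefix, "_genes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix written by [write_counts()] (or any MTX/TSV matrix)
#'
#' @param path Path of a `.mtx` or `.tsv` counts file, or of a directory
#'   containing `<prefix>.mtx`/`<prefix>.tsv`.
#' @param prefix Prefix used when `path` is a directory.
#' @return List with `counts` (base matrix) and, when present, `cell_meta`
#'   and `gene_meta`.
#' @export
read_counts <- function(path, prefix = "counts") {
  if (dir.exists(path)) {
    base <- file.path(path, prefix)
    file <- if (file.exists(paste0(base, ".mtx"))) paste0(base, ".mtx")
            else paste0(base, ".tsv")
  } else file <- path
  if (!file.exists(file)) stop_domain("no counts found at: ", path)
  counts <- if (grepl("\\.mtx$", file)) {
    as.matrix(Matrix::readMM(file))
  } else {
    as.matrix(read.delim(file, row.names = 1, check.names = FALSE))
  }
  out <- list(counts = counts)
  side <- function(suffix) {
    f <- sub("\\.(mtx|tsv)$", paste0("_", suffix, ".tsv"), file)
    if (file.exists(f)) read.delim(f, stringsAsFactors = FALSE) else NULL
  }
  out$cell_meta <- side("cells")
  out$gene_meta <- side("genes")
  out
}

# Packaged fixtures --------------------------------------------------------

burstsim_file <- function(name) {
  path <- system.file("extdata", name, package = "burstsim")
  if (path == "") stop_domain("packaged file not found: ", name)
  path
}

#' Packaged example cell-state tree
#'
#' A five-population tree (leaves "1".."5") in which populations 2 and 4
#' are sibling leaves and population 1 is their outgroup, suitable for
#' discrete, continuous and DE-hierarchy examples. Branch lengths are
#' illustrative squared-EVF units, not estimates from data.
#'
#' @return A `state_tree` object.
#' @export
example_tree <- function() {
  read_state_tree(burstsim_file("tree_5pop.nwk"))
}

#' Packaged synthetic gene-length table
#'
#' Log-normally distributed transcript lengths (bp) with a human-like
#' median around 2 kb; a synthetic stand-in for reference-genome transcript
#' lengths. With `n` genes requested the first rows are recycled, keeping
#' gene identities deterministic.
#'
#' @param n Optional number of genes.
#' @return Integer vector of lengths (all rows when `n` is NULL).
#' @export
default_gene_lengths <- function(n = NULL) {
  tab <- read.delim(burstsim_file("gene_lengths_synthetic.tsv"))
  len <- tab$length
  if (is.null(n)) len else rep_len(len, n)
}

#' Packaged synthetic reference kinetic-parameter distributions
#'
#' Strictly positive log-normal samples of `k_on`, `k_off` and `s`
#' (relative to degradation rate 1) spanning the ranges reported for
#' mammalian genes; synthetic stand-ins for distributions estimated from
#' real data, and replaceable by any user table or by
#' [aggregate_posteriors()] output.
#'
#' @return data.frame with columns `k_on`, `k_off`, `s`.
#' @export
default_kinetic_reference <- function() {
  read.delim(burstsim_file("kinetic_reference_synthetic.tsv"))
}
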