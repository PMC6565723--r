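# Calibration of simulation parameters to a target count matrix: simulate
# a database over a grid of parameter configurations, summarise each
# simulated dataset by per-gene statistics, and return the configuration
# whose statistic distributions are closest to the target's.

#' Per-gene summary statistics of a count matrix
#'
#' @param counts Non-negative genes x cells matrix.
#' @return An object of class `summary_stats`: list of per-gene vectors
#'   `mean`, `pct_nonzero` (0-100) and `sd` (sample SD over cells).
#' @export
count_summary_stats <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0) stop_domain("count matrix is empty")
  if (any(counts < 0)) stop_domain("counts must be non-negative")
  structure(list(mean = rowMeans(counts),
                 pct_nonzero = 100 * rowMeans(counts > 0),
                 sd = apply(counts, 1, sd)),
            class = "summary_stats")
}

#' Distance between two summary-statistic sets
#'
#' Sums, over the three per-gene statistics (mean, percent non-zero, SD),
#' the mean absolute difference between `n_quantiles` evenly spaced
#' quantiles of the two per-gene distributions. Comparing quantile profiles
#' makes the distance independent of the two datasets' gene counts. To keep
#' the three statistics commensurable, mean and SD quantiles are compared
#' on the log1p scale and percent non-zero as a fraction, so each
#' contribution is O(1) and no single heavy-tailed statistic dominates.
#' The distance is non-negative, symmetric, and zero only for identical
#' quantile profiles.
#'
#' @param a,b `summary_stats` objects.
#' @param n_quantiles Number of probes (default 100).
#' @return A single non-negative number.
#' @export
stats_distance <- function(a, b, n_quantiles = 100) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  probs <- seq(0, 1, length.out = n_quantiles)
  trans <- list(mean = log1p, pct_nonzero = function(x) x / 100,
                sd = log1p)
  sum(vapply(c("mean", "pct_nonzero", "sd"), function(stat) {
    mean(abs(quantile(trans[[stat]](a[[stat]]), probs, na.rm = TRUE) -
             quantile(trans[[stat]](b[[stat]]), probs, na.rm = TRUE)))
  }, numeric(1)))
}

#' Reduced default calibration grids
#'
#' Desk-scale subsets (3-4 values per axis on the most influential axes) of
#' the full UMI / non-UMI calibration ranges; any data.frame of
#' configuration columns can be supplied to [build_sim_database()] instead.
#'
#' @param protocol `"UMI"` or `"nonUMI"`.
#' @return data.frame with one row per grid configuration.
#' @export
default_calibration_grid <- function(protocol = c("UMI", "nonUMI")) {
  protocol <- match.arg(protocol)
  # capture efficiency and within-population spread have distinct
  # statistical signatures (dropout/mean level vs cross-cell SD); the cell
  # size factor scale_s is omitted because observed counts depend on
  # alpha and scale_s almost exclusively through their product, so the
  # pair is not separately identifiable from count statistics
  if (protocol == "UMI") {
    expand.grid(alpha_mean = c(0.01, 0.04, 0.1),
                sigma = c(0.2, 0.4, 0.6),
                depth_mean = c(45000, 150000),
                KEEP.OUT.ATTRS = FALSE)
  } else {
    expand.grid(alpha_mean = c(0.05, 0.15, 0.25),
                sigma = c(0.1, 0.2, 0.6),
                depth_mean = c(1e5, 1e6),
                KEEP.OUT.ATTRS = FALSE)
  }
}

apply_config_row <- function(config, tech, row) {
  row <- as.list(row)
  for (nm in names(row)) {
    if (nm %in% names(tech)) tech[[nm]] <- row[[nm]]
    else if (nm %in% names(config)) config[[nm]] <- row[[nm]]
    else stop_domain("unknown grid parameter: ", nm)
  }
  list(config = config, tech = tech)
}

#' Build a database of simulated datasets over a parameter grid
#'
#' Runs one full simulation (true counts then observed counts) per grid
#' row, summarises each with [count_summary_stats()], and optionally
#' persists the database as JSON configuration records plus TSV statistics.
#' When `dir` already holds entries with matching names they are reloaded
#' instead of re-simulated, so an interrupted build resumes.
#'
#' @param grid data.frame of configuration columns; names must be
#'   [sim_config()] or [tech_params()] fields.
#' @param config Base [sim_config()] shared by all entries.
#' @param tech Base [tech_params()] shared by all entries.
#' @param dir Optional directory for persistence.
#' @param seed Seed; entry i runs on sub-stream `"db_entry_i"`.
#' @return An object of class `sim_database`: list with `grid` and `stats`
#'   (list of `summary_stats`). Invalid configurations are skipped with a
#'   warning and carry `NULL` stats.
#' @export
build_sim_database <- function(grid, config = sim_config(),
                               tech = tech_params(), dir = NULL, seed = 1) {
  grid <- unique(as.data.frame(grid))
  if (nrow(grid) == 0) stop_domain("empty calibration grid")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.table(grid, file.path(dir, "grid.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  stats <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    stat_file <- if (is.null(dir)) NULL else
      file.path(dir, sprintf("entry%03d_stats.tsv", i))
    if (!is.null(stat_file) && file.exists(stat_file)) {
      d <- read.delim(stat_file)
      stats[[i]] <- structure(as.list(d), class = "summary_stats")
      next
    }
    entry <- tryCatch({
      cfgs <- apply_config_row(config, tech, grid[i, , drop = FALSE])
      cfgs$config$seed <- substream_seed(seed, sprintf("db_entry_%d", i))
      tc <- simulate_true_counts(cfgs$config)
      obs <- simulate_observed_counts(tc, cfgs$tech,
                                      seed = cfgs$config$seed)
      count_summary_stats(obs$counts)
    }, error = function(e) {
      warning(sprintf("grid entry %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    stats[[i]] <- entry
    if (!is.null(stat_file) && !is.null(entry)) {
      write.table(as.data.frame(unclass(entry)), stat_file, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(as.list(grid[i, , drop = FALSE]),
                           file.path(dir, sprintf("entry%03d_config.json", i)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  structure(list(grid = grid, stats = stats), class = "sim_database")
}

#' Load a persisted simulation database
#'
#' @param dir Directory written by [build_sim_database()].
#' @return A `sim_database` object.
#' @export
load_sim_database <- function(dir) {
  grid_file <- file.path(dir, "grid.tsv")
  if (!file.exists(grid_file)) stop_domain("no database found in: ", dir)
  grid <- read.delim(grid_file)
  stats <- lapply(seq_len(nrow(grid)), function(i) {
    f <- file.path(dir, sprintf("entry%03d_stats.tsv", i))
    if (!file.exists(f)) return(NULL)
    structure(as.list(read.delim(f)), class = "summary_stats")
  })
  structure(list(grid = grid, stats = stats), class = "sim_database")
}

#' Find the database entry closest to a target dataset
#'
#' @param target A `summary_stats` object (or a count matrix, which is
#'   summarised first).
#' @param database A [build_sim_database()] result.
#' @return List with `config` (the best grid row), `distance`, `index`,
#'   and `distances` (all entries; ties broken by grid order).
#' @export
match_parameters <- function(target, database) {
  stopifnot(inherits(database, "sim_database"))
  if (!inherits(target, "summary_stats")) {
    target <- count_summary_stats(target)
  }
  ok <- !vapply(database$stats, is.null, logical(1))
  if (!any(ok)) stop_domain("database has no usable entries")
  d <- rep(Inf, length(database$stats))
  d[ok] <- vapply(which(ok), function(i) {
    stats_distance(target, database$stats[[i]])
  }, numeric(1))
  best <- which.min(d)  # first minimum: deterministic tie-break
  list(config = database$grid[best, , drop = FALSE], distance = d[best],
       index = best, distances = d)
}
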