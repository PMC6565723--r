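# Library preparation and sequencing: true molecules -> observed counts.
#
# Explicitly simulated steps: mRNA capture (Binomial thinning with per-cell
# efficiency), pre-amplification (per-cycle stochastic duplication with
# gene-length-biased rates, or linear IVT), fragmentation with size
# selection, post-fragmentation PCR, sequencing (reads drawn without
# replacement from the fragment pool), read/UMI counting, and
# multiplicative batch effects. Reverse transcription and library clean-up
# are deliberately not modelled, and reads are assumed error-free and
# perfectly assigned to genes.

#' Technical (library preparation) parameters
#'
#' Validated container of all knobs for [simulate_observed_counts()].
#'
#' @param protocol `"UMI"` (3' tag counting with molecule collapsing) or
#'   `"nonUMI"` (full-length read counting).
#' @param alpha_mean,alpha_sd Mean and cross-cell SD of the mRNA capture
#'   efficiency; each cell's efficiency is drawn from a normal distribution
#'   truncated to (0, 1\].
#' @param rate_2PCR Basal per-cycle PCR amplification probability in (0, 1\]
#'   (the across-gene average rate; default 0.7).
#' @param nPCR1 Pre-amplification PCR cycles (default 14 for `"nonUMI"`,
#'   10 for `"UMI"`).
#' @param nPCR2 Post-fragmentation PCR cycles (default 10).
#' @param linear_amp Use linear in-vitro-transcription amplification in the
#'   pre-amplification step instead of PCR (CEL-seq style).
#' @param linear_amp_rounds IVT rounds when `linear_amp = TRUE`.
#' @param lenslope,MaxAmpBias,nbins Amplification length-bias controls:
#'   genes are binned into `nbins` length bins and the per-cycle rate of bin
#'   i is offset by `lenslope * ((nbins + 1)/2 - i)`, plus a per-gene random
#'   offset `N(0, MaxAmpBias - lenslope*(nbins-1)/2)`. Requires
#'   `lenslope < 2 * MaxAmpBias / (nbins - 1)`.
#' @param depth_mean,depth_sd Mean and SD of the per-cell number of
#'   sequenced reads (fragments).
#' @param frag_len_mean Target mean fragment length in bp (default 400).
#' @param frag_size_window Size-selection window in bp (default 100-1000).
#' @param n_batches,batch_factor_sd Number of batches and the log2-scale SD
#'   of the multiplicative gene-by-batch factors.
#' @param seq_method `"auto"` (exact without-replacement sampling unless the
#'   fragment pool exceeds 100x the depth or the integer range, then
#'   multinomial), `"hypergeometric"`, or `"multinomial"`.
#' @return A list of class `tech_params`.
#' @export
tech_params <- function(protocol = c("UMI", "nonUMI"),
                        alpha_mean = 0.1, alpha_sd = 0.01,
                        rate_2PCR = 0.7, nPCR1 = NULL, nPCR2 = 10,
                        linear_amp = FALSE, linear_amp_rounds = 14,
                        lenslope = 0.023, MaxAmpBias = 0.3, nbins = 20,
                        depth_mean = 1e5, depth_sd = 1e4,
                        frag_len_mean = 400, frag_size_window = c(100, 1000),
                        n_batches = 1, batch_factor_sd = 0,
                        seq_method = c("auto", "hypergeometric", "multinomial")) {
  protocol <- match.arg(protocol)
  seq_method <- match.arg(seq_method)
  # tag-counting protocols run fewer pre-amplification cycles than
  # full-length ones
  if (is.null(nPCR1)) nPCR1 <- if (protocol == "UMI") 10 else 14
  check_range(alpha_mean, "alpha_mean", 0, 1, lo_open = TRUE)
  if (alpha_sd < 0) stop_domain("'alpha_sd' must be >= 0")
  check_range(rate_2PCR, "rate_2PCR", 0, 1, lo_open = TRUE)
  stopifnot(nPCR1 >= 0, nPCR2 >= 0, nbins >= 2, linear_amp_rounds >= 1)
  if (lenslope < 0) stop_domain("'lenslope' must be >= 0")
  if (MaxAmpBias < 0) stop_domain("'MaxAmpBias' must be >= 0")
  if (lenslope >= 2 * MaxAmpBias / (nbins - 1) && lenslope > 0) {
    stop_domain("'lenslope' must be smaller than 2*MaxAmpBias/(nbins - 1)")
  }
  if (depth_mean <= 0) stop_domain("'depth_mean' must be > 0")
  if (depth_sd < 0) stop_domain("'depth_sd' must be >= 0")
  if (length(frag_size_window) != 2 ||
      frag_size_window[1] >= frag_size_window[2] || frag_size_window[1] <= 0) {
    stop_domain("'frag_size_window' must be increasing positive (low, high)")
  }
  stopifnot(n_batches >= 1, batch_factor_sd >= 0, frag_len_mean > 0)
  structure(list(protocol = protocol, alpha_mean = alpha_mean,
                 alpha_sd = alpha_sd, rate_2PCR = rate_2PCR, nPCR1 = nPCR1,
                 nPCR2 = nPCR2, linear_amp = linear_amp,
                 linear_amp_rounds = linear_amp_rounds, lenslope = lenslope,
                 MaxAmpBias = MaxAmpBias, nbins = nbins,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 frag_len_mean = frag_len_mean,
                 frag_size_window = frag_size_window, n_batches = n_batches,
                 batch_factor_sd = batch_factor_sd, seq_method = seq_method),
            class = "tech_params")
}

#' Capture mRNA molecules with per-cell efficiency
#'
#' Each cell's capture efficiency is drawn once from
#' `N(alpha_mean, alpha_sd)` truncated to (0, 1\] and shared by all its
#' genes; each molecule is then retained independently with that
#' probability (Binomial thinning).
#'
#' @param true_counts Genes x cells matrix of true molecule counts.
#' @param alpha_mean,alpha_sd Capture efficiency mean and cross-cell SD.
#' @return List with `captured` (genes x cells matrix) and `alpha`
#'   (per-cell realised efficiency).
#' @export
capture_molecules <- function(true_counts, alpha_mean, alpha_sd) {
  check_range(alpha_mean, "alpha_mean", 0, 1, lo_open = TRUE)
  n_cells <- ncol(true_counts)
  alpha <- rnorm(n_cells, alpha_mean, alpha_sd)
  for (i in 1:100) {
    bad <- alpha <= 0 | alpha > 1
    if (!any(bad)) break
    alpha[bad] <- rnorm(sum(bad), alpha_mean, alpha_sd)
  }
  alpha <- pmin(pmax(alpha, 1e-6), 1)
  captured <- matrix(rbinom_big(as.vector(true_counts),
                                rep(alpha, each = nrow(true_counts))),
                     nrow = nrow(true_counts), dimnames = dimnames(true_counts))
  list(captured = captured, alpha = alpha)
}

#' Per-gene PCR amplification rates with length bias
#'
#' Genes are ranked by transcript length into `nbins` equal-occupancy bins.
#' The per-cycle amplification probability of a gene is the basal
#' `rate_2PCR` plus a deterministic length-bias term
#' `lenslope * ((nbins + 1)/2 - bin)` (shorter transcripts amplify better)
#' plus a random gene-specific term `N(0, MaxRandBias)` with
#' `MaxRandBias = MaxAmpBias - lenslope * (nbins - 1)/2`, clamped to
#' \[0, 1\].
#'
#' @param gene_lengths Transcript lengths in bp.
#' @param rate_2PCR Basal per-cycle amplification probability.
#' @param lenslope,MaxAmpBias,nbins Bias controls; requires
#'   `lenslope < 2 * MaxAmpBias / (nbins - 1)`.
#' @return Numeric vector of per-gene rates with attributes `bin`,
#'   `B_length` and `MaxRandBias`.
#' @export
amplification_rates <- function(gene_lengths, rate_2PCR = 0.7,
                                lenslope = 0.023, MaxAmpBias = 0.3,
                                nbins = 20) {
  check_positive(gene_lengths, "gene_lengths")
  check_range(rate_2PCR, "rate_2PCR", 0, 1, lo_open = TRUE)
  if (lenslope > 0 && lenslope >= 2 * MaxAmpBias / (nbins - 1)) {
    stop_domain("'lenslope' must be smaller than 2*MaxAmpBias/(nbins - 1)")
  }
  n <- length(gene_lengths)
  bin <- ceiling(nbins * rank(gene_lengths, ties.method = "first") / n)
  B_length <- lenslope * ((nbins + 1) / 2 - bin)
  MaxRandBias <- MaxAmpBias - lenslope * (nbins - 1) / 2
  B_rand <- rnorm(n, 0, MaxRandBias)
  rate <- pmin(pmax(rate_2PCR + B_length + B_rand, 0), 1)
  attributes(rate) <- list(bin = bin, B_length = B_length,
                           MaxRandBias = MaxRandBias)
  rate
}

#' Amplify a pool of molecules or fragments
#'
#' PCR mode: per cycle, every existing copy is duplicated with its
#' category's per-cycle rate, so a count x becomes `x + Binomial(x, rate)`
#' and the expectation grows as `(1 + rate)^cycles`. Linear (IVT) mode:
#' each copy deterministically yields `max(1, round(rate * rounds))`
#' transcripts with no exponential compounding.
#'
#' @param counts Numeric vector or matrix of copy counts (matrix rows are
#'   genes).
#' @param rates Per-category amplification rate, recycled along `counts`
#'   rows for a matrix.
#' @param cycles Number of PCR cycles (ignored in linear mode).
#' @param linear Use linear amplification.
#' @param rounds IVT rounds in linear mode.
#' @return Object of the same shape as `counts`.
#' @export
amplify_counts <- function(counts, rates, cycles, linear = FALSE,
                           rounds = 14) {
  if (any(rates < 0 | rates > 1)) stop_domain("rates must lie in [0, 1]")
  dm <- dim(counts); dn <- dimnames(counts)
  x <- as.vector(counts)
  r <- if (!is.null(dm)) rep_len(rates, length(x)) else
    rep_len(rates, length(x))
  if (linear) {
    x <- x * pmax(1, round(r * rounds))
  } else {
    for (i in seq_len(cycles)) x <- .pcr_cycle_cpp(x, r)
  }
  if (!is.null(dm)) { dim(x) <- dm; dimnames(x) <- dn }
  x
}

#' Fragment counts per transcript copy
#'
#' A copy of a transcript of length `l` is cut into
#' `K = 1 + Poisson(max(0, l - frag_len_mean) / frag_len_mean)` fragments
#' (uniform random breakpoints), so the expected fragment count is exactly
#' `l / frag_len_mean` for transcripts at least one mean fragment long and
#' the overall mean fragment length is calibrated to `frag_len_mean`.
#'
#' @param lengths Transcript length (bp) of each copy.
#' @param frag_len_mean Target mean fragment length (default 400 bp).
#' @return Integer-valued vector of per-copy fragment counts.
#' @export
fragment_copies <- function(lengths, frag_len_mean = 400) {
  check_positive(lengths, "lengths")
  1 + rpois_big(pmax(0, lengths - frag_len_mean) / frag_len_mean)
}

#' Mean fragment length over a pool of transcript copies
#'
#' Fragments the given copies with [fragment_copies()] and returns total
#' transcript length divided by total fragment count (before size
#' selection).
#'
#' @inheritParams fragment_copies
#' @return A single number (bp).
#' @export
mean_fragment_length <- function(lengths, frag_len_mean = 400) {
  sum(lengths) / sum(fragment_copies(lengths, frag_len_mean))
}

#' Probability that a fragment survives size selection
#'
#' Under uniform random breakpoints, the length of any one fragment (and of
#' the 3'-terminal fragment) of a copy cut into K pieces is
#' `l * Beta(1, K - 1)`; averaging over `K - 1 ~ Poisson(mu)` with
#' `mu = max(0, l - frag_len_mean)/frag_len_mean` gives the closed form
#' `exp(-mu * low/l) - exp(-mu * high/l)` (second term only when
#' `l > high`), and 0 when `l < low`.
#'
#' @param lengths Transcript lengths (bp).
#' @param frag_size_window Size-selection window `(low, high)` in bp.
#' @param frag_len_mean Mean fragment length used in [fragment_copies()].
#' @return Per-gene retention probability in \[0, 1\].
#' @export
fragment_retention_prob <- function(lengths, frag_size_window = c(100, 1000),
                                    frag_len_mean = 400) {
  check_positive(lengths, "lengths")
  lo <- frag_size_window[1]; hi <- frag_size_window[2]
  mu <- pmax(0, lengths - frag_len_mean) / frag_len_mean
  p <- exp(-mu * lo / lengths) -
    ifelse(lengths > hi, exp(-mu * hi / lengths), 0)
  p[lengths < lo] <- 0
  pmin(pmax(p, 0), 1)
}

#' Draw sequenced reads from a fragment pool
#'
#' Reads are physical fragments sampled without replacement, i.e. the
#' per-category read counts follow the multivariate hypergeometric law of
#' the pool. A multinomial approximation is used when the pool dwarfs the
#' depth (> 100x) or exceeds the integer range (`"auto"`), or on request.
#'
#' @param pool Per-category fragment counts (numeric vector).
#' @param depth Number of reads to draw.
#' @param method `"auto"`, `"hypergeometric"` or `"multinomial"`.
#' @return Per-category read counts; equal to `pool` when `depth` exceeds
#'   the pool size.
#' @export
sequence_pool <- function(pool, depth, method = "auto") {
  if (any(pool < 0)) stop_domain("pool counts must be >= 0")
  total <- sum(pool)
  if (depth <= 0) return(pool * 0)
  if (depth >= total) return(pool)
  exact <- method == "hypergeometric" ||
    (method == "auto" && total <= 2^31 - 1 && total <= 100 * depth)
  if (exact) {
    out <- .mvhyper_cpp(pool, depth)
  } else {
    out <- as.vector(rmultinom(1, depth, pool))
  }
  names(out) <- names(pool)
  out
}

#' Apply gene- and batch-specific multiplicative factors
#'
#' Cells are assigned to batches at random (as evenly as possible); counts
#' of gene g in batch b are multiplied by `2^N(0, batch_factor_sd)` drawn
#' once per (g, b), then rounded.
#'
#' @param observed An `observed_counts` object (or a plain counts matrix).
#' @param n_batches Number of batches.
#' @param batch_factor_sd Log2-scale SD of the factors.
#' @return The input with modified counts, batch labels in `cell_meta` and
#'   the factor matrix in `batch_factors`.
#' @export
add_batch_effects <- function(observed, n_batches = 1, batch_factor_sd = 0) {
  counts <- if (inherits(observed, "observed_counts")) observed$counts else observed
  n_cells <- ncol(counts); n_genes <- nrow(counts)
  batch <- sample(rep_len(seq_len(n_batches), n_cells))
  factors <- matrix(2^rnorm(n_genes * n_batches, 0, batch_factor_sd),
                    n_genes, n_batches)
  if (n_batches > 1 || batch_factor_sd > 0) {
    counts <- round(counts * factors[, batch, drop = FALSE])
  }
  if (inherits(observed, "observed_counts")) {
    observed$counts <- counts
    observed$cell_meta$batch <- batch
    observed$batch_factors <- factors
    observed
  } else {
    structure(counts, batch = batch, batch_factors = factors)
  }
}

#' Simulate observed read or UMI counts from true counts
#'
#' Composes the full library-preparation pipeline: capture,
#' pre-amplification, fragmentation and size selection, post-fragmentation
#' PCR, sequencing, read/UMI counting, and batch effects. For the UMI
#' protocol the identity of every captured molecule is tracked: only the
#' 3'-terminal fragment of each copy is kept for sequencing and all reads
#' from one original molecule collapse to a single UMI count, so UMI counts
#' can never exceed the number of captured molecules.
#'
#' @param true A `true_counts` object from [simulate_true_counts()], or a
#'   genes x cells matrix of true counts.
#' @param tech A [tech_params] object.
#' @param gene_lengths Per-gene transcript length (bp); defaults to the
#'   packaged synthetic gene-length table.
#' @param seed Optional integer seed; sub-seeds are derived per stage.
#' @return An object of class `observed_counts`: list with `counts`
#'   (reads for `"nonUMI"`, UMIs for `"UMI"`), `cell_meta` (`cell_id`,
#'   `alpha`, `depth`, `batch`), `gene_meta` (`gene_id`, `length`,
#'   `amp_rate`), `captured` (molecule counts after capture), `protocol`
#'   and `tech`.
#' @examples
#' tc <- simulate_true_counts(sim_config(n_genes = 40, n_cells = 20, seed = 1))
#' obs <- simulate_observed_counts(tc, tech_params("UMI", depth_mean = 5e4),
#'                                 seed = 1)
#' all(obs$counts <= tc$counts)
#' @export
simulate_observed_counts <- function(true, tech = tech_params(),
                                     gene_lengths = NULL, seed = NULL) {
  stopifnot(inherits(tech, "tech_params"))
  counts <- if (inherits(true, "true_counts")) true$counts else as.matrix(true)
  n_genes <- nrow(counts); n_cells <- ncol(counts)
  if (is.null(gene_lengths)) gene_lengths <- default_gene_lengths(n_genes)
  if (length(gene_lengths) != n_genes) {
    stop_domain("gene_lengths must have one entry per gene")
  }

  cap <- with_stage_seed(seed, "capture",
    capture_molecules(counts, tech$alpha_mean, tech$alpha_sd))
  rates <- with_stage_seed(seed, "amp_rates",
    amplification_rates(gene_lengths, tech$rate_2PCR, tech$lenslope,
                        tech$MaxAmpBias, tech$nbins))
  p_keep <- fragment_retention_prob(gene_lengths, tech$frag_size_window,
                                    tech$frag_len_mean)
  depth <- with_stage_seed(seed, "depth",
    pmax(0, round(rnorm(n_cells, tech$depth_mean, tech$depth_sd))))

  if (!is.null(seed)) set.seed(substream_seed(seed, "library"))
  mu_frag <- pmax(0, gene_lengths - tech$frag_len_mean) / tech$frag_len_mean

  if (tech$protocol == "nonUMI") {
    # molecule identity is irrelevant: track per (gene, cell) totals
    amp <- amplify_counts(cap$captured, rates, tech$nPCR1,
                          linear = tech$linear_amp,
                          rounds = tech$linear_amp_rounds)
    frag_tot <- amp + matrix(
      rpois_big(as.vector(amp * mu_frag)), n_genes, n_cells)
    retained <- matrix(rbinom_big(as.vector(frag_tot),
                                  rep(p_keep, n_cells)),
                       n_genes, n_cells)
    # gene-length bias acts on full-length cDNA; post-fragmentation PCR
    # amplifies short fragments at the basal rate
    frag <- amplify_counts(retained, rep(tech$rate_2PCR, n_genes),
                           tech$nPCR2)
    obs <- vapply(seq_len(n_cells), function(c) {
      sequence_pool(frag[, c], depth[c], tech$seq_method)
    }, numeric(n_genes))
  } else {
    # UMI: per-molecule bookkeeping; keep at most the 3' fragment per copy
    obs <- matrix(0, n_genes, n_cells)
    for (c in seq_len(n_cells)) {
      n_mol_g <- cap$captured[, c]
      if (sum(n_mol_g) == 0 || depth[c] == 0) next
      gene_idx <- rep(seq_len(n_genes), n_mol_g)
      copies <- rep(1, length(gene_idx))
      r_mol <- rates[gene_idx]
      if (tech$linear_amp) {
        copies <- copies * pmax(1, round(r_mol * tech$linear_amp_rounds))
      } else {
        for (i in seq_len(tech$nPCR1)) copies <- .pcr_cycle_cpp(copies, r_mol)
      }
      retained <- rbinom_big(copies, p_keep[gene_idx])
      r_frag <- rep(tech$rate_2PCR, length(retained))
      for (i in seq_len(tech$nPCR2)) retained <- .pcr_cycle_cpp(retained, r_frag)
      reads <- sequence_pool(retained, depth[c], tech$seq_method)
      obs[, c] <- tabulate(gene_idx[reads > 0], nbins = n_genes)
    }
  }
  obs <- matrix(obs, n_genes, n_cells, dimnames = dimnames(counts))

  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(n_genes))
  cell_ids <- colnames(counts)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%d", seq_len(n_cells))
  result <- structure(list(
    counts = obs,
    cell_meta = data.frame(cell_id = cell_ids, alpha = cap$alpha,
                           depth = depth, batch = 1L,
                           stringsAsFactors = FALSE),
    gene_meta = data.frame(gene_id = gene_ids, length = gene_lengths,
                           amp_rate = as.vector(rates),
                           stringsAsFactors = FALSE),
    captured = cap$captured, protocol = tech$protocol, tech = tech),
    class = "observed_counts")
  with_stage_seed(seed, "batch",
    add_batch_effects(result, tech$n_batches, tech$batch_factor_sd))
}

#' @exportS3Method base::print
print.observed_counts <- function(x, ...) {
  cat(sprintf("Observed %s counts: %d genes x %d cells\n",
              if (x$protocol == "UMI") "UMI" else "read",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  mean %.2f, %.1f%% zeros, mean capture %.3f, mean depth %.0f\n",
              mean(x$counts), 100 * mean(x$counts == 0),
              mean(x$cell_meta$alpha), mean(x$cell_meta$depth)))
  invisible(x)
}

#' Spearman correlation between gene length and mean expression
#'
#' For read counts (`"nonUMI"`), expression is length-normalised
#' (`counts / length`) before averaging, since full-length protocols yield
#' more fragments from longer transcripts; UMI counts count molecules and
#' are not length-normalised. With length-biased amplification the non-UMI
#' statistic is negative; UMI collapsing removes the bias.
#'
#' @param observed An `observed_counts` object.
#' @return Spearman correlation coefficient.
#' @export
length_bias_correlation <- function(observed) {
  stopifnot(inherits(observed, "observed_counts"))
  len <- observed$gene_meta$length
  expr <- if (observed$protocol == "nonUMI") observed$counts / len else
    observed$counts
  cor(len, rowMeans(expr), method = "spearman")
}
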