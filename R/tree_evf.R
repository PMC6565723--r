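# Cell-state manifold: extrinsic variability factors (EVFs) laid out by
# Brownian motion on a tree.
#
# Each cell carries one EVF vector per kinetic parameter. A small number of
# columns ("Diff-EVFs") have tree-position-dependent means obtained by
# Brownian motion from the root (value 1), so the expected absolute
# difference between two cells' Diff-EVF values grows with the square root
# of their tree distance. All remaining columns are iid N(1, sigma)
# regardless of position and carry no between-population signal.

#' Read and validate a cell-state tree
#'
#' Parses a rooted tree in Newick format (a string or a file path) whose
#' leaves are population identifiers and whose branch lengths are in
#' squared-EVF units: a Diff-EVF performs one Gaussian step of variance
#' equal to the branch length along each branch.
#'
#' @param x Newick text, or the path of a file containing it.
#' @return An object of classes `state_tree` and `phylo` (see
#'   [ape::read.tree()]), with branch lengths required and non-negative.
#' @examples
#' tr <- read_state_tree("(A:1,B:1);")
#' @export
read_state_tree <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  tr <- tryCatch(
    if (file.exists(x)) ape::read.tree(file = x) else ape::read.tree(text = x),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop_domain("could not parse Newick tree: ", x)
  }
  if (is.null(tr$edge.length)) stop_domain("tree must have branch lengths")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0)) {
    stop_domain("branch lengths must be finite and non-negative")
  }
  if (anyDuplicated(tr$tip.label)) stop_domain("leaf labels must be unique")
  class(tr) <- c("state_tree", "phylo")
  tr
}

# Edges ordered so that every parent is visited before its children.
preorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  cbind(tr$edge, length = tr$edge.length)
}

# Depth (distance from root) of every node.
node_depths <- function(tree) {
  e <- preorder_edges(tree)
  depth <- numeric(ape::Ntip(tree) + tree$Nnode)
  for (i in seq_len(nrow(e))) depth[e[i, 2]] <- depth[e[i, 1]] + e[i, 3]
  depth
}

#' Sample Brownian tip values on a state tree
#'
#' For each replicate, performs one Gaussian step of variance equal to the
#' branch length along every branch, starting from `root_value` at the root;
#' internal-node values are shared by all descendant branches. This is the
#' mechanism that gives Diff-EVFs their expected values at the leaves in
#' discrete mode.
#'
#' @param tree A [read_state_tree()] tree.
#' @param n Number of independent replicates.
#' @param root_value Value at the root (default 1).
#' @return A tips x `n` numeric matrix with row names from `tree$tip.label`.
#' @export
sample_brownian_tips <- function(tree, n = 1, root_value = 1) {
  stopifnot(inherits(tree, "phylo"), n >= 1)
  e <- preorder_edges(tree)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  val <- matrix(root_value, n_nodes, n)
  inc <- matrix(rnorm(nrow(e) * n, 0, rep(sqrt(e[, 3]), n)), nrow(e), n)
  for (i in seq_len(nrow(e))) val[e[i, 2], ] <- val[e[i, 1], ] + inc[i, ]
  tips <- val[seq_len(ape::Ntip(tree)), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  tips
}

# Allocate cells to branch positions for the continuous modes: multinomial
# over branches with probability proportional to branch length, uniform
# positions within a branch, sorted so position order defines pseudotime.
allocate_branch_positions <- function(tree, n_cells) {
  e <- preorder_edges(tree)
  if (sum(e[, 3]) <= 0) stop_domain("tree has no positive branch length")
  counts <- as.vector(rmultinom(1, n_cells, e[, 3] / sum(e[, 3])))
  lapply(seq_len(nrow(e)), function(i) sort(runif(counts[i], 0, e[i, 3])))
}

#' Three-phase impulse function
#'
#' The standard product-of-two-sigmoids impulse used to describe transient
#' expression programs: a rise from `h0` towards `h1` around time `t_on`,
#' then a relaxation towards `h2` around `t_off`, with steepness `slope`.
#'
#' @param t Time points (pseudotime, in tree-depth units).
#' @param h0,h1,h2 Onset, peak and offset levels.
#' @param t_on,t_off Onset and offset times.
#' @param slope Sigmoid steepness (per time unit).
#' @return Numeric vector of impulse values at `t`.
#' @export
impulse_function <- function(t, h0 = 1, h1 = 3, h2 = 1,
                             t_on = 0.25, t_off = 0.75, slope = 10) {
  s1 <- h0 + (h1 - h0) / (1 + exp(-slope * (t - t_on)))
  s2 <- h2 + (h1 - h2) / (1 + exp(slope * (t - t_off)))
  s1 * s2 / h1
}

#' Sample per-cell EVF matrices from a cell-state tree
#'
#' Generates the three EVF matrices (one per kinetic parameter) that define
#' cell states. The first `n_diff_evf` columns of each matrix are Diff-EVFs
#' whose means follow the tree; the rest are iid `N(1, sigma)`.
#'
#' In `"discrete"` mode cells sit at the leaves: each population's Diff-EVF
#' mean is a Brownian tip value (one variance-`branch length` step per
#' branch) and cells scatter around it with standard deviation `sigma`.
#' In `"continuous"` mode cells are spread along the branches (multinomial
#' allocation proportional to branch length, uniform positions within a
#' branch) and each Diff-EVF follows one Brownian path over the whole tree,
#' evaluated at every cell's position. In `"impulse"` mode the Diff-EVF mean
#' along one designated root-to-leaf path is an [impulse_function()] of
#' pseudotime; cells off that path take the impulse value at their most
#' recent common ancestor with the path.
#'
#' @param tree A [read_state_tree()] tree.
#' @param mode One of `"discrete"`, `"continuous"`, `"impulse"`.
#' @param n_cells Total number of cells (continuous/impulse modes, and
#'   discrete mode when `cells_per_population` is not given, in which case
#'   cells are split as evenly as possible across leaves).
#' @param cells_per_population Optional named or unnamed integer vector of
#'   cells per leaf (discrete mode).
#' @param sigma Within-population standard deviation of EVF values (>= 0).
#' @param n_evf Number of EVFs per kinetic parameter.
#' @param n_diff_evf Number of Diff-EVFs per kinetic parameter
#'   (0 <= n_diff_evf <= n_evf).
#' @param impulse Optional list of [impulse_function()] parameters plus
#'   `tip` (label of the varying path's leaf; default the first leaf).
#'   Times are interpreted as fractions of the path depth when `t_on`,
#'   `t_off` lie in \[0, 1\].
#' @return An object of class `evf_set`: list with `evf` (list of three
#'   cells x n_evf matrices named `k_on`, `k_off`, `s`), `diff_mask`
#'   (logical per column), `meta` (data.frame with `cell_id`, `population`,
#'   `branch`, `pseudotime`), `sigma`, `mode` and `tree`.
#' @examples
#' tr <- read_state_tree("((1:1,2:1):1,3:2);")
#' set.seed(1)
#' ev <- sample_evfs(tr, "discrete", n_cells = 30, sigma = 0.5,
#'                   n_evf = 10, n_diff_evf = 2)
#' table(ev$meta$population)
#' @export
sample_evfs <- function(tree, mode = c("discrete", "continuous", "impulse"),
                        n_cells = NULL, cells_per_population = NULL,
                        sigma = 0.5, n_evf = 20, n_diff_evf = 4,
                        impulse = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (sigma < 0) stop_domain("'sigma' must be >= 0")
  if (n_diff_evf < 0 || n_diff_evf > n_evf) {
    stop_domain("'n_diff_evf' must lie in [0, n_evf]")
  }
  n_tip <- ape::Ntip(tree)

  if (mode == "discrete") {
    if (is.null(cells_per_population)) {
      stopifnot(!is.null(n_cells), n_cells >= n_tip)
      base <- n_cells %/% n_tip
      cells_per_population <- rep(base, n_tip) +
        c(rep(1, n_cells %% n_tip), rep(0, n_tip - n_cells %% n_tip))
    }
    if (!is.null(names(cells_per_population))) {
      if (!setequal(names(cells_per_population), tree$tip.label)) {
        stop_domain("'cells_per_population' names must be the tree's leaves")
      }
      cells_per_population <- cells_per_population[tree$tip.label]
    }
    if (length(cells_per_population) != n_tip || any(cells_per_population < 1)) {
      stop_domain("'cells_per_population' needs >= 1 cell for each leaf")
    }
    pop <- rep(tree$tip.label, cells_per_population)
    n_cells <- length(pop)
    meta <- data.frame(cell_id = sprintf("cell%d", seq_len(n_cells)),
                       population = pop, branch = NA_character_,
                       pseudotime = NA_real_, stringsAsFactors = FALSE)
    evf <- lapply(1:3, function(param) {
      m <- matrix(rnorm(n_cells * n_evf, 1, sigma), n_cells, n_evf)
      if (n_diff_evf > 0) {
        tips <- sample_brownian_tips(tree, n_diff_evf)  # tips x n_diff
        mu <- tips[match(pop, tree$tip.label), , drop = FALSE]
        m[, seq_len(n_diff_evf)] <-
          matrix(rnorm(n_cells * n_diff_evf, as.vector(mu), sigma),
                 n_cells, n_diff_evf)
      }
      m
    })
  } else {
    stopifnot(!is.null(n_cells), n_cells >= 1)
    e <- preorder_edges(tree)
    depth <- node_depths(tree)
    pos <- allocate_branch_positions(tree, n_cells)
    branch <- rep(e[, 2], lengths(pos))
    ptime <- depth[rep(e[, 1], lengths(pos))] + unlist(pos)
    node_lab <- function(id) {
      ifelse(id <= n_tip, tree$tip.label[id], as.character(id))
    }
    ord <- order(ptime)  # pseudotime-sorted cell ids
    branch <- branch[ord]; ptime <- ptime[ord]
    cell_edge <- match(branch, e[, 2])
    meta <- data.frame(cell_id = sprintf("cell%d", seq_len(n_cells)),
                       population = node_lab(branch),
                       branch = node_lab(branch), pseudotime = ptime,
                       stringsAsFactors = FALSE)

    # per-EVF cell means on the tree
    diff_means <- function() {
      if (mode == "continuous") {
        # one Brownian path over the tree, evaluated at each cell position
        n_nodes <- n_tip + tree$Nnode
        node_val <- numeric(n_nodes); node_val[e[1, 1]] <- 1
        mu <- numeric(n_cells)
        for (i in seq_len(nrow(e))) {
          on_edge <- which(cell_edge == i)
          t_cell <- ptime[on_edge] - depth[e[i, 1]]
          o <- order(t_cell)
          grid <- c(t_cell[o], e[i, 3])
          inc <- rnorm(length(grid), 0, sqrt(pmax(0, diff(c(0, grid)))))
          vals <- node_val[e[i, 1]] + cumsum(inc)
          if (length(on_edge)) mu[on_edge[o]] <- vals[seq_along(on_edge)]
          node_val[e[i, 2]] <- vals[length(grid)]
        }
        mu
      } else {
        imp <- modifyList(list(tip = tree$tip.label[1], h0 = 1, h1 = 3,
                               h2 = 1, t_on = 0.25, t_off = 0.75,
                               slope = 10), impulse)
        tip_id <- match(imp$tip, tree$tip.label)
        if (is.na(tip_id)) stop_domain("impulse 'tip' is not a leaf label")
        path <- ape::nodepath(tree, from = n_tip + 1, to = tip_id)
        path_depth <- depth[tip_id]
        t_on <- if (imp$t_on <= 1) imp$t_on * path_depth else imp$t_on
        t_off <- if (imp$t_off <= 1) imp$t_off * path_depth else imp$t_off
        f <- function(t) impulse_function(t, imp$h0, imp$h1, imp$h2,
                                          t_on, t_off, imp$slope)
        on_path <- e[cell_edge, 2] %in% path
        mu <- numeric(n_cells)
        mu[on_path] <- f(ptime[on_path])
        if (any(!on_path)) {
          # deepest path node that is an ancestor of the cell's branch
          anc_depth <- vapply(which(!on_path), function(ci) {
            node <- e[cell_edge[ci], 1]
            while (!(node %in% path)) {
              node <- e[match(node, e[, 2]), 1]
            }
            depth[node]
          }, numeric(1))
          mu[!on_path] <- f(anc_depth)
        }
        mu
      }
    }
    evf <- lapply(1:3, function(param) {
      m <- matrix(rnorm(n_cells * n_evf, 1, sigma), n_cells, n_evf)
      for (j in seq_len(n_diff_evf)) {
        m[, j] <- rnorm(n_cells, diff_means(), sigma)
      }
      m
    })
  }

  names(evf) <- c("k_on", "k_off", "s")
  evf <- lapply(evf, function(m) {
    dimnames(m) <- list(meta$cell_id, sprintf("evf%d", seq_len(n_evf)))
    m
  })
  structure(list(evf = evf,
                 diff_mask = seq_len(n_evf) <= n_diff_evf,
                 meta = meta, sigma = sigma, mode = mode, tree = tree),
            class = "evf_set")
}

#' @exportS3Method base::print
print.evf_set <- function(x, ...) {
  cat(sprintf("EVF set (%s mode): %d cells, %d EVFs (%d Diff) per kinetic parameter\n",
              x$mode, nrow(x$meta), length(x$diff_mask), sum(x$diff_mask)))
  invisible(x)
}
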