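#' Time-calibrate a supertree from stratigraphic tip ages
#'
#' Assigns node ages so that every internal node is as old as its oldest
#' descendant tip, extends the root age by `root_extension` (default 1 Myr),
#' and removes the resulting zero-length branches by sharing the duration
#' of the nearest older ancestor branch equally along each zero-length
#' chain. Tip ages are the midpoints of the taxa's stratigraphic intervals,
#' in Myr before present.
#'
#' @param phy an `ape::phylo` topology (branch lengths, if any, are
#'   ignored) or a `time_tree`.
#' @param tip_ages named numeric vector of tip ages (Myr before present);
#'   every tip must be present.
#' @param root_extension extra age added to the root, in Myr.
#' @return a [time_tree()] with all branch lengths > 0.
#' @export
calibrate_branch_lengths <- function(phy, tip_ages, root_extension = 1) {
  if (inherits(phy, "time_tree")) phy <- phy$phylo
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("calibration requires a rooted, fully bifurcating topology")
  phy$tip.label <- normalize_labels(phy$tip.label)
  names(tip_ages) <- normalize_labels(names(tip_ages))
  miss <- setdiff(phy$tip.label, names(tip_ages))
  if (length(miss)) stop("tip ages missing for: ", paste(miss, collapse = ", "))
  n <- length(phy$tip.label)
  m <- phy$Nnode
  root <- n + 1L
  ages <- numeric(n + m)
  ages[seq_len(n)] <- tip_ages[phy$tip.label]
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; c <- po$edge[e, 2L]
    ages[p] <- max(ages[p], ages[c])
  }
  ages[root] <- ages[root] + root_extension
  parent <- integer(n + m)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  eps <- 1e-9
  # scan zero-length branches deepest-first so each whole zero chain is
  # spaced out in one pass from its nearest strictly older ancestor
  po_edge <- po$edge
  repeat {
    el <- ages[po_edge[, 1L]] - ages[po_edge[, 2L]]
    zero <- which(el <= eps)
    if (!length(zero)) break
    child <- po_edge[zero[1L], 2L]
    # walk up to the nearest strictly older ancestor
    a <- parent[child]
    while (a != root && ages[a] <= ages[child] + eps) a <- parent[a]
    if (ages[a] <= ages[child] + eps)
      stop("cannot calibrate: zero-length chain reaches the root; ",
           "increase 'root_extension'")
    chain <- child
    node <- parent[child]
    while (node != a) { chain <- c(node, chain); node <- parent[node] }
    steps <- length(chain)                    # edges from a down to child
    spacing <- (ages[a] - ages[child]) / steps
    for (i in seq_along(chain)[-length(chain)])
      ages[chain[i]] <- ages[a] - i * spacing
  }
  phy$edge.length <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
  if (any(phy$edge.length <= 0))
    stop("calibration failed: nonpositive branch length remains ",
         "(a tip is older than an assigned ancestor)")
  time_tree(phy, tip_ages = tip_ages[phy$tip.label], root_age = ages[root])
}

# Weighted graph Laplacian of a time_tree: weights 1/branch-length.
# Returns list(L, n, m) with nodes in ape numbering (tips 1..n first).
tree_laplacian <- function(tree) {
  phy <- tree$phylo
  n <- length(phy$tip.label)
  m <- phy$Nnode
  if (any(phy$edge.length <= 0)) stop("all branch lengths must be positive")
  w <- 1 / phy$edge.length
  i <- c(phy$edge[, 1L], phy$edge[, 2L], phy$edge[, 1L], phy$edge[, 2L])
  j <- c(phy$edge[, 1L], phy$edge[, 2L], phy$edge[, 2L], phy$edge[, 1L])
  xv <- c(w, w, -w, -w)
  L <- Matrix::sparseMatrix(i = i, j = j, x = xv, dims = c(n + m, n + m))
  list(L = L, n = n, m = m)
}

align_tip_states <- function(tree, tip_states) {
  labels <- tree$phylo$tip.label
  Y <- if (is.matrix(tip_states)) tip_states else
    matrix(tip_states, ncol = 1L, dimnames = list(names(tip_states), NULL))
  if (!is.null(rownames(Y))) {
    rownames(Y) <- normalize_labels(rownames(Y))
    miss <- setdiff(labels, rownames(Y))
    if (length(miss)) stop("tip states missing for: ", paste(miss, collapse = ", "))
    Y <- Y[labels, , drop = FALSE]
  } else if (nrow(Y) != length(labels)) {
    stop("tip states must be named or in tip order")
  } else rownames(Y) <- labels
  Y
}

#' Squared-change parsimony ancestral states
#'
#' Reconstructs ancestral states of continuous characters (shape
#' coordinates, log centroid sizes) by minimizing the branch-length-weighted
#' sum of squared changes over the tree,
#' sum over branches of ||child - parent||^2 / branch length.
#' The minimizer is found exactly, per coordinate, from the sparse linear
#' system obtained by zeroing the objective's gradient; it coincides with
#' the maximum-likelihood ancestral states under Brownian motion.
#'
#' @param tree a calibrated `time_tree` (all branch lengths > 0).
#' @param tip_states numeric matrix (rows named by tip label) or a named
#'   vector of scalar states.
#' @return object of class `ancestral_recon` with `node_states`
#'   (one row per internal node, in ape node order, named by node label
#'   where available), `tree_length` (the minimized weighted sum),
#'   `tree`, `tip_states`.
#' @export
ancestral_states_scp <- function(tree, tip_states) {
  stopifnot(inherits(tree, "time_tree"))
  Y <- align_tip_states(tree, tip_states)
  lap <- tree_laplacian(tree)
  n <- lap$n; m <- lap$m
  tips <- seq_len(n); internal <- n + seq_len(m)
  Lii <- lap$L[internal, internal, drop = FALSE]
  Lit <- lap$L[internal, tips, drop = FALSE]
  A <- as.matrix(Matrix::solve(Lii, -Lit %*% Y))
  labs <- tree$phylo$node.label
  rownames(A) <- if (!is.null(labs) && length(labs) == m)
    ifelse(nzchar(labs), labs, paste0("node_", internal)) else
    paste0("node_", internal)
  colnames(A) <- colnames(Y)
  all_states <- rbind(Y, A)
  phy <- tree$phylo
  d <- all_states[phy$edge[, 2L], , drop = FALSE] -
       all_states[phy$edge[, 1L], , drop = FALSE]
  tl <- sum(rowSums(d^2) / phy$edge.length)
  structure(list(node_states = A, tree_length = tl, tree = tree,
                 tip_states = Y),
            class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("<ancestral_recon> ", nrow(x$node_states), " internal nodes, ",
      ncol(x$node_states), " characters, weighted tree length ",
      format(x$tree_length, digits = 6), "\n", sep = "")
  invisible(x)
}

# Reduced quadratic form of the minimized weighted squared-change objective:
# min over internal states = sum_j y_j' M y_j with
# M = L_tt - L_ti L_ii^{-1} L_it (Schur complement on the tips).
scp_quadratic_form <- function(tree) {
  lap <- tree_laplacian(tree)
  n <- lap$n; m <- lap$m
  tips <- seq_len(n); internal <- n + seq_len(m)
  Ltt <- lap$L[tips, tips, drop = FALSE]
  Lti <- lap$L[tips, internal, drop = FALSE]
  Lii <- lap$L[internal, internal, drop = FALSE]
  as.matrix(Ltt - Lti %*% Matrix::solve(Lii, Matrix::t(Lti)))
}

#' Permutation test of phylogenetic signal via tree length
#'
#' The statistic is the minimized branch-length-weighted tree length of the
#' squared-change parsimony mapping of the tip states. The null
#' distribution is built by permuting the assignment of states to tips;
#' shorter observed trees indicate stronger signal, so
#' p = (number of permuted lengths <= observed + 1) / (n_perm + 1).
#'
#' @param tree a calibrated `time_tree`.
#' @param tip_states matrix (rows = tips) or named vector.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @param keep_null store the permuted statistics.
#' @return object of class `signal_test` with `statistic` (observed tree
#'   length), `p_value`, `n_permutations`, optional `null_distribution`.
#' @export
permutation_signal_test <- function(tree, tip_states, n_perm = 10000L,
                                    seed = NULL, keep_null = FALSE) {
  Y <- align_tip_states(tree, tip_states)
  if (n_perm < 100L) warning("fewer than 100 permutations: p is unreliable")
  M <- scp_quadratic_form(tree)
  qf <- function(Z) sum(Z * (M %*% Z))
  obs <- qf(Y)
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  nulls <- numeric(n_perm)
  n <- nrow(Y)
  for (i in seq_len(n_perm)) nulls[i] <- qf(Y[sample.int(n), , drop = FALSE])
  p <- (sum(nulls <= obs) + 1L) / (n_perm + 1L)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 null_distribution = if (keep_null) nulls else NULL,
                 method = "squared-change parsimony tree length"),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat("<signal_test> ", x$method, ": statistic = ",
      format(x$statistic, digits = 6), ", p = ",
      format(x$p_value, digits = 4), " (", x$n_permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

#' Multivariate K statistic of phylogenetic signal
#'
#' Computes the multivariate generalization of Blomberg's K (Adams 2014):
#' the ratio of mean squared tip deviations from the phylogenetic
#' (GLS) mean in the original versus phylogenetically transformed space,
#' divided by its expectation under Brownian motion on the given tree,
#' (tr(C) - n / sum(C^-1)) / (n - 1) with C the phylogenetic covariance
#' in Myr units. K = 1 is the Brownian expectation; K < 1 means less
#' signal than Brownian, K > 1 more. Significance by permuting tip
#' assignments, p = (number of permuted K >= observed + 1) / (n_perm + 1).
#'
#' @inheritParams permutation_signal_test
#' @return a `signal_test` object whose `statistic` is K.
#' @export
k_mult <- function(tree, tip_states, n_perm = 10000L, seed = NULL,
                   keep_null = FALSE) {
  Y <- align_tip_states(tree, tip_states)
  n <- nrow(Y)
  C <- ape::vcv(tree$phylo)
  C <- C[rownames(Y), rownames(Y)]
  invC <- tryCatch(solve(C), error = function(e)
    stop("non-invertible phylogenetic covariance matrix: ", conditionMessage(e)))
  ones <- rep(1, n)
  denom_a <- sum(invC)
  expectation <- (sum(diag(C)) - n / denom_a) / (n - 1)
  k_of <- function(Z) {
    a <- as.vector(crossprod(ones, invC %*% Z)) / denom_a
    Zc <- sweep(Z, 2L, a)
    num <- sum(Zc^2)
    den <- sum(Zc * (invC %*% Zc))
    if (num <= .Machine$double.eps || den <= .Machine$double.eps)
      stop("degenerate tip states: K is undefined for constant data")
    (num / den) / expectation
  }
  obs <- k_of(Y)
  if (n_perm < 100L) warning("fewer than 100 permutations: p is unreliable")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  nulls <- numeric(n_perm)
  for (i in seq_len(n_perm)) nulls[i] <- k_of(Y[sample.int(n), , drop = FALSE])
  p <- (sum(nulls >= obs) + 1L) / (n_perm + 1L)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 null_distribution = if (keep_null) nulls else NULL,
                 method = "multivariate K"),
            class = "signal_test")
}

#' Simulate Brownian motion tip (and node) states on a time tree
#'
#' Independent Brownian motion per column with variance `rate` per Myr,
#' started at `root_state`.
#'
#' @param tree a calibrated `time_tree`.
#' @param p number of trait columns.
#' @param rate Brownian variance per Myr (per trait).
#' @param root_state numeric vector of length p (default zeros).
#' @return matrix of tip states (rows named by tip label).
#' @export
simulate_bm <- function(tree, p = 1L, rate = 1, root_state = numeric(p)) {
  phy <- tree$phylo
  n <- length(phy$tip.label)
  states <- matrix(0, n + phy$Nnode, p)
  states[n + 1L, ] <- root_state
  pre <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]
    states[ch, ] <- states[par, ] +
      stats::rnorm(p, sd = sqrt(rate * pre$edge.length[e]))
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- phy$tip.label
  out
}
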