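#' Principal component analysis of Procrustes coordinates
#'
#' Eigendecomposition of the sample covariance matrix (divisor n - 1) of
#' the aligned coordinates. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#' Variance fractions are taken over the nonzero eigenvalues
#' (GPA leaves near-null dimensions which are excluded by an eigenvalue
#' threshold of 1e-12 times the largest).
#'
#' @param sample an `aligned_sample` or a numeric n x p matrix.
#' @return object of class `pca_result` with `eigenvalues`,
#'   `variance_fractions`, `scores`, `loadings`, `center`, `n_nonzero`,
#'   `n_significant` (broken stick).
#' @export
shape_pca <- function(sample) {
  X <- if (inherits(sample, "aligned_sample")) sample$procrustes_coords
       else as.matrix(sample)
  if (nrow(X) < 3L) stop("PCA needs at least 3 specimens")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  if (max(ev) <= 0) stop("rank-0 data: no shape variation to ordinate")
  nonzero <- ev > 1e-12 * max(ev)
  p <- sum(nonzero)
  V <- eig$vectors
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  fractions <- ev[seq_len(p)] / sum(ev[seq_len(p)])
  scores <- Xc %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(ncol(V)))
  rownames(scores) <- rownames(X)
  structure(
    list(eigenvalues = ev,
         variance_fractions = fractions,
         scores = scores,
         loadings = V,
         center = ctr,
         n_nonzero = p,
         n_significant = broken_stick_significant(ev[seq_len(p)])),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " specimens, ", x$n_nonzero,
      " nonzero components, ", x$n_significant,
      " significant (broken stick)\n", sep = "")
  top <- utils::head(x$variance_fractions, 3L)
  cat("  leading variance fractions:",
      paste(format(top, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Broken-stick count of significant components
#'
#' For p nonzero components the broken-stick expectation for component i is
#' b_i = (1/p) * sum_{j=i..p} 1/j. Components are retained while the
#' observed variance fraction exceeds its expectation, starting at the
#' first component; the length of that initial run is returned.
#'
#' @param eigenvalues descending nonnegative eigenvalues (or variance
#'   fractions; only ratios matter). Near-null dimensions below 1e-12 of
#'   the largest value are dropped before forming the stick.
#' @return integer count of retained components.
#' @export
broken_stick_significant <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (!length(ev) || max(ev) <= 0) stop("need at least one positive eigenvalue")
  ev <- ev[ev > 1e-12 * max(ev)]
  p <- length(ev)
  if (p == 1L) return(1L)   # all variation on a single component
  fractions <- ev / sum(ev)
  b <- rev(cumsum(1 / rev(seq_len(p)))) / p
  keep <- fractions > b
  if (!keep[1L]) return(0L)
  run <- which(!keep)
  if (!length(run)) p else run[1L] - 1L
}
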