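#' Centroid size of a landmark configuration
#'
#' The square root of the sum of squared distances of each landmark to the
#' configuration centroid: the standard geometric-morphometric size
#' measure. Invariant to translation and rotation; scales linearly under
#' uniform scaling.
#'
#' @param config a `landmark_config` or a k x 2 coordinate matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  coords <- if (inherits(config, "landmark_config")) config$coords else as.matrix(config)
  cen <- colMeans(coords)
  cs <- sqrt(sum(sweep(coords, 2L, cen)^2))
  if (cs <= .Machine$double.eps * nrow(coords))
    stop("degenerate configuration: centroid size is zero")
  cs
}

#' Generalized Procrustes analysis
#'
#' Iteratively translates, scales and rotates all configurations onto an
#' evolving mean shape until the consensus stops moving. Semilandmarks are
#' weighted exactly like landmarks and are never slid. Rotations are
#' restricted to det +1 (no reflections) unless `allow_reflection = TRUE`;
#' all specimens must therefore be digitized facing the same direction.
#' After convergence the aligned shapes are (optionally) projected
#' orthogonally onto the tangent space at the consensus.
#'
#' `scale_method = "unit"` (default) scales every configuration to unit
#' centroid size; `"full"` additionally applies the optimal full-Procrustes
#' scale (cos of the Procrustes angle) to each specimen after the final
#' rotation sweep.
#'
#' @param configs list of `landmark_config` objects with common k.
#' @param allow_reflection permit improper rotations (default `FALSE`).
#' @param tangent_project project onto the tangent space at the consensus
#'   (default `TRUE`).
#' @param scale_method `"unit"` or `"full"` (see Details).
#' @param tol convergence tolerance on consensus displacement.
#' @param max_iter maximum alignment sweeps.
#' @return an object of class `aligned_sample` with fields
#'   `procrustes_coords` (n x 2k, rows named by specimen id),
#'   `centroid_sizes`, `log_cs`, `consensus`, `iterations`, `converged`,
#'   plus the specimen metadata (`ids`, `taxa`, `stages`, `is_semilandmark`).
#' @export
gpa <- function(configs, allow_reflection = FALSE, tangent_project = TRUE,
                scale_method = c("unit", "full"),
                tol = 1e-10, max_iter = 200L) {
  scale_method <- match.arg(scale_method)
  k <- validate_config_set(configs)
  n <- length(configs)
  if (n < 2L) stop("GPA needs at least two configurations")
  cs <- vapply(configs, centroid_size, numeric(1))
  # center and scale to unit centroid size
  mats <- lapply(configs, function(cf) {
    m <- sweep(cf$coords, 2L, colMeans(cf$coords))
    m / sqrt(sum(m^2))
  })
  consensus <- mats[[1L]]
  iterations <- 0L
  converged <- FALSE
  delta <- Inf
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    mats <- lapply(mats, rotate_onto, target = consensus,
                   allow_reflection = allow_reflection)
    new_cons <- Reduce(`+`, mats) / n
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("GPA did not converge after ", max_iter,
         " iterations (last consensus displacement ",
         format(delta, digits = 3), ")")
  # canonical orientation (principal axes of the consensus) so the result
  # does not depend on how the input happened to be oriented
  Rc <- canonical_rotation(consensus)
  consensus <- consensus %*% Rc
  mats <- lapply(mats, `%*%`, Rc)
  if (scale_method == "full") {
    mats <- lapply(mats, function(m) m * sum(m * consensus))
  }
  X <- t(vapply(mats, function(m) as.vector(t(m)), numeric(2L * k)))
  cvec <- as.vector(t(consensus))
  if (tangent_project) {
    # orthogonal projection onto the tangent plane {v : v . c = 1} at the
    # unit consensus: x -> x - (x.c - 1) c
    proj <- X %*% cvec
    X <- X - outer(as.vector(proj) - 1, cvec)
  }
  rownames(X) <- config_ids(configs)
  colnames(X) <- as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k)))
  names(cvec) <- colnames(X)
  structure(
    list(procrustes_coords = X,
         centroid_sizes = stats::setNames(cs, config_ids(configs)),
         log_cs = stats::setNames(log(cs), config_ids(configs)),
         consensus = cvec,
         iterations = iterations,
         converged = converged,
         k = k,
         ids = config_ids(configs),
         taxa = config_taxa(configs),
         stages = config_stages(configs),
         is_semilandmark = configs[[1L]]$is_semilandmark,
         tangent_projected = tangent_project,
         scale_method = scale_method),
    class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat("<aligned_sample> ", nrow(x$procrustes_coords), " specimens, k = ",
      x$k, ", converged in ", x$iterations, " sweeps\n", sep = "")
  invisible(x)
}

# Proper rotation bringing a centered configuration onto its principal
# axes (major axis along x), with the 180-degree ambiguity resolved by
# requiring the landmark farthest from the centroid to lie at positive x.
canonical_rotation <- function(m) {
  e <- eigen(crossprod(m), symmetric = TRUE)
  R <- e$vectors
  if (det(R) < 0) R[, 2L] <- -R[, 2L]
  rotated <- m %*% R
  far <- which.max(rowSums(rotated^2))
  if (rotated[far, 1L] < 0) R <- -R
  R
}

# Optimal rotation of m (k x 2, centered) onto target; det +1 enforced
# unless allow_reflection.
rotate_onto <- function(m, target, allow_reflection = FALSE) {
  sv <- svd(crossprod(m, target))
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    d <- diag(c(1, -1))
    R <- sv$u %*% d %*% t(sv$v)
  }
  m %*% R
}

#' Procrustes (Euclidean) distance between two aligned shapes
#'
#' For shapes aligned in one common GPA the Euclidean norm of their
#' difference approximates the Procrustes distance and is used as the
#' package's shape metric throughout.
#'
#' @param a,b shape vectors (length 2k) or k x 2 matrices from a common GPA.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- if (is.matrix(a)) as.vector(t(a)) else as.numeric(a)
  b <- if (is.matrix(b)) as.vector(t(b)) else as.numeric(b)
  if (length(a) != length(b))
    stop("shape vectors have mismatched dimensionality: ",
         length(a), " vs ", length(b))
  sqrt(sum((a - b)^2))
}
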