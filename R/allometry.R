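#' Multivariate regression of shape on log centroid size
#'
#' Least-squares regression of the Procrustes coordinates on
#' log-transformed centroid size. With `groups` supplied, a pooled
#' within-group regression is fitted: both shape and log CS are centered
#' within groups before estimating the common slope (each group then needs
#' at least 2 specimens). The amount of shape variation explained by size
#' is reported as `percent_predicted` = 100 x predicted SS / total SS,
#' tested by permuting the size values against the shapes.
#'
#' @param sample an `aligned_sample`, or a list with elements `shapes`
#'   (n x 2k matrix) and `log_cs` (length-n numeric).
#' @param groups optional grouping labels (length n) for the pooled
#'   within-group variant, e.g. the ontogenetic series each specimen
#'   belongs to.
#' @param n_perm number of permutations for the significance test.
#' @param seed optional integer seed making the permutation p reproducible.
#' @return object of class `regression_result` with `coefficient_vector`
#'   (shape change per unit log CS), `percent_predicted`, `permutation_p`
#'   (computed as (b + 1) / (n_perm + 1)), `regression_scores`, `pooled`,
#'   `grand_mean`, `group_means`.
#' @export
regress_shape_on_size <- function(sample, groups = NULL, n_perm = 10000L,
                                  seed = NULL) {
  dat <- as_shape_size(sample)
  Y <- dat$shapes; x <- dat$log_cs
  n <- nrow(Y)
  if (n < 3L) stop("regression needs at least 3 specimens")
  pooled <- !is.null(groups)
  grand_mean <- colMeans(Y)
  group_means <- NULL
  if (pooled) {
    groups <- as.character(groups)
    if (length(groups) != n) stop("'groups' must have length n")
    sizes <- table(groups)
    if (any(sizes < 2L))
      stop("pooled regression needs >= 2 specimens per group; offending: ",
           paste(names(sizes)[sizes < 2L], collapse = ", "))
    Yc <- Y; xc <- x
    group_means <- list()
    for (g in unique(groups)) {
      idx <- groups == g
      gm <- colMeans(Y[idx, , drop = FALSE])
      Yc[idx, ] <- sweep(Y[idx, , drop = FALSE], 2L, gm)
      xc[idx] <- x[idx] - mean(x[idx])
      group_means[[g]] <- list(shape = gm, log_cs = mean(x[idx]))
    }
  } else {
    Yc <- sweep(Y, 2L, grand_mean)
    xc <- x - mean(x)
  }
  sxx <- sum(xc^2)
  if (sxx <= .Machine$double.eps * n)
    stop("zero size variance: cannot regress shape on size")
  b <- as.vector(crossprod(Yc, xc)) / sxx
  pred_ss <- sxx * sum(b^2)
  tot_ss <- sum(Yc^2)
  percent <- 100 * pred_ss / tot_ss
  # permutation: shuffle sizes against shapes; statistic = predicted SS
  perm_p <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) {
      old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
    }
    hits <- 0L
    for (i in seq_len(n_perm)) {
      xp <- sample(xc)
      bp <- as.vector(crossprod(Yc, xp)) / sxx
      if (sxx * sum(bp^2) >= pred_ss) hits <- hits + 1L
    }
    perm_p <- (hits + 1L) / (n_perm + 1L)
  }
  res <- structure(
    list(coefficient_vector = b,
         percent_predicted = percent,
         permutation_p = perm_p,
         n_perm = n_perm,
         pooled = pooled,
         grand_mean = grand_mean,
         group_means = group_means),
    class = "regression_result")
  res$regression_scores <- stats::setNames(regression_score(Y, res),
                                           rownames(Y))
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> ", if (x$pooled) "pooled within-group " else "",
      "shape ~ log CS: ", format(x$percent_predicted, digits = 4),
      "% predicted, permutation p = ", format(x$permutation_p, digits = 4),
      "\n", sep = "")
  invisible(x)
}

as_shape_size <- function(sample) {
  if (inherits(sample, "aligned_sample"))
    list(shapes = sample$procrustes_coords, log_cs = as.numeric(sample$log_cs))
  else if (is.list(sample) && all(c("shapes", "log_cs") %in% names(sample)))
    list(shapes = as.matrix(sample$shapes), log_cs = as.numeric(sample$log_cs))
  else stop("'sample' must be an aligned_sample or list(shapes, log_cs)")
}

#' Regression score of shapes on a fitted allometric axis
#'
#' Orthogonal projection of (shape - grand mean) onto the unit-normalized
#' regression coefficient vector, giving one allometric shape scalar per
#' specimen, in Procrustes units.
#'
#' @param shapes n x 2k matrix of aligned shapes (or a single shape vector)
#'   from the same GPA as the fit.
#' @param result a `regression_result`.
#' @return numeric vector of scores.
#' @export
regression_score <- function(shapes, result) {
  if (!inherits(result, "regression_result"))
    stop("'result' must be a regression_result")
  b <- result$coefficient_vector
  nb <- sqrt(sum(b^2))
  if (nb <= .Machine$double.eps) stop("zero coefficient vector")
  if (!is.matrix(shapes)) shapes <- matrix(shapes, nrow = 1L)
  as.vector(sweep(shapes, 2L, result$grand_mean) %*% (b / nb))
}

#' Euclidean-distance shape variable
#'
#' Per-specimen Euclidean (Procrustes) distance from a reference specimen,
#' which is set to zero; by convention the reference is the smallest
#' specimen of the sample so the variable increases away from it.
#'
#' @param sample an `aligned_sample`, or an n x 2k matrix with row names.
#' @param reference_id specimen id used as the zero point. Defaults, for an
#'   `aligned_sample`, to the specimen with the smallest centroid size.
#' @return object of class `shape_variable_series`: list with `variable`,
#'   `values` (named), `reference_id`.
#' @export
euclidean_distance_variable <- function(sample, reference_id = NULL) {
  if (inherits(sample, "aligned_sample")) {
    X <- sample$procrustes_coords
    if (is.null(reference_id))
      reference_id <- names(which.min(sample$centroid_sizes))
  } else {
    X <- as.matrix(sample)
    if (is.null(reference_id)) stop("'reference_id' required for raw matrices")
  }
  if (!reference_id %in% rownames(X))
    stop("reference specimen '", reference_id, "' not present in sample")
  ref <- X[reference_id, ]
  vals <- sqrt(rowSums(sweep(X, 2L, ref)^2))
  vals[reference_id] <- 0
  structure(list(variable = "euclidean_distance",
                 values = vals,
                 reference_id = reference_id),
            class = "shape_variable_series")
}

#' Slope of a two-stage ontogenetic trajectory
#'
#' Change in a scalar shape variable per unit log centroid size between the
#' juvenile and adult stage of one trajectory.
#'
#' @param juvenile,adult numeric length-2 vectors `c(log_cs, shape_variable)`.
#' @return scalar slope.
#' @export
trajectory_slope <- function(juvenile, adult) {
  dx <- adult[1L] - juvenile[1L]
  if (abs(dx) <= .Machine$double.eps)
    stop("undefined slope: juvenile and adult have equal log centroid size")
  unname((adult[2L] - juvenile[2L]) / dx)
}

# Seed handling: set a temporary RNG state and restore the caller's.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
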