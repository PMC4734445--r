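test_that("exact allometric data is fully explained with the right axis", {
  set.seed(61)
  p <- 20L
  mu <- stats::rnorm(p)
  v <- stats::rnorm(p); v <- v / sqrt(sum(v^2))
  lcs <- seq(0.5, 2, length.out = 12)
  Y <- t(vapply(lcs, function(x) mu + x * 0.07 * v, numeric(p)))
  rownames(Y) <- paste0("s", seq_along(lcs))
  fit <- regress_shape_on_size(list(shapes = Y, log_cs = lcs), n_perm = 0L)
  expect_equal(fit$percent_predicted, 100, tolerance = 1e-9)
  cosang <- sum(fit$coefficient_vector * v) /
    sqrt(sum(fit$coefficient_vector^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-9)
})

test_that("regression scores are unit-axis projections from the grand mean", {
  set.seed(62)
  p <- 16L
  Y <- matrix(stats::rnorm(10 * p), 10, p,
              dimnames = list(paste0("s", 1:10), NULL))
  lcs <- stats::rnorm(10)
  fit <- regress_shape_on_size(list(shapes = Y, log_cs = lcs), n_perm = 0L)
  expect_equal(regression_score(fit$grand_mean, fit), 0, tolerance = 1e-12)
  u <- fit$coefficient_vector / sqrt(sum(fit$coefficient_vector^2))
  expect_equal(regression_score(fit$grand_mean + 2 * u, fit), 2,
               tolerance = 1e-9)
  # univariate regression of the scores reproduces percent_predicted of
  # the projection onto the allometric axis
  rs <- fit$regression_scores
  proj <- as.vector(sweep(Y, 2L, fit$grand_mean) %*% u)
  expect_equal(unname(rs), proj, tolerance = 1e-9)
})

test_that("pooled within-group regression centers both shape and size", {
  set.seed(63)
  p <- 12L
  v <- stats::rnorm(p); v <- v / sqrt(sum(v^2))
  groups <- rep(c("a", "b", "c"), each = 4L)
  offsets <- list(a = stats::rnorm(p, sd = 3), b = stats::rnorm(p, sd = 3),
                  c = stats::rnorm(p, sd = 3))
  lcs <- rep(c(0, 1, 2, 3), times = 3L) + rep(c(0, 5, 10), each = 4L)
  Y <- t(vapply(seq_along(lcs), function(i)
    offsets[[groups[i]]] + lcs[i] %% 5 * 0.1 * v, numeric(p)))
  # within groups shape depends on size exactly; between-group offsets are
  # arbitrary, so the pooled fit explains all within-group variation
  fit <- regress_shape_on_size(list(shapes = Y, log_cs = lcs),
                               groups = groups, n_perm = 0L)
  expect_equal(fit$percent_predicted, 100, tolerance = 1e-9)
  expect_error(regress_shape_on_size(list(shapes = Y, log_cs = lcs),
                                     groups = seq_along(lcs), n_perm = 0L),
               ">= 2 specimens")
})

test_that("permutation p is seed-reproducible and valid under the null", {
  set.seed(64)
  Y <- matrix(stats::rnorm(30 * 10), 30, 10)
  lcs <- stats::rnorm(30)
  p1 <- regress_shape_on_size(list(shapes = Y, log_cs = lcs),
                              n_perm = 500L, seed = 9L)$permutation_p
  p2 <- regress_shape_on_size(list(shapes = Y, log_cs = lcs),
                              n_perm = 500L, seed = 9L)$permutation_p
  expect_identical(p1, p2)

  # size-independent shapes: non-rejection rate at the 5% level stays
  # within 3 binomial standard errors of 95%
  set.seed(65)
  hits <- 0L
  for (r in 1:100) {
    Yr <- matrix(stats::rnorm(50 * 8), 50, 8)
    xr <- stats::rnorm(50)
    pr <- regress_shape_on_size(list(shapes = Yr, log_cs = xr),
                                n_perm = 499L, seed = r)$permutation_p
    hits <- hits + (pr > 0.05)
  }
  expect_lt(abs(hits / 100 - 0.95), 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("estimated allometric axis converges to truth with sample size", {
  angle_to_truth <- function(n, seed) {
    set.seed(seed)
    p <- 30L
    v <- stats::rnorm(p); v <- v / sqrt(sum(v^2))
    lcs <- stats::runif(n, 0, 2)
    Y <- t(vapply(lcs, function(x)
      x * 0.05 * v + stats::rnorm(p, sd = 0.02), numeric(p)))
    fit <- regress_shape_on_size(list(shapes = Y, log_cs = lcs), n_perm = 0L)
    b <- fit$coefficient_vector / sqrt(sum(fit$coefficient_vector^2))
    acos(min(1, abs(sum(b * v)))) * 180 / pi
  }
  a10 <- mean(vapply(1:8, function(s) angle_to_truth(10L, s), numeric(1)))
  a100 <- mean(vapply(1:8, function(s) angle_to_truth(100L, s), numeric(1)))
  expect_lt(a100, a10)
})

test_that("Euclidean-distance variable zeroes the reference specimen", {
  set.seed(66)
  sample <- gpa(random_config_set(n = 8, k = 12))
  ed <- euclidean_distance_variable(sample, reference_id = "s3")
  expect_identical(unname(ed$values["s3"]), 0)
  X <- sample$procrustes_coords
  brute <- apply(X, 1L, function(r) sqrt(sum((r - X["s3", ])^2)))
  expect_equal(ed$values, brute, tolerance = 1e-12)

  # default reference is the smallest specimen
  ed2 <- euclidean_distance_variable(sample)
  expect_identical(ed2$reference_id, names(which.min(sample$centroid_sizes)))
  expect_error(euclidean_distance_variable(sample, reference_id = "nope"),
               "not present")

  # swapping the reference permutes values consistently
  ed4 <- euclidean_distance_variable(sample, reference_id = "s4")
  expect_equal(unname(ed4$values["s3"]), unname(ed$values["s4"]),
               tolerance = 1e-12)
})

test_that("trajectory slopes are finite differences of the shape variable", {
  expect_identical(trajectory_slope(c(0, 0), c(1, 2)), 2)
  expect_identical(trajectory_slope(c(1, 5), c(3, 5)), 0)
  expect_error(trajectory_slope(c(1, 0), c(1, 2)), "undefined slope")
  set.seed(67)
  for (i in 1:100) {
    j <- stats::rnorm(2); a <- stats::rnorm(2)
    if (abs(a[1] - j[1]) < 1e-6) next
    expect_equal(trajectory_slope(j, a), (a[2] - j[2]) / (a[1] - j[1]),
                 tolerance = 1e-12)
  }
})

test_that("percent predicted is invariant to a common rotation", {
  set.seed(68)
  sample <- gpa(random_config_set(n = 10, k = 12))
  X <- sample$procrustes_coords
  lcs <- stats::rnorm(10)
  R <- rotation2(77)
  Xr <- t(apply(X, 1L, function(v) as.vector(t(unflatten_shape(v) %*% R))))
  f1 <- regress_shape_on_size(list(shapes = X, log_cs = lcs), n_perm = 0L)
  f2 <- regress_shape_on_size(list(shapes = Xr, log_cs = lcs), n_perm = 0L)
  expect_equal(f1$percent_predicted, f2$percent_predicted, tolerance = 1e-9)
})
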