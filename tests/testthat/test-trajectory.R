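make_traj <- function(label, j_scores, a_scores, j_lcs = 0.5, a_lcs = 2,
                      is_ancestral = FALSE) {
  ontogenetic_trajectory(
    label,
    juvenile = list(shape = stats::rnorm(8), log_cs = j_lcs,
                    scores = j_scores),
    adult = list(shape = stats::rnorm(8), log_cs = a_lcs,
                 scores = a_scores),
    is_ancestral = is_ancestral)
}

test_that("change vectors point from juvenile to adult", {
  set.seed(81)
  tr <- make_traj("x", c(PC1 = 0, PC2 = 0), c(PC1 = 3, PC2 = 4))
  v <- change_vector(tr, c("PC1", "PC2"))
  expect_equal(v, c(3, 4))
  expect_equal(trajectory_length(v), 5)
  same <- make_traj("y", c(PC1 = 1, PC2 = 2), c(PC1 = 1, PC2 = 2))
  expect_equal(change_vector(same, c("PC1", "PC2")), c(0, 0))
  for (i in 1:20) {
    j <- stats::rnorm(2); a <- stats::rnorm(2)
    tr <- make_traj("z", c(PC1 = j[1], PC2 = j[2]),
                    c(PC1 = a[1], PC2 = a[2]))
    expect_equal(change_vector(tr, c("PC1", "PC2")), a - j,
                 tolerance = 1e-12)
  }
  expect_error(change_vector(tr, c("PC1", "PC9")), "lacks traits")
})

test_that("trajectory angles are exact on analytic cases", {
  expect_equal(trajectory_angle(c(1, 2), c(1, 2)), 0, tolerance = 1e-9)
  expect_equal(trajectory_angle(c(1, 2), c(-1, -2)), 180, tolerance = 1e-9)
  expect_equal(trajectory_angle(c(1, 0), c(0, 1)), 90, tolerance = 1e-12)
  expect_equal(trajectory_angle(c(1, 0), c(1, 1)), 45, tolerance = 1e-9)
  expect_error(trajectory_angle(c(0, 0), c(1, 1)), "zero-length")
  # invariant to a common rescaling; length scales linearly
  set.seed(82)
  a <- stats::rnorm(2); b <- stats::rnorm(2)
  expect_equal(trajectory_angle(a, b), trajectory_angle(7 * a, 0.3 * b),
               tolerance = 1e-9)
  expect_equal(trajectory_length(7 * a), 7 * trajectory_length(a),
               tolerance = 1e-12)
})

test_that("CI threshold matches the closed-form t interval", {
  expect_equal(ci_threshold(rep(2.5, 10)), 0, tolerance = 1e-12)
  # {-1, 1}: mean 0, sd = sqrt(2), half-width t(.975, 1) * sqrt(2)/sqrt(2)
  expect_equal(ci_threshold(c(-1, 1)), stats::qt(0.975, 1), tolerance = 1e-9)
  set.seed(83)
  d <- stats::rnorm(68, sd = 0.3)
  expect_equal(ci_threshold(d),
               stats::qt(0.975, 67) * stats::sd(d) / sqrt(68),
               tolerance = 1e-12)
  q <- ci_threshold(d, method = "quantile")
  expect_equal(q, diff(stats::quantile(d, c(0.025, 0.975),
                                       names = FALSE)) / 2,
               tolerance = 1e-12)
  expect_error(ci_threshold(1), "at least 2")
})

test_that("the t interval for the mean has nominal coverage", {
  set.seed(84)
  mu <- 0.4; sigma <- 1.3
  covered <- 0L
  for (r in 1:1000) {
    d <- stats::rnorm(68, mean = mu, sd = sigma)
    half <- ci_threshold(d)
    covered <- covered + (abs(mean(d) - mu) <= half)
  }
  expect_gt(covered / 1000, 0.93)
  expect_lt(covered / 1000, 0.97)
})

test_that("classification needs both variables significant and concordant", {
  anc <- make_traj("anc", c(rs = 0, ed = 0), c(rs = 0.5, ed = 0.5))
  same <- make_traj("d0", c(rs = 0, ed = 0), c(rs = 0.5, ed = 0.5))
  cl <- classify_heterochrony(anc, same, ci_rs = 0.1, ci_ed = 0.1)
  expect_identical(cl$classification, "undetermined")
  expect_false(cl$rs_significant); expect_false(cl$ed_significant)

  paedo <- make_traj("dp", c(rs = 0, ed = 0), c(rs = 0.1, ed = 0.2))
  cl <- classify_heterochrony(anc, paedo, ci_rs = 0.1, ci_ed = 0.1)
  expect_identical(cl$classification, "paedomorphosis")
  expect_equal(cl$delta_rs, -0.4); expect_equal(cl$delta_ed, -0.3)

  pera <- make_traj("dq", c(rs = 0, ed = 0), c(rs = 0.9, ed = 0.8))
  expect_identical(classify_heterochrony(anc, pera, 0.1, 0.1)$classification,
                   "peramorphosis")

  # |delta| exactly 1.5 x CI counts as significant
  edge <- make_traj("de", c(rs = 0, ed = 0), c(rs = 0.65, ed = 0.65))
  cl <- classify_heterochrony(anc, edge, ci_rs = 0.1, ci_ed = 0.1)
  expect_true(cl$rs_significant && cl$ed_significant)
  expect_identical(cl$classification, "peramorphosis")

  # discordant signs stay undetermined even when both are significant
  mixed <- make_traj("dm", c(rs = 0, ed = 0), c(rs = 0.1, ed = 0.9))
  expect_identical(classify_heterochrony(anc, mixed, 0.1, 0.1)$classification,
                   "undetermined")
})

test_that("ancestral trajectories pair the two reconstructions by clade", {
  st <- fixture_study(seed = 19, n_perm = 0L)
  cfg <- st$config; cfg$run_signal_tests <- FALSE; cfg$n_perm <- 0L
  res <- run_full_analysis(cfg)
  anc <- res$trajectories[c("clade_stem", "clade_B", "clade_C", "clade_D")]
  expect_true(all(vapply(anc, `[[`, logical(1), "is_ancestral")))
  expect_length(res$trajectories, 9L)
  expect_error(
    ancestral_trajectories(res$adult_recon, res$juvenile_recon,
                           list(bad = c("nope1", "nope2"))),
    "no tips")
})

test_that("shared ontogeny is recovered in ancestral trajectories", {
  # all tips share exactly one ontogeny (no drift, no noise): every
  # reconstructed ancestral trajectory aligns with the shared one
  res <- quiet_pipeline(seed = 91, shifts = numeric(0),
                        truth_args = list(bm_rate = 0, bm_rate_logcs = 0,
                                          noise_sd = 0))
  shared <- change_vector(res$trajectories[["t1"]], c("PC1", "PC2"))
  for (nm in c("clade_stem", "clade_B", "clade_C", "clade_D")) {
    anc_vec <- change_vector(res$trajectories[[nm]], c("PC1", "PC2"))
    expect_lt(trajectory_angle(anc_vec, shared), 1)
  }
  # under digitization noise and drift the direction is preserved grossly
  res2 <- quiet_pipeline(seed = 91, shifts = numeric(0),
                         truth_args = list(bm_rate_logcs = 0))
  shared2 <- change_vector(res2$trajectories[["t1"]], c("PC1", "PC2"))
  for (nm in c("clade_stem", "clade_B", "clade_C", "clade_D")) {
    anc_vec <- change_vector(res2$trajectories[[nm]], c("PC1", "PC2"))
    expect_lt(trajectory_angle(anc_vec, shared2), 45)
  }
})

test_that("branch differences cover every branch of the tree", {
  set.seed(85)
  tt <- fixture_tree()
  y <- stats::setNames(stats::rnorm(12), tt$phylo$tip.label)
  rec <- ancestral_states_scp(tt, y)
  d <- branch_differences(rec, tip_values = y,
                          node_values = rec$node_states[, 1])
  expect_length(d, 22L)
  # child-minus-parent along one known edge
  phy <- tt$phylo
  e1 <- which(phy$edge[, 2] == match("t1", phy$tip.label))
  all_vals <- c(y[phy$tip.label], rec$node_states[, 1])
  expect_equal(d[e1], unname(y["t1"] - all_vals[phy$edge[e1, 1]]),
               tolerance = 1e-12)
})
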