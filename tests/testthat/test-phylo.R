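test_that("root extension resolves equal-age cherries", {
  phy <- ape::read.tree(text = "(A,B);")
  tt <- calibrate_branch_lengths(phy, c(A = 200, B = 200))
  expect_equal(tt$root_age, 201)
  expect_equal(unname(tt$phylo$edge.length), c(1, 1))
})

test_that("zero-length chains share the subtending duration equally", {
  # caterpillar with a 6-Myr branch above a chain of zero-length branches:
  # root(196) -> n3(190) -> n2(190) -> n1(190) -> t1(190); the chain of
  # 4 edges (6, 0, 0, 0) is shared equally into 1.5 Myr each
  phy <- ape::read.tree(text = "((((t1,t2),t3),t4),t5);")
  ages <- c(t1 = 190, t2 = 170, t3 = 172, t4 = 174, t5 = 195)
  tt <- calibrate_branch_lengths(phy, ages, root_extension = 1)
  expect_equal(tt$root_age, 196)
  nages <- ontomorph:::node_ages(tt)
  # internal nodes sit at 194.5, 193, 191.5 (equal spacing to t1 at 190)
  expect_equal(sort(nages[7:9], decreasing = TRUE), c(194.5, 193, 191.5))
  expect_true(all(tt$phylo$edge.length > 0))
})

test_that("calibrated fixture tree respects ages and branch-count identity", {
  tt <- fixture_tree()
  n <- length(tt$phylo$tip.label)
  expect_identical(nrow(tt$phylo$edge), 2L * n - 2L)
  expect_identical(tt$phylo$Nnode, n - 1L)
  expect_true(all(tt$phylo$edge.length > 0))
  nages <- ontomorph:::node_ages(tt)
  expect_equal(unname(nages[seq_len(n)]),
               unname(tt$tip_ages[tt$phylo$tip.label]), tolerance = 1e-9)
  # every parent is older than its children
  expect_true(all(nages[tt$phylo$edge[, 1]] > nages[tt$phylo$edge[, 2]]))
})

test_that("squared-change parsimony solves the two-tip cases exactly", {
  phy <- ape::read.tree(text = "(A:1,B:1);")
  rec <- ancestral_states_scp(time_tree(phy), c(A = 0, B = 4))
  expect_equal(unname(rec$node_states[1, 1]), 2, tolerance = 1e-12)
  phy2 <- ape::read.tree(text = "(A:1,B:3);")
  # minimize (x-0)^2/1 + (x-4)^2/3: x = 1
  rec2 <- ancestral_states_scp(time_tree(phy2), c(A = 0, B = 4))
  expect_equal(unname(rec2$node_states[1, 1]), 1, tolerance = 1e-12)
  expect_equal(rec2$tree_length, 1 / 1 + 9 / 3, tolerance = 1e-12)
})

test_that("SCP minimizes the weighted objective (brute-force check)", {
  for (seed in 1:5) {
    set.seed(seed)
    phy <- ape::rtree(5)
    phy$edge.length <- stats::runif(nrow(phy$edge), 0.5, 3)
    tt <- time_tree(phy)
    y <- stats::setNames(stats::rnorm(5), phy$tip.label)
    rec <- ancestral_states_scp(tt, y)
    all_states <- function(internal) {
      s <- c(y[phy$tip.label], internal)
      d <- s[phy$edge[, 2]] - s[phy$edge[, 1]]
      sum(d^2 / phy$edge.length)
    }
    o <- stats::optim(rep(mean(y), 4), all_states, method = "BFGS",
                      control = list(reltol = 1e-15))
    expect_equal(rec$tree_length, o$value, tolerance = 1e-8)
    expect_equal(unname(rec$node_states[, 1]), unname(o$par),
                 tolerance = 1e-5)
  }
})

test_that("weighted SCP equals Brownian-motion ML ancestral states", {
  skip_if_not_installed("phytools")
  set.seed(71)
  phy <- ape::rtree(24)
  phy$edge.length <- phy$edge.length + 0.2
  y <- stats::setNames(stats::rnorm(24), phy$tip.label)
  rec <- ancestral_states_scp(time_tree(phy), y)
  fa <- phytools::fastAnc(phy, y)
  expect_lt(max(abs(rec$node_states[, 1] - as.numeric(fa))), 1e-8)
})

test_that("tree length is invariant to rotation and scales with branch time", {
  set.seed(72)
  tt <- fixture_tree()
  Y <- matrix(stats::rnorm(12 * 8), 12, 8,
              dimnames = list(tt$phylo$tip.label, NULL))
  rec <- ancestral_states_scp(tt, Y)
  # doubling all branch lengths halves the weighted tree length
  tt2 <- tt
  tt2$phylo$edge.length <- 2 * tt$phylo$edge.length
  rec2 <- ancestral_states_scp(tt2, Y)
  expect_equal(rec2$tree_length, rec$tree_length / 2, tolerance = 1e-9)
  # global rotation of paired coordinates leaves the length unchanged
  R <- rotation2(41)
  Yr <- t(apply(Y, 1L, function(v) as.vector(t(unflatten_shape(v) %*% R))))
  rownames(Yr) <- rownames(Y)
  expect_equal(ancestral_states_scp(tt, Yr)$tree_length, rec$tree_length,
               tolerance = 1e-9)
})

test_that("permutation signal test matches the SCP statistic and is seeded", {
  set.seed(73)
  tt <- fixture_tree()
  Y <- simulate_bm(tt, p = 4, rate = 0.01)
  rec <- ancestral_states_scp(tt, Y)
  s1 <- suppressWarnings(permutation_signal_test(tt, Y, n_perm = 99,
                                                 seed = 5))
  expect_equal(s1$statistic, rec$tree_length, tolerance = 1e-9)
  s2 <- suppressWarnings(permutation_signal_test(tt, Y, n_perm = 99,
                                                 seed = 5))
  expect_identical(s1$p_value, s2$p_value)
  # strong Brownian signal on the tree: observed length is short
  s3 <- permutation_signal_test(tt, Y, n_perm = 499, seed = 6)
  expect_lt(s3$p_value, 0.05)
})

test_that("multivariate K reduces to Blomberg's K for one trait", {
  skip_if_not_installed("phytools")
  set.seed(74)
  phy <- ape::rtree(20)
  phy$edge.length <- phy$edge.length + 0.1
  y <- stats::setNames(stats::rnorm(20), phy$tip.label)
  k_ours <- suppressWarnings(k_mult(time_tree(phy), y, n_perm = 0))$statistic
  k_ref <- as.numeric(phytools::phylosig(phy, y, method = "K"))
  expect_equal(k_ours, k_ref, tolerance = 1e-8)
})

test_that("K is degenerate for constant tip states", {
  tt <- fixture_tree()
  Y <- matrix(1, 12, 3, dimnames = list(tt$phylo$tip.label, NULL))
  expect_error(suppressWarnings(k_mult(tt, Y, n_perm = 0)), "degenerate")
})

test_that("Brownian simulation is seed-deterministic on the tree", {
  tt <- fixture_tree()
  set.seed(75); a <- simulate_bm(tt, p = 3, rate = 0.1)
  set.seed(75); b <- simulate_bm(tt, p = 3, rate = 0.1)
  expect_identical(a, b)
  expect_identical(rownames(a), tt$phylo$tip.label)
})
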