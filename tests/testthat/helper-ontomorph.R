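# Shared helpers: geometric transforms, tiny random data sets, and a quiet
# pipeline wrapper for replicate simulations.

rotation2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

# Apply a similarity transform (rotation deg, scaling, shift, optional
# reflection) to a landmark configuration.
transform_config <- function(config, deg = 0, scale = 1, shift = c(0, 0),
                             reflect = FALSE) {
  m <- config$coords
  if (reflect) m[, 1L] <- -m[, 1L]
  m <- m %*% rotation2(deg) * scale
  m <- sweep(m, 2L, shift, `+`)
  landmark_configuration(m, specimen_id = paste0(config$specimen_id, "_t"),
                         taxon = config$taxon, stage = config$stage,
                         is_semilandmark = config$is_semilandmark)
}

random_config <- function(k = 12L, id = "s1", stage = "adult",
                          taxon = id) {
  landmark_configuration(matrix(stats::rnorm(2L * k), k, 2L),
                         specimen_id = id, taxon = taxon, stage = stage)
}

# Noisy copies of a base shape, for GPA tests.
random_config_set <- function(n = 8L, k = 12L, sd = 0.02) {
  base <- matrix(stats::rnorm(2L * k), k, 2L)
  lapply(seq_len(n), function(i)
    landmark_configuration(base + matrix(stats::rnorm(2L * k, sd = sd), k, 2L),
                           specimen_id = paste0("s", i)))
}

# Pipeline run without permutation tests, for replicate simulations.
quiet_pipeline <- function(seed, shifts = numeric(0), truth_args = list()) {
  st <- fixture_study(seed = seed, shifts = shifts, n_perm = 0L,
                      truth_args = truth_args)
  cfg <- st$config
  cfg$run_signal_tests <- FALSE
  cfg$n_perm <- 0L
  run_full_analysis(cfg)
}

# Branch-difference spread (SD) of the regression score implied by a
# pipeline result's stored CI threshold.
rs_branch_spread <- function(result) {
  m <- result$ci$n_branches
  result$ci$rs * sqrt(m) / stats::qt(0.975, m - 1L)
}

balanced_unit_tree <- function(n_tips = 64L) {
  phy <- ape::stree(n_tips, type = "balanced")
  phy$edge.length <- rep(1, nrow(phy$edge))
  time_tree(phy)
}

# Paths where the deposited landmark and supertree files would be bundled.
published_data_paths <- function() {
  dir <- system.file("extdata", package = "ontomorph")
  c(landmarks = file.path(dir, "saurischia_landmarks_morphoj.txt"),
    tree = file.path(dir, "saurischia_supertree.nex"))
}
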