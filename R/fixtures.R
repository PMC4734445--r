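#' Miniature study: time tree
#'
#' A deterministic 12-taxon supertree with named internal clades
#' (`clade_stem`, `clade_B`, `clade_C`, `clade_D`) and Mesozoic-scale
#' stratigraphic tip ages, calibrated with [calibrate_branch_lengths()].
#' Five taxa (t1, t4, t6, t10, t11) carry juvenile stages in the matching
#' synthetic data, mirroring a study design with nested two-stage
#' ontogenetic series.
#'
#' @return a calibrated `time_tree`.
#' @export
fixture_tree <- function() {
  nwk <- "((t1,(t2,t3)),((t4,t5),((t6,t7),((t8,t9),(t10,(t11,t12))))));"
  phy <- ape::read.tree(text = nwk)
  phy$node.label <- rep("", phy$Nnode)
  n <- length(phy$tip.label)
  label_mrca <- function(tips, lab) {
    node <- ape::getMRCA(phy, tips)
    phy$node.label[node - n] <<- lab
  }
  label_mrca(phy$tip.label, "clade_stem")
  label_mrca(paste0("t", 4:12), "clade_B")
  label_mrca(paste0("t", 6:12), "clade_C")
  label_mrca(paste0("t", 8:12), "clade_D")
  # the oldest tip (t2) is a background taxon: the root reconstruction is
  # inevitably pinned to the oldest tip by the short post-calibration
  # branches, so that tip must not carry a juvenile series or a shift
  ages <- c(t1 = 195, t2 = 205, t3 = 200, t4 = 188, t5 = 185, t6 = 175,
            t7 = 170, t8 = 160, t9 = 155, t10 = 150, t11 = 80, t12 = 85)
  calibrate_branch_lengths(phy, ages)
}

fixture_juvenile_taxa <- function() c("t1", "t4", "t6", "t10", "t11")

fixture_clades <- function() {
  list(clade_stem = paste0("t", 1:12),
       clade_B = paste0("t", 4:12),
       clade_C = paste0("t", 6:12),
       clade_D = paste0("t", 8:12))
}

fixture_comparisons <- function() {
  list(c("clade_stem", "t1"), c("clade_stem", "clade_B"),
       c("clade_B", "t4"), c("clade_B", "clade_C"),
       c("clade_C", "t6"), c("clade_C", "clade_D"),
       c("clade_D", "t10"), c("clade_D", "t11"))
}

# Injected heterochronic structure of the miniature study: a paedomorphic
# basal lineage (t1) and ancestor (clade_D), peramorphic shifts on the
# clade_B stem and on t4 and t6, and no shift elsewhere.
fixture_shifts <- function(magnitude = 0.02) {
  c(t1 = -magnitude, clade_B = magnitude, t4 = magnitude,
    t6 = magnitude, clade_D = -magnitude)
}

#' Miniature study: complete synthetic data bundle
#'
#' Generates the package's reference synthetic study: 12 taxa on
#' [fixture_tree()], adult shapes evolving by Brownian motion, five
#' two-stage ontogenetic series, and heterochronic shifts of known sign on
#' five branches ([fixture_shifts()]). The returned list plugs directly
#' into [run_full_analysis()].
#'
#' @param seed integer seed.
#' @param shifts named shift vector (default [fixture_shifts()]; pass
#'   `numeric(0)` for a null study without heterochrony).
#' @param n_perm permutation count forwarded to the pipeline config.
#' @param truth_args extra arguments to [synthetic_truth()] overriding the
#'   study conditions (e.g. `bm_rate_logcs = 0` for a null study without
#'   size evolution, since allometric sliding driven by adult-size change
#'   is itself heterochronic signal).
#' @return list with `configs`, `tree`, `truth`, `sim`, `clades`,
#'   `comparisons`, `juvenile_taxa`, and a ready-made `config` list.
#' @export
fixture_study <- function(seed = 1L, shifts = fixture_shifts(),
                          n_perm = 999L, truth_args = list()) {
  tree <- fixture_tree()
  truth <- do.call(synthetic_truth,
                   c(list(heterochrony_shifts = shifts, seed = seed),
                     truth_args))
  sim <- simulate_clade(tree, truth,
                        juvenile_taxa = fixture_juvenile_taxa(),
                        seed = seed)
  config <- list(configs = sim$configs, tree = tree,
                 clades = fixture_clades(),
                 comparisons = fixture_comparisons(),
                 n_perm = n_perm, seed = seed)
  list(configs = sim$configs, tree = tree, truth = truth, sim = sim,
       clades = fixture_clades(), comparisons = fixture_comparisons(),
       juvenile_taxa = fixture_juvenile_taxa(), config = config)
}

#' Write the miniature study to disk as a fixture bundle
#'
#' Emits the complete miniature study as plain-text files: landmarks as
#' TPS and CSV, the calibrated tree as NEXUS, and a pipeline configuration
#' as JSON (referencing the CSV and NEXUS files by relative path).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the synthetic data.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- fixture_study(seed = seed)
  paths <- c(csv = file.path(dir, "landmarks.csv"),
             tps = file.path(dir, "landmarks.tps"),
             tree = file.path(dir, "tree.nex"),
             config = file.path(dir, "config.json"))
  write_landmark_csv(study$configs, paths[["csv"]])
  write_tps(study$configs, paths[["tps"]])
  write_nexus_tree(study$tree, paths[["tree"]])
  cfg <- list(landmarks = "landmarks.csv",
              semilandmarks = which(study$configs[[1L]]$is_semilandmark),
              tree = "tree.nex",
              clades = study$clades,
              comparisons = study$comparisons,
              n_perm = 999L, seed = seed)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Scree plot of a PCA result
#'
#' Bar plot of variance fractions with the broken-stick expectations
#' overlaid.
#'
#' @param pca a `pca_result`.
#' @param n_components number of leading components to show.
#' @return invisibly, the plotted fractions.
#' @export
plot_scree <- function(pca, n_components = 10L) {
  f <- utils::head(pca$variance_fractions, n_components)
  p <- pca$n_nonzero
  b <- (rev(cumsum(1 / rev(seq_len(p)))) / p)[seq_along(f)]
  bp <- graphics::barplot(f, names.arg = seq_along(f),
                          xlab = "Component", ylab = "Variance fraction")
  graphics::points(bp, b, pch = 19)
  graphics::lines(bp, b)
  invisible(f)
}

#' Wireframe plot of a shape
#'
#' Plots a configuration (or the GPA consensus) as points, with
#' semilandmarks distinguished from fixed landmarks.
#'
#' @param shape a `landmark_config`, an `aligned_sample` (consensus is
#'   drawn), or a shape vector/matrix.
#' @param ... forwarded to [graphics::plot()].
#' @return invisibly, the k x 2 coordinate matrix.
#' @export
plot_wireframe <- function(shape, ...) {
  mask <- NULL
  if (inherits(shape, "aligned_sample")) {
    mask <- shape$is_semilandmark
    shape <- unflatten_shape(shape$consensus)
  } else if (inherits(shape, "landmark_config")) {
    mask <- shape$is_semilandmark
    shape <- shape$coords
  } else if (!is.matrix(shape)) shape <- unflatten_shape(shape)
  graphics::plot(shape, asp = 1, pch = ifelse(isTRUE(mask), 1, 19),
                 xlab = "x", ylab = "y", ...)
  if (!is.null(mask)) {
    graphics::points(shape[!mask, , drop = FALSE], pch = 19)
    graphics::points(shape[mask, , drop = FALSE], pch = 1)
  }
  invisible(shape)
}
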