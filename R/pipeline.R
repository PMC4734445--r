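#' Run the full ontogeny/heterochrony analysis
#'
#' Executes the whole pipeline from one configuration: generalized
#' Procrustes superimposition of all specimens, PCA with broken-stick
#' component selection, multivariate regression of shape on log centroid
#' size with a permutation test, phylogenetic-signal tests (squared-change
#' parsimony tree length and multivariate K) of the adult shapes and
#' centroid sizes, ancestral reconstruction of adult states on the full
#' calibrated tree and of juvenile states on the pruned juvenile-bearing
#' tree, assembly of terminal and ancestral two-stage trajectories,
#' trajectory PCA, pooled within-group allometric regression with
#' regression-score and Euclidean-distance shape variables, branch-wise CI
#' thresholds, and paedomorphosis/peramorphosis calls for the configured
#' ancestor-descendant pairs.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{configs / landmarks}{list of `landmark_config` objects, or a
#'       path to a CSV/TPS landmark file (`semilandmarks` may give the
#'       mask for file input).}
#'     \item{tree}{a `time_tree`, or a path to a NEXUS/Newick file.}
#'     \item{tip_ages}{optional named tip ages (Myr); when present the
#'       tree is (re)calibrated with [calibrate_branch_lengths()].}
#'     \item{clades}{named list: clade name -> tip labels, defining the
#'       hypothetical ancestors.}
#'     \item{comparisons}{list of ancestor/descendant label pairs to
#'       classify.}
#'     \item{n_perm, seed}{permutation count (default 10000) and seed
#'       (default 1).}
#'     \item{reference_specimen}{optional id of the Euclidean-distance
#'       zero point (default: smallest specimen of the trajectory set).}
#'     \item{allow_reflection, tangent_project, scale_method}{GPA switches.}
#'     \item{output_dir}{optional directory for CSV/JSON exports.}
#'   }
#' @return object of class `onto_pipeline_result`; see the elements
#'   `sample`, `pca`, `regression`, `signal`, `adult_recon`,
#'   `juvenile_recon`, `trajectories`, `trajectory_pca`,
#'   `trajectory_regression`, `trajectory_table`, `ci`, `calls`,
#'   `call_table`, `provenance`.
#' @export
run_full_analysis <- function(config) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1L) {
    base_dir <- dirname(config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$comparisons) && is.matrix(config$comparisons))
      config$comparisons <- split(config$comparisons,
                                  seq_len(nrow(config$comparisons)))
  }
  cfg <- config
  resolve <- function(p)
    if (file.exists(p)) p else file.path(base_dir, p)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  n_perm <- if (is.null(cfg$n_perm)) 10000L else as.integer(cfg$n_perm)

  configs <- if (!is.null(cfg$configs)) cfg$configs else {
    if (is.null(cfg$landmarks)) stop("config lacks landmark input")
    lp <- resolve(cfg$landmarks)
    if (!file.exists(lp))
      stop("landmark file not found: ", cfg$landmarks)
    mask <- cfg$semilandmarks
    if (!is.null(mask)) mask <- as.integer(unlist(mask))
    if (grepl("\\.tps$", lp, ignore.case = TRUE))
      read_tps(lp, is_semilandmark = NULL)
    else read_landmark_csv(lp, is_semilandmark = mask)
  }
  validate_config_set(configs)

  tree <- cfg$tree
  if (is.character(tree)) {
    tp <- resolve(tree)
    if (!file.exists(tp)) stop("tree file not found: ", tree)
    tree <- read_nexus_tree(tp)
  }
  if (!is.null(cfg$tip_ages)) {
    ages <- unlist(cfg$tip_ages)
    tree <- calibrate_branch_lengths(
      if (inherits(tree, "time_tree")) tree$phylo else tree, ages,
      root_extension = if (is.null(cfg$root_extension)) 1 else cfg$root_extension)
  }
  if (!inherits(tree, "time_tree")) tree <- time_tree(tree)

  stages <- config_stages(configs)
  taxa <- config_taxa(configs)
  adult_idx <- which(stages == "adult")
  juv_idx <- which(stages == "juvenile")
  if (!length(adult_idx)) stop("no adult specimens in input")
  adult_taxa <- taxa[adult_idx]
  if (anyDuplicated(adult_taxa))
    stop("more than one adult specimen per taxon: ",
         paste(unique(adult_taxa[duplicated(adult_taxa)]), collapse = ", "))
  miss <- setdiff(tree$phylo$tip.label, normalize_labels(adult_taxa))
  if (length(miss))
    stop("tree tips without adult specimens: ", paste(miss, collapse = ", "))
  juvenile_taxa <- intersect(tree$phylo$tip.label,
                             normalize_labels(taxa[juv_idx]))

  # --- superimposition and whole-sample analyses -------------------------
  sample <- gpa(configs,
                allow_reflection = isTRUE(cfg$allow_reflection),
                tangent_project = !isFALSE(cfg$tangent_project),
                scale_method = if (is.null(cfg$scale_method)) "unit"
                               else cfg$scale_method)
  pca <- shape_pca(sample)
  regression <- regress_shape_on_size(sample, n_perm = n_perm, seed = seed)

  adult_rows <- adult_idx[match(tree$phylo$tip.label,
                                normalize_labels(adult_taxa))]
  adult_shapes <- sample$procrustes_coords[adult_rows, , drop = FALSE]
  rownames(adult_shapes) <- tree$phylo$tip.label
  adult_lcs <- stats::setNames(unname(sample$log_cs[adult_rows]),
                               tree$phylo$tip.label)

  signal <- if (isFALSE(cfg$run_signal_tests)) NULL else list(
    shape_permutation = permutation_signal_test(tree, adult_shapes,
                                                n_perm = n_perm,
                                                seed = seed + 1L),
    shape_k = k_mult(tree, adult_shapes, n_perm = n_perm, seed = seed + 2L),
    size_permutation = permutation_signal_test(tree, cbind(adult_lcs),
                                               n_perm = n_perm,
                                               seed = seed + 3L),
    size_k = k_mult(tree, cbind(adult_lcs), n_perm = n_perm, seed = seed + 4L))

  # --- ancestral reconstructions ----------------------------------------
  adult_states <- cbind(adult_shapes, log_cs = adult_lcs)
  adult_recon <- ancestral_states_scp(tree, adult_states)

  if (length(juvenile_taxa) < 2L)
    stop("need at least two juvenile-bearing taxa for ancestral trajectories")
  juv_tree <- prune_time_tree(tree, juvenile_taxa)
  juv_shapes <- t(vapply(juvenile_taxa, function(tx) {
    i <- which(normalize_labels(taxa) == tx & stages == "juvenile")[1L]
    sample$procrustes_coords[i, ]
  }, numeric(ncol(sample$procrustes_coords))))
  juv_lcs <- vapply(juvenile_taxa, function(tx) {
    i <- which(normalize_labels(taxa) == tx & stages == "juvenile")[1L]
    unname(sample$log_cs[i])
  }, numeric(1))
  juvenile_recon <- ancestral_states_scp(juv_tree,
                                         cbind(juv_shapes, log_cs = juv_lcs))

  # --- trajectories ------------------------------------------------------
  terminal <- lapply(juvenile_taxa, function(tx) {
    ontogenetic_trajectory(
      tx,
      juvenile = list(shape = juv_shapes[tx, ], log_cs = juv_lcs[[tx]]),
      adult = list(shape = adult_shapes[tx, ], log_cs = adult_lcs[[tx]]))
  })
  ancestral <- if (!is.null(cfg$clades) && length(cfg$clades))
    ancestral_trajectories(adult_recon, juvenile_recon, cfg$clades)
  else list()
  trajectories <- c(terminal, ancestral)
  names(trajectories) <- vapply(trajectories, `[[`, character(1), "label")

  traj_shapes <- do.call(rbind, lapply(trajectories, function(tr)
    rbind(tr$juvenile$shape, tr$adult$shape)))
  rownames(traj_shapes) <- as.vector(vapply(trajectories, function(tr)
    paste0(tr$label, c("_juv", "_ad")), character(2)))
  traj_lcs <- as.vector(vapply(trajectories, function(tr)
    c(tr$juvenile$log_cs, tr$adult$log_cs), numeric(2)))
  names(traj_lcs) <- rownames(traj_shapes)
  traj_groups <- rep(names(trajectories), each = 2L)

  trajectory_pca <- shape_pca(traj_shapes)
  trajectory_regression <- regress_shape_on_size(
    list(shapes = traj_shapes, log_cs = traj_lcs),
    groups = traj_groups, n_perm = n_perm, seed = seed + 5L)

  ref_id <- if (!is.null(cfg$reference_specimen)) cfg$reference_specimen
            else names(which.min(traj_lcs))
  ed_series <- euclidean_distance_variable(traj_shapes, reference_id = ref_id)
  ref_shape <- traj_shapes[ref_id, ]
  rs_vals <- stats::setNames(
    regression_score(traj_shapes, trajectory_regression),
    rownames(traj_shapes))

  n_pc <- max(2L, min(3L, trajectory_pca$n_significant))
  for (nm in names(trajectories)) {
    for (st in c("juvenile", "adult")) {
      row <- paste0(nm, if (st == "juvenile") "_juv" else "_ad")
      sc <- c(trajectory_pca$scores[row, seq_len(n_pc)],
              rs = unname(rs_vals[row]),
              ed = unname(ed_series$values[row]))
      trajectories[[nm]][[st]]$scores <- sc
    }
  }

  # --- CI thresholds over the adult supertree ---------------------------
  shape_cols <- setdiff(colnames(adult_states), "log_cs")
  node_shapes <- adult_recon$node_states[, shape_cols, drop = FALSE]
  rs_tips <- stats::setNames(
    regression_score(adult_shapes, trajectory_regression),
    rownames(adult_shapes))
  rs_nodes <- regression_score(node_shapes, trajectory_regression)
  ed_tips <- stats::setNames(
    sqrt(rowSums(sweep(adult_shapes, 2L, ref_shape)^2)),
    rownames(adult_shapes))
  ed_nodes <- sqrt(rowSums(sweep(node_shapes, 2L, ref_shape)^2))
  ci_method <- if (is.null(cfg$ci_method)) "t" else cfg$ci_method
  rs_diffs <- branch_differences(adult_recon, tip_values = rs_tips,
                                 node_values = rs_nodes)
  ed_diffs <- branch_differences(adult_recon, tip_values = ed_tips,
                                 node_values = ed_nodes)
  ci <- list(rs = ci_threshold(rs_diffs, method = ci_method),
             ed = ci_threshold(ed_diffs, method = ci_method),
             n_branches = length(rs_diffs))

  # --- heterochrony calls ------------------------------------------------
  calls <- list()
  if (!is.null(cfg$comparisons)) {
    for (pair in cfg$comparisons) {
      pair <- unlist(pair)
      if (!all(pair %in% names(trajectories)))
        stop("comparison refers to unknown trajectory: ",
             paste(pair, collapse = " -> "))
      calls[[paste(pair, collapse = " -> ")]] <-
        classify_heterochrony(trajectories[[pair[1L]]],
                              trajectories[[pair[2L]]],
                              ci_rs = ci$rs, ci_ed = ci$ed)
    }
  }

  result <- structure(list(
    sample = sample, pca = pca, regression = regression, signal = signal,
    adult_recon = adult_recon, juvenile_recon = juvenile_recon,
    trajectories = trajectories, trajectory_pca = trajectory_pca,
    trajectory_regression = trajectory_regression,
    trajectory_table = trajectory_table(trajectories),
    ci = ci, calls = calls, call_table = call_table(calls),
    reference_specimen = ref_id,
    provenance = list(seed = seed, n_perm = n_perm,
                      n_specimens = length(configs),
                      k = sample$k,
                      n_tips = length(tree$phylo$tip.label),
                      package_version = as.character(
                        utils::packageVersion("ontomorph")))),
    class = "onto_pipeline_result")
  if (!is.null(cfg$output_dir)) export_results(result, cfg$output_dir)
  result
}

#' @export
print.onto_pipeline_result <- function(x, ...) {
  cat("<onto_pipeline_result> ", x$provenance$n_specimens, " specimens, ",
      x$provenance$n_tips, " tree tips, ", length(x$trajectories),
      " trajectories, ", length(x$calls), " heterochrony calls\n", sep = "")
  invisible(x)
}

prune_time_tree <- function(tree, keep) {
  phy <- ape::keep.tip(tree$phylo, keep)
  time_tree(phy, tip_ages = tree$tip_ages[keep])
}

# Table of per-trajectory descriptors in the PC1-PC2 (and, where scored,
# PC1-PC3) planes plus RS/ED slopes against log CS.
trajectory_table <- function(trajectories) {
  rows <- lapply(trajectories, function(tr) {
    v12 <- change_vector(tr, c("PC1", "PC2"))
    has3 <- "PC3" %in% names(tr$adult$scores)
    v13 <- if (has3) change_vector(tr, c("PC1", "PC3")) else c(NA, NA)
    data.frame(
      label = tr$label,
      is_ancestral = tr$is_ancestral,
      log_cs_juvenile = tr$juvenile$log_cs,
      log_cs_adult = tr$adult$log_cs,
      angle_pc1_12 = trajectory_angle(v12, c(1, 0)),
      length_12 = trajectory_length(v12),
      angle_pc1_13 = if (has3) trajectory_angle(v13, c(1, 0)) else NA_real_,
      length_13 = if (has3) trajectory_length(v13) else NA_real_,
      rs_slope = trajectory_slope(c(tr$juvenile$log_cs, tr$juvenile$scores["rs"]),
                                  c(tr$adult$log_cs, tr$adult$scores["rs"])),
      ed_slope = trajectory_slope(c(tr$juvenile$log_cs, tr$juvenile$scores["ed"]),
                                  c(tr$adult$log_cs, tr$adult$scores["ed"])),
      row.names = NULL)
  })
  do.call(rbind, rows)
}

call_table <- function(calls) {
  if (!length(calls)) return(data.frame())
  do.call(rbind, lapply(calls, function(cl)
    data.frame(ancestor = cl$ancestor, descendant = cl$descendant,
               delta_rs = cl$delta_rs, delta_ed = cl$delta_ed,
               rs_significant = cl$rs_significant,
               ed_significant = cl$ed_significant,
               classification = cl$classification, row.names = NULL)))
}

#' Pairwise angles between trajectory change vectors
#'
#' @param trajectories named list of `onto_trajectory` objects with scored
#'   stages.
#' @param traits trait axes, default `c("PC1", "PC2")`.
#' @return symmetric matrix of angles in degrees.
#' @export
pairwise_trajectory_angles <- function(trajectories, traits = c("PC1", "PC2")) {
  vecs <- lapply(trajectories, change_vector, traits = traits)
  nms <- names(trajectories)
  A <- matrix(0, length(vecs), length(vecs), dimnames = list(nms, nms))
  for (i in seq_along(vecs))
    for (j in seq_along(vecs))
      if (i != j) A[i, j] <- trajectory_angle(vecs[[i]], vecs[[j]])
  A
}

#' Export pipeline results as CSV/JSON files
#'
#' Writes aligned coordinates, centroid sizes, PCA scores and eigenvalues,
#' the trajectory table, the heterochrony call table, ancestral states and
#' a JSON summary (signal tests, regression, CI thresholds, provenance).
#'
#' @param result an `onto_pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = TRUE)
  w(result$sample$procrustes_coords, "procrustes_coords.csv")
  w(data.frame(centroid_size = result$sample$centroid_sizes,
               log_cs = result$sample$log_cs), "centroid_sizes.csv")
  w(result$pca$scores, "pca_scores.csv")
  utils::write.csv(data.frame(eigenvalue = result$pca$eigenvalues),
                   file.path(dir, "pca_eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(result$trajectory_table,
                   file.path(dir, "trajectory_table.csv"), row.names = FALSE)
  if (nrow(result$call_table))
    utils::write.csv(result$call_table,
                     file.path(dir, "heterochrony_calls.csv"),
                     row.names = FALSE)
  w(result$adult_recon$node_states, "adult_ancestral_states.csv")
  w(result$juvenile_recon$node_states, "juvenile_ancestral_states.csv")
  summary <- list(
    regression = list(percent_predicted = result$regression$percent_predicted,
                      permutation_p = result$regression$permutation_p),
    signal = lapply(result$signal, function(s)
      list(statistic = s$statistic, p_value = s$p_value)),
    trajectory_pca = list(
      variance_fractions = result$trajectory_pca$variance_fractions,
      n_significant = result$trajectory_pca$n_significant),
    ci = result$ci[c("rs", "ed", "n_branches")],
    reference_specimen = result$reference_specimen,
    provenance = result$provenance)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Export the GPA consensus as a wireframe CSV
#'
#' @param sample an `aligned_sample`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_consensus_wireframe <- function(sample, path) {
  m <- unflatten_shape(sample$consensus)
  utils::write.csv(data.frame(landmark = seq_len(nrow(m)),
                              x = m[, 1L], y = m[, 2L],
                              is_semilandmark = sample$is_semilandmark),
                   path, row.names = FALSE)
  invisible(path)
}
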