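#' Two-stage ontogenetic trajectory
#'
#' A juvenile and an adult observation of one taxon (or one reconstructed
#' hypothetical ancestor), each carrying an aligned shape vector, a log
#' centroid size, and optionally scalar shape variables (e.g. regression
#' score `rs`, Euclidean distance `ed`, PC scores). Both stages must come
#' from one common GPA for the derived descriptors to be meaningful.
#'
#' @param label taxon or clade name.
#' @param juvenile,adult lists with elements `shape` (numeric vector),
#'   `log_cs` (scalar) and optionally `scores` (named numeric).
#' @param is_ancestral whether the stages are reconstructed ancestral
#'   states rather than observed specimens.
#' @param check_size assert adult CS > juvenile CS (default `TRUE`).
#' @return object of class `onto_trajectory`.
#' @export
ontogenetic_trajectory <- function(label, juvenile, adult,
                                   is_ancestral = FALSE, check_size = TRUE) {
  for (st in list(juvenile, adult))
    if (!is.list(st) || !all(c("shape", "log_cs") %in% names(st)))
      stop("each stage must be a list with 'shape' and 'log_cs'")
  if (length(juvenile$shape) != length(adult$shape))
    stop("juvenile and adult shapes have different dimension")
  if (check_size && adult$log_cs <= juvenile$log_cs)
    stop("trajectory '", label, "': adult log CS (", adult$log_cs,
         ") is not larger than juvenile (", juvenile$log_cs,
         "); set check_size = FALSE to override")
  structure(list(label = label, juvenile = juvenile, adult = adult,
                 is_ancestral = is_ancestral),
            class = "onto_trajectory")
}

#' @export
print.onto_trajectory <- function(x, ...) {
  cat("<onto_trajectory> ", x$label,
      if (x$is_ancestral) " (ancestral)" else "",
      ": log CS ", format(x$juvenile$log_cs, digits = 4), " -> ",
      format(x$adult$log_cs, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Phenotypic change vector of a trajectory
#'
#' Componentwise adult minus juvenile difference on the requested trait
#' axes; the vector points from the juvenile to the adult stage.
#'
#' @param traj an `onto_trajectory` whose stages carry `scores`.
#' @param traits names (or indices) of the trait axes, e.g.
#'   `c("PC1", "PC2")`.
#' @return numeric vector, one entry per trait.
#' @export
change_vector <- function(traj, traits) {
  for (st in c("juvenile", "adult")) {
    sc <- traj[[st]]$scores
    if (is.null(sc)) stop("stage '", st, "' has no trait scores")
    if (is.character(traits) && !all(traits %in% names(sc)))
      stop("stage '", st, "' lacks traits: ",
           paste(setdiff(traits, names(sc)), collapse = ", "))
  }
  unname(traj$adult$scores[traits] - traj$juvenile$scores[traits])
}

#' Angle between two phenotypic change vectors
#'
#' arccos of the normalized dot product, in degrees, in the closed range
#' 0 to 180.
#'
#' @param a,b numeric vectors (same length, both nonzero).
#' @return angle in degrees.
#' @export
trajectory_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na <= .Machine$double.eps || nb <= .Machine$double.eps)
    stop("undefined angle: zero-length change vector")
  dot <- sum(a * b)
  # atan2 form of the dot-product angle, with the orthogonal rejection
  # computed directly: exact at 0, 90 and 180 degrees
  rej <- b - (dot / na^2) * a
  atan2(sqrt(sum(rej^2)) * na, dot) * 180 / pi
}

#' Length of a phenotypic change vector
#'
#' @param v numeric change vector (two traits or a full shape difference).
#' @return Euclidean norm of `v`.
#' @export
trajectory_length <- function(v) sqrt(sum(v^2))

#' Pair ancestral reconstructions into ancestral trajectories
#'
#' For each named clade, pairs the adult state reconstructed on the full
#' tree with the juvenile state reconstructed on the pruned
#' (juvenile-bearing) tree into an ancestral two-stage trajectory. The
#' clade-to-node map gives, per clade name, a vector of tip labels whose
#' most recent common ancestor is the clade's node; labels absent from a
#' tree are dropped before taking the MRCA, and a clade resolving in only
#' one of the trees is an error. State matrices must carry a `log_cs`
#' column; the remaining columns are the shape coordinates.
#'
#' @param adult_recon `ancestral_recon` on the full tree (adult states,
#'   including a `log_cs` column).
#' @param juvenile_recon `ancestral_recon` on the pruned tree (juvenile
#'   states, same layout).
#' @param clades named list: clade name -> character vector of tip labels.
#' @return list of `onto_trajectory` objects flagged `is_ancestral`.
#' @export
ancestral_trajectories <- function(adult_recon, juvenile_recon, clades) {
  stopifnot(inherits(adult_recon, "ancestral_recon"),
            inherits(juvenile_recon, "ancestral_recon"))
  lapply(names(clades), function(nm) {
    ad <- recon_node_state(adult_recon, clades[[nm]], nm)
    ju <- recon_node_state(juvenile_recon, clades[[nm]], nm)
    ontogenetic_trajectory(
      nm,
      juvenile = list(shape = ju$shape, log_cs = ju$log_cs),
      adult = list(shape = ad$shape, log_cs = ad$log_cs),
      is_ancestral = TRUE, check_size = FALSE)
  })
}

recon_node_state <- function(recon, tips, clade_name) {
  phy <- recon$tree$phylo
  tips <- intersect(normalize_labels(tips), phy$tip.label)
  if (length(tips) < 1L)
    stop("clade '", clade_name, "' has no tips in tree")
  node <- if (length(tips) == 1L)
    phy$edge[phy$edge[, 2L] == match(tips, phy$tip.label), 1L]
  else ape::getMRCA(phy, tips)
  if (is.null(node) || !length(node))
    stop("clade '", clade_name, "' not resolvable in tree")
  row <- node - length(phy$tip.label)
  states <- recon$node_states[row, ]
  if (!"log_cs" %in% names(states))
    stop("reconstruction lacks a 'log_cs' column")
  list(shape = states[names(states) != "log_cs"],
       log_cs = unname(states["log_cs"]))
}

#' Per-branch differences of a node-valued scalar
#'
#' Child minus parent difference of a scalar variable over every branch of
#' the tree; with n tips this yields 2n - 2 values, the population over
#' which the significance threshold for heterochrony calls is computed.
#'
#' @param recon an `ancestral_recon`.
#' @param tip_values named scalar per tip.
#' @param node_values scalar per internal node, in node order of
#'   `recon$node_states` (defaults to a column of the reconstruction named
#'   by `column`).
#' @param column column of the state matrices to difference when explicit
#'   values are not given.
#' @return numeric vector of length 2n - 2.
#' @export
branch_differences <- function(recon, tip_values = NULL, node_values = NULL,
                               column = NULL) {
  phy <- recon$tree$phylo
  n <- length(phy$tip.label)
  if (is.null(tip_values)) {
    stopifnot(!is.null(column))
    tip_values <- recon$tip_states[, column]
  } else tip_values <- tip_values[phy$tip.label]
  if (is.null(node_values)) {
    stopifnot(!is.null(column))
    node_values <- recon$node_states[, column]
  }
  all_vals <- c(tip_values, node_values)
  unname(all_vals[phy$edge[, 2L]] - all_vals[phy$edge[, 1L]])
}

#' Significance threshold for ancestor-descendant shape change
#'
#' Half-width of the two-sided confidence interval of the mean branch-wise
#' difference, by default the t-based interval
#' t(1 - (1-level)/2, m - 1) * sd / sqrt(m); an empirical-quantile
#' alternative (half the central `level` range of the differences) is
#' available behind `method = "quantile"`.
#'
#' @param branch_diffs numeric vector of branch-wise differences (length
#'   >= 2; for an n-tip supertree there are 2n - 2 of them).
#' @param level confidence level (default 0.95).
#' @param method `"t"` (default) or `"quantile"`.
#' @return nonnegative scalar threshold.
#' @export
ci_threshold <- function(branch_diffs, level = 0.95,
                         method = c("t", "quantile")) {
  method <- match.arg(method)
  m <- length(branch_diffs)
  if (m < 2L) stop("need at least 2 branch differences")
  if (method == "t") {
    stats::qt(1 - (1 - level) / 2, df = m - 1L) *
      stats::sd(branch_diffs) / sqrt(m)
  } else {
    q <- stats::quantile(branch_diffs, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    (q[2L] - q[1L]) / 2
  }
}

#' Classify an ancestor-descendant pair as paedo- or peramorphic
#'
#' Compares the adult stages of two trajectories on both scalar shape
#' variables (regression score `rs` and Euclidean distance `ed`, stored in
#' each stage's `scores`). A change is significant when |delta| is at
#' least `factor` (default 1.5) times the corresponding CI threshold.
#' Both variables significant and negative: paedomorphosis (the descendant
#' adult retains lower, more juvenile shape values). Both significant and
#' positive: peramorphosis. Anything else: undetermined.
#'
#' @param ancestor,descendant `onto_trajectory` objects whose adult stages
#'   carry `rs` and `ed` scores from a common regression/reference.
#' @param ci_rs,ci_ed CI thresholds for the two shape variables.
#' @param factor significance multiplier (default 1.5).
#' @return object of class `heterochrony_call` with `ancestor`,
#'   `descendant`, `delta_rs`, `delta_ed`, `ci_rs`, `ci_ed`,
#'   `rs_significant`, `ed_significant`, `classification`.
#' @export
classify_heterochrony <- function(ancestor, descendant, ci_rs, ci_ed,
                                  factor = 1.5) {
  for (tr in list(ancestor, descendant)) {
    sc <- tr$adult$scores
    if (is.null(sc) || !all(c("rs", "ed") %in% names(sc)))
      stop("trajectory '", tr$label,
           "': adult stage lacks 'rs'/'ed' shape variables")
  }
  delta_rs <- unname(descendant$adult$scores["rs"] - ancestor$adult$scores["rs"])
  delta_ed <- unname(descendant$adult$scores["ed"] - ancestor$adult$scores["ed"])
  rs_sig <- abs(delta_rs) >= factor * ci_rs
  ed_sig <- abs(delta_ed) >= factor * ci_ed
  classification <- if (rs_sig && ed_sig && delta_rs < 0 && delta_ed < 0)
    "paedomorphosis"
  else if (rs_sig && ed_sig && delta_rs > 0 && delta_ed > 0)
    "peramorphosis"
  else "undetermined"
  structure(list(ancestor = ancestor$label, descendant = descendant$label,
                 delta_rs = delta_rs, delta_ed = delta_ed,
                 ci_rs = ci_rs, ci_ed = ci_ed,
                 rs_significant = rs_sig, ed_significant = ed_sig,
                 classification = classification),
            class = "heterochrony_call")
}

#' @export
print.heterochrony_call <- function(x, ...) {
  cat("<heterochrony_call> ", x$ancestor, " -> ", x$descendant, ": ",
      x$classification,
      " (dRS = ", format(x$delta_rs, digits = 3),
      if (x$rs_significant) "*" else "",
      ", dED = ", format(x$delta_ed, digits = 3),
      if (x$ed_significant) "*" else "", ")\n", sep = "")
  invisible(x)
}
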