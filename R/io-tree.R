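#' Time-calibrated phylogeny
#'
#' Wraps an `ape::phylo` tree with branch lengths in millions of years (Myr)
#' and tip ages in Myr before present. The tree must be rooted and fully
#' bifurcating: with n tips it has exactly 2n - 2 branches and n - 1
#' internal nodes.
#'
#' @param phy an `ape::phylo` object with branch lengths.
#' @param tip_ages optional named numeric vector of tip ages (Myr before
#'   present); names matched to tip labels. Defaults to 0 for all tips.
#' @param root_age optional root age in Myr before present; computed from
#'   tip ages and branch lengths when omitted.
#' @return an object of class `time_tree` with fields `phylo`, `tip_ages`,
#'   `root_age`.
#' @export
time_tree <- function(phy, tip_ages = NULL, root_age = NULL) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("tree contains polytomies or is unrooted; the pipeline requires ",
         "rooted, fully bifurcating trees")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths")
  n <- length(phy$tip.label)
  stopifnot(nrow(phy$edge) == 2L * n - 2L)
  phy$tip.label <- normalize_labels(phy$tip.label)
  if (is.null(tip_ages)) {
    tip_ages <- stats::setNames(rep(0, n), phy$tip.label)
  } else {
    names(tip_ages) <- normalize_labels(names(tip_ages))
    if (!all(phy$tip.label %in% names(tip_ages)))
      stop("tip ages missing for: ",
           paste(setdiff(phy$tip.label, names(tip_ages)), collapse = ", "))
    tip_ages <- tip_ages[phy$tip.label]
  }
  if (is.null(root_age)) {
    depths <- ape::node.depth.edgelength(phy)      # root-to-node path lengths
    root_age <- max(tip_ages + max(depths[seq_len(n)]) - depths[seq_len(n)])
  }
  structure(list(phylo = phy, tip_ages = tip_ages, root_age = root_age),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat("<time_tree> ", length(x$phylo$tip.label), " tips, ",
      nrow(x$phylo$edge), " branches, root age ",
      format(x$root_age, digits = 6), " Myr\n", sep = "")
  invisible(x)
}

normalize_labels <- function(x) gsub("\\s+", "_", trimws(x))

#' Read a time tree from a NEXUS or Newick file
#'
#' Reads the first tree of a NEXUS `TREES` block (Newick files are also
#' accepted), normalizes whitespace in labels to underscores, and checks
#' the bifurcation requirement. Zero-length branches trigger a warning;
#' the caller is expected to run [calibrate_branch_lengths()].
#'
#' @param path path to a NEXUS or Newick file.
#' @param tip_ages optional named tip ages (Myr before present).
#' @return a [time_tree()].
#' @export
read_nexus_tree <- function(path, tip_ages = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  phy <- tryCatch(ape::read.nexus(path), error = function(e) NULL)
  if (is.null(phy)) phy <- ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (is.null(phy)) stop("could not parse a tree from ", path)
  if (!is.null(phy$edge.length) && any(phy$edge.length <= 0))
    warning("tree contains zero or negative branch lengths; ",
            "run calibrate_branch_lengths() before comparative analyses")
  time_tree(phy, tip_ages = tip_ages)
}

#' Write a time tree to NEXUS
#'
#' @param tree a `time_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus_tree <- function(tree, path) {
  ape::write.nexus(tree$phylo, file = path)
  invisible(path)
}

# Node ages (Myr before present) for every node of a time_tree,
# indexed 1..(2n-1) in ape numbering.
node_ages <- function(tree) {
  phy <- tree$phylo
  depths <- ape::node.depth.edgelength(phy)
  tree$root_age - depths
}
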