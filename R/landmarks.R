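#' Landmark configuration for one specimen
#'
#' Container for a single specimen's raw 2D landmark coordinates together
#' with its identifiers, ontogenetic stage and semilandmark flags.
#' Coordinates are planar, y up, x along the anteroposterior axis, in
#' arbitrary digitizing units; all specimens of a data set must be digitized
#' facing the same direction because reflections are disallowed during
#' superimposition.
#'
#' @param coords numeric k x 2 matrix of landmark coordinates (k >= 3,
#'   no missing values).
#' @param specimen_id character scalar identifying the specimen.
#' @param taxon character scalar; defaults to `specimen_id`.
#' @param stage ontogenetic stage, `"juvenile"`, `"adult"` or `NA`.
#' @param is_semilandmark logical vector of length k flagging semilandmarks;
#'   defaults to all `FALSE`.
#' @param scale optional units-per-coordinate factor (e.g. from a TPS
#'   `SCALE=` record). Stored, never applied implicitly.
#' @return an object of class `landmark_config`.
#' @export
landmark_configuration <- function(coords, specimen_id, taxon = specimen_id,
                                   stage = NA_character_,
                                   is_semilandmark = NULL, scale = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("'coords' must be a k x 2 matrix, got ", ncol(coords), " columns")
  if (nrow(coords) < 3L)
    stop("a landmark configuration needs at least 3 landmarks")
  if (anyNA(coords))
    stop("missing coordinates in specimen '", specimen_id, "'")
  k <- nrow(coords)
  if (is.null(is_semilandmark)) is_semilandmark <- rep(FALSE, k)
  if (length(is_semilandmark) != k)
    stop("'is_semilandmark' must have length k = ", k)
  if (!is.na(stage) && !stage %in% c("juvenile", "adult"))
    stop("'stage' must be \"juvenile\", \"adult\" or NA")
  structure(
    list(specimen_id = as.character(specimen_id),
         taxon = as.character(taxon),
         stage = as.character(stage),
         coords = unname(coords),
         is_semilandmark = as.logical(is_semilandmark),
         scale = if (is.null(scale)) NULL else as.numeric(scale)),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> ", x$specimen_id,
      " (", x$taxon, ", ", x$stage, "): ",
      nrow(x$coords), " landmarks (",
      sum(x$is_semilandmark), " semilandmarks)\n", sep = "")
  invisible(x)
}

#' Flatten a k x 2 coordinate matrix to a shape vector
#'
#' Shape vectors interleave coordinates as (x1, y1, x2, y2, ..., xk, yk),
#' matching the CSV column order used throughout the package.
#'
#' @param coords k x 2 matrix or a `landmark_config`.
#' @return numeric vector of length 2k.
#' @export
flatten_shape <- function(coords) {
  if (inherits(coords, "landmark_config")) coords <- coords$coords
  as.vector(t(coords))
}

#' Rebuild a k x 2 coordinate matrix from a shape vector
#'
#' @param v numeric vector of length 2k, interleaved (x1, y1, ...).
#' @return k x 2 matrix.
#' @export
unflatten_shape <- function(v) {
  if (length(v) %% 2L != 0L) stop("shape vector length must be even")
  matrix(v, ncol = 2L, byrow = TRUE)
}

# Shared validation for a set of configurations: constant k and constant
# semilandmark mask, or fail loudly naming the offender.
validate_config_set <- function(configs) {
  if (!length(configs)) stop("empty configuration set")
  ks <- vapply(configs, function(cf) nrow(cf$coords), integer(1))
  if (length(unique(ks)) != 1L) {
    bad <- which(ks != ks[1])[1]
    stop("inconsistent landmark count: specimen '",
         configs[[bad]]$specimen_id, "' has ", ks[bad],
         " landmarks, expected ", ks[1])
  }
  masks <- vapply(configs, function(cf) paste(as.integer(cf$is_semilandmark),
                                              collapse = ""), character(1))
  if (length(unique(masks)) != 1L)
    stop("semilandmark mask differs across specimens")
  invisible(ks[1])
}

config_ids <- function(configs) vapply(configs, `[[`, character(1), "specimen_id")
config_taxa <- function(configs) vapply(configs, `[[`, character(1), "taxon")
config_stages <- function(configs) vapply(configs, `[[`, character(1), "stage")
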