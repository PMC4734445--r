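#' Read landmark configurations from a TPS file
#'
#' Parses the TPS records produced by standard 2D digitizing software:
#' `LM=` starts a specimen record and is followed by that many coordinate
#' lines, optionally followed by `IMAGE=`, `ID=` and `SCALE=` records.
#' Coordinates use the standard TPS orientation (origin bottom-left, y up)
#' and are returned raw; `SCALE=` factors are stored in the `scale` field
#' for the caller to apply.
#'
#' @param path path to a TPS file.
#' @param is_semilandmark optional logical mask applied to every specimen.
#' @return list of [landmark_configuration()] objects, in file order.
#' @export
read_tps <- function(path, is_semilandmark = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  configs <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop("malformed TPS file: expected 'LM=' at line ", i,
           ", got: ", lines[i])
    rec <- rec + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("malformed TPS record ", rec, ": bad landmark count in '",
           lines[i], "'")
    i <- i + 1L
    if (i + k - 1L > length(lines))
      stop("malformed TPS record ", rec, ": fewer than ", k,
           " coordinate lines")
    coords <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (length(xy) != 2L || anyNA(xy))
        stop("malformed TPS record ", rec, ": coordinate line ", j,
             " is not an x/y pair: '", lines[i], "'")
      coords[j, ] <- xy
      i <- i + 1L
    }
    id <- NULL; image <- NULL; scale <- NULL
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE))
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE))
        image <- sub("^IMAGE\\s*=\\s*", "", ln, ignore.case = TRUE)
      else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE))
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln, ignore.case = TRUE))
      i <- i + 1L
    }
    if (is.null(id) || !nzchar(id))
      id <- if (!is.null(image) && nzchar(image)) image else paste0("specimen_", rec)
    configs[[length(configs) + 1L]] <-
      landmark_configuration(coords, specimen_id = id,
                             is_semilandmark = is_semilandmark,
                             scale = scale)
  }
  validate_config_set(configs)
  configs
}

#' Write landmark configurations to a TPS file
#'
#' @param configs list of `landmark_config` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  validate_config_set(configs)
  out <- character(0)
  for (cf in configs) {
    out <- c(out,
             paste0("LM=", nrow(cf$coords)),
             apply(cf$coords, 1L, function(r)
               paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = " ")),
             paste0("ID=", cf$specimen_id))
    if (!is.null(cf$scale)) out <- c(out, paste0("SCALE=", cf$scale))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read landmark configurations from CSV
#'
#' Expects the documented header `specimen, taxon, stage, x1, y1, ..., xk, yk`.
#' Round-trips bit-exactly with [write_landmark_csv()] for finite decimal
#' input.
#'
#' @param path CSV path.
#' @param is_semilandmark optional logical mask (length k) or integer vector
#'   of semilandmark indices.
#' @return list of `landmark_config` objects.
#' @export
read_landmark_csv <- function(path, is_semilandmark = NULL) {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("specimen", "taxon", "stage")
  if (!all(need %in% names(df)))
    stop("CSV header must start with: specimen, taxon, stage")
  coord_cols <- setdiff(names(df), need)
  k <- length(coord_cols) / 2L
  if (k != floor(k) || k < 3L)
    stop("CSV must contain x1,y1,...,xk,yk coordinate columns")
  exp_cols <- as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k)))
  if (!identical(coord_cols, exp_cols))
    stop("coordinate columns must be named x1,y1,...,x", k, ",y", k)
  mask <- normalize_mask(is_semilandmark, k)
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.numeric(df[i, coord_cols])
    if (anyNA(row))
      stop("missing coordinate for specimen '", df$specimen[i],
           "' at landmark ", ceiling(which(is.na(row))[1] / 2))
    landmark_configuration(unflatten_shape(row),
                           specimen_id = df$specimen[i],
                           taxon = df$taxon[i],
                           stage = df$stage[i],
                           is_semilandmark = mask)
  })
}

#' Write landmark configurations to CSV
#'
#' @param configs list of `landmark_config` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(configs, path) {
  k <- validate_config_set(configs)
  mat <- t(vapply(configs, flatten_shape, numeric(2L * k)))
  # full double precision so the round trip is bit-exact
  chr <- apply(mat, 2L, function(col) formatC(col, digits = 17, format = "g"))
  colnames(chr) <- as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k)))
  df <- data.frame(specimen = config_ids(configs),
                   taxon = config_taxa(configs),
                   stage = config_stages(configs),
                   chr, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

normalize_mask <- function(is_semilandmark, k) {
  if (is.null(is_semilandmark)) return(rep(FALSE, k))
  if (is.logical(is_semilandmark)) {
    if (length(is_semilandmark) != k)
      stop("semilandmark mask length ", length(is_semilandmark),
           " does not match k = ", k)
    return(is_semilandmark)
  }
  idx <- as.integer(is_semilandmark)
  if (any(idx < 1L | idx > k)) stop("semilandmark indices out of range 1..", k)
  mask <- rep(FALSE, k)
  mask[idx] <- TRUE
  mask
}
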