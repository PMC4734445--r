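#' Read landmark data from a MorphoJ text export
#'
#' MorphoJ project files are an undocumented dialect; this reader is
#' best-effort and targets the tab-separated text export of a raw-coordinate
#' dataset: a header line with an `Id` column, optional classifier columns
#' (`taxon`, `stage`, case-insensitive), and an even number of coordinate
#' columns in x/y order. Analyses stored in a project are ignored. Binary
#' or compressed containers are rejected with advice to export to TPS/CSV.
#'
#' @param path path to the exported text file.
#' @param is_semilandmark optional semilandmark mask or index vector.
#' @return list with elements `configs` (list of `landmark_config`) and
#'   `tree` (always `NULL`; trees travel separately as NEXUS).
#' @export
read_morphoj_project <- function(path, is_semilandmark = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_raw <- readBin(path, "raw", n = 4L)
  is_zip <- length(head_raw) >= 2L && head_raw[1] == as.raw(0x50) &&
    head_raw[2] == as.raw(0x4b)
  is_gz <- length(head_raw) >= 2L && head_raw[1] == as.raw(0x1f) &&
    head_raw[2] == as.raw(0x8b)
  if (is_zip || is_gz || any(head_raw == as.raw(0)))
    stop("unrecognized MorphoJ container (binary/compressed); ",
         "export the dataset from MorphoJ as a text file, or use ",
         "TPS/CSV input instead")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  id_col <- which(nm %in% c("id", "specimen", "name"))[1]
  if (is.na(id_col))
    stop("unrecognized MorphoJ export: no Id column; ",
         "use TPS/CSV input instead")
  taxon_col <- which(nm == "taxon")[1]
  stage_col <- which(nm == "stage")[1]
  num_cols <- which(vapply(df, is.numeric, logical(1)))
  num_cols <- setdiff(num_cols, c(id_col, taxon_col, stage_col))
  if (length(num_cols) < 6L || length(num_cols) %% 2L != 0L)
    stop("unrecognized MorphoJ export: expected an even number (>= 6) of ",
         "coordinate columns; use TPS/CSV input instead")
  k <- length(num_cols) %/% 2L
  mask <- normalize_mask(is_semilandmark, k)
  if (is.na(stage_col))
    warning("MorphoJ export has no 'stage' classifier; stages left unset")
  configs <- lapply(seq_len(nrow(df)), function(i) {
    landmark_configuration(
      unflatten_shape(as.numeric(df[i, num_cols])),
      specimen_id = as.character(df[[id_col]][i]),
      taxon = if (is.na(taxon_col)) as.character(df[[id_col]][i])
              else as.character(df[[taxon_col]][i]),
      stage = if (is.na(stage_col)) NA_character_
              else as.character(df[[stage_col]][i]),
      is_semilandmark = mask)
  })
  validate_config_set(configs)
  list(configs = configs, tree = NULL)
}
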