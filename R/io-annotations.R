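# Annotation file readers. All coordinates are 1-based (row, col), matching
# R matrix indexing. Malformed rows are reported with their file line
# numbers (line 1 is the header).

.readAnnotationCSV <- function(path, columns, numeric_cols, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    atStop(sprintf("cannot read %s file '%s': file does not exist",
                   what, as.character(path)[1L]),
           "adipotrace_input_error")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character"),
                 error = function(e)
                   atStop(sprintf("cannot parse %s file '%s': %s", what, path,
                                  conditionMessage(e)),
                          "adipotrace_input_error"))
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols))
    atStop(sprintf("%s file '%s' lacks column(s): %s", what, path,
                   paste(missing_cols, collapse = ", ")),
           "adipotrace_input_error")
  df <- df[, columns, drop = FALSE]
  bad <- rep(FALSE, nrow(df))
  for (cc in numeric_cols) {
    val <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- bad | is.na(val)
    df[[cc]] <- val
  }
  bad <- bad | is.na(df$cell_id) | df$cell_id == ""
  if (any(bad))
    atStop(sprintf("%s file '%s' has malformed row(s) at line(s): %s",
                   what, path, paste(which(bad) + 1L, collapse = ", ")),
           "adipotrace_input_error")
  df
}

#' Read trace-mode seed points
#'
#' Seed file format: CSV with header `cell_id,row,col`; coordinates are
#' 1-based integer pixel positions, one row per cell (one click each).
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `cell_id`, `row`, `col`.
#' @export
readSeedCSV <- function(path) {
  df <- .readAnnotationCSV(path, c("cell_id", "row", "col"),
                           c("row", "col"), "seed")
  if (any(df$row != round(df$row) | df$col != round(df$col)))
    atStop(sprintf("seed file '%s' has non-integer coordinates at line(s): %s",
                   path,
                   paste(which(df$row != round(df$row) |
                               df$col != round(df$col)) + 1L, collapse = ", ")),
           "adipotrace_input_error")
  df$row <- as.integer(df$row); df$col <- as.integer(df$col)
  df
}

#' Read hand-trace polygon vertices
#'
#' Vertex file format: CSV with header `cell_id,vertex_index,row,col`;
#' several rows per cell, ordered by `vertex_index`; coordinates are
#' 1-based and may be fractional.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `cell_id`, `vertex_index`, `row`, `col`.
#' @export
readVertexCSV <- function(path) {
  .readAnnotationCSV(path, c("cell_id", "vertex_index", "row", "col"),
                     c("vertex_index", "row", "col"), "vertex")
}

#' Read ellipse-approximation annotations
#'
#' Ellipse file format: CSV with header
#' `cell_id,p1_row,p1_col,p2_row,p2_col,b`: the two clicked major-axis
#' endpoints and the semi-minor length in pixels, one row per cell.
#'
#' @param path path to the CSV file.
#' @return data.frame with the columns above, numeric.
#' @export
readEllipseCSV <- function(path) {
  .readAnnotationCSV(path,
                     c("cell_id", "p1_row", "p1_col", "p2_row", "p2_col", "b"),
                     c("p1_row", "p1_col", "p2_row", "p2_col", "b"), "ellipse")
}

#' Read a JSON run configuration
#'
#' A run configuration mirrors the arguments of [runMeasure()]:
#' `image`, `method` (`"tm"`, `"ht"` or `"ea"`), `annotations`,
#' `microns_per_pixel`, `out_dir`, optional `overlay`, `run_index`,
#' `max_area_frac`, and a `transform` block with any of `shadows`,
#' `low_level_in`, `binary_threshold`, `despeckle_radius`,
#' `despeckle_passes` (defaults are the published operating point).
#'
#' @param path path to a JSON file.
#' @return a named list suitable for `do.call(runMeasure, ...)` after path
#'   resolution.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    atStop(sprintf("config file '%s' does not exist", path),
           "adipotrace_input_error")
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    atStop(sprintf("cannot parse config '%s': %s", path,
                                   conditionMessage(e)),
                           "adipotrace_input_error"))
  if (!is.null(cfg$method)) cfg$method <- tolower(cfg$method)
  if (!is.null(cfg$transform)) {
    tr <- cfg$transform
    cfg$params <- TransformParams(
      shadows = tr$shadows %||% 0.15,
      lowLevelIn = tr$low_level_in %||% 0.9,
      binaryThreshold = tr$binary_threshold %||% 0.8,
      despeckleRadius = tr$despeckle_radius %||% 5L,
      despecklePasses = tr$despeckle_passes %||% 5L)
    cfg$transform <- NULL
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
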