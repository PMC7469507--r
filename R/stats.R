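# Measurement summaries: tables, size histograms, repeatability, and
# pairwise method concordance.

#' Tabulate a collection of cell measurements
#'
#' @param measurements a list of [CellMeasurement] objects (a single object
#'   is accepted).
#' @return data.frame with columns `cell_id`, `method`, `run_index`,
#'   `area_px`, `area_um2`, `flags` (comma-joined, empty when clean).
#' @export
measurementTable <- function(measurements) {
  if (is(measurements, "CellMeasurement")) measurements <- list(measurements)
  if (!length(measurements))
    return(data.frame(cell_id = character(0), method = character(0),
                      run_index = integer(0), area_px = numeric(0),
                      area_um2 = numeric(0), flags = character(0),
                      stringsAsFactors = FALSE))
  ok <- vapply(measurements, function(m) is(m, "CellMeasurement"), logical(1))
  if (!all(ok))
    atStop("all elements must be CellMeasurement objects",
           "adipotrace_validation_error")
  data.frame(
    cell_id = vapply(measurements, cellLabel, character(1)),
    method = vapply(measurements, quantMethod, character(1)),
    run_index = vapply(measurements, runIndex, integer(1)),
    area_px = vapply(measurements, areaPx, numeric(1)),
    area_um2 = vapply(measurements, areaUm2, numeric(1)),
    flags = vapply(measurements, function(m) paste(qualityFlags(m), collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
}

#' Adipocyte size-distribution histogram
#'
#' Bins areas into half-open bins `[e_i, e_{i+1})`, with the last bin closed
#' at the top so the maximum is not dropped. Either explicit `edges` or a
#' bin count may be given; with a bin count, equal-width bins span
#' `[min, max]` of the data. The default of 6 bins matches the conventional
#' presentation of adipocyte size distributions.
#'
#' @param areas numeric vector of areas (um^2), non-empty.
#' @param edges strictly increasing numeric bin edges (overrides `nBins`).
#' @param nBins number of equal-width bins when `edges` is not given.
#' @return a [SizeHistogram]. Areas outside `[first, last]` edges are not
#'   counted (see `nOutside`); the bin counts always sum to the number of
#'   in-range areas.
#' @examples
#' h <- sizeHistogram(c(5000, 8000), edges = c(4500, 7000, 9500))
#' binCounts(h)  # 1 1
#' @export
sizeHistogram <- function(areas, edges = NULL, nBins = 6L) {
  if (!is.numeric(areas) || !length(areas) || anyNA(areas))
    atStop("areas must be a non-empty numeric vector without NA",
           "adipotrace_validation_error")
  if (is.null(edges)) {
    nBins <- as.integer(nBins)
    if (is.na(nBins) || nBins < 1L)
      atStop("nBins must be a positive integer", "adipotrace_validation_error")
    lo <- min(areas); hi <- max(areas)
    if (lo == hi)
      atStop("cannot derive bins: all areas are identical; supply edges",
             "adipotrace_validation_error")
    edges <- seq(lo, hi, length.out = nBins + 1L)
  }
  edges <- as.numeric(edges)
  if (length(edges) < 2L || anyNA(edges) || any(diff(edges) <= 0))
    atStop("bin edges must be strictly increasing", "adipotrace_validation_error")
  # findInterval: i for e_i <= x < e_{i+1}; rightmost.closed puts x == last
  # edge into the final bin
  bin <- findInterval(areas, edges, rightmost.closed = TRUE)
  inrange <- bin >= 1L & bin <= length(edges) - 1L
  counts <- tabulate(bin[inrange], nbins = length(edges) - 1L)
  new("SizeHistogram", binEdges = edges, counts = as.integer(counts),
      nOutside = as.integer(sum(!inrange)))
}

#' Per-cell repeatability of repeated measurements
#'
#' Groups measurements by `(cell_id, method)` -- methods are never pooled --
#' and reports the mean and sample standard deviation (n-1 denominator) of
#' the calibrated area across repeated runs. The standard deviation of a
#' single-run group is `NA` (undefined), not 0. Trace mode is expected to
#' show sd exactly 0: the filled component does not depend on where inside
#' the cell the user clicks.
#'
#' @param measurements a list of [CellMeasurement] or a data.frame with
#'   columns `cell_id`, `method`, `area_um2`.
#' @return data.frame with columns `cell_id`, `method`, `mean_um2`,
#'   `sd_um2`, `n_runs`, one row per group.
#' @export
repeatability <- function(measurements) {
  df <- if (is.data.frame(measurements)) measurements else measurementTable(measurements)
  need <- c("cell_id", "method", "area_um2")
  if (!all(need %in% names(df)) || !nrow(df))
    atStop("need a non-empty table with cell_id, method, area_um2",
           "adipotrace_validation_error")
  key <- interaction(df$cell_id, df$method, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(cell_id = g$cell_id[1L], method = g$method[1L],
               mean_um2 = mean(g$area_um2),
               sd_um2 = if (nrow(g) >= 2L) stats::sd(g$area_um2) else NA_real_,
               n_runs = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$method, out$cell_id), , drop = FALSE]
}

#' Concordance between two measurement methods
#'
#' Ordinary least-squares fit `y = slope * x + intercept` over per-cell
#' areas already paired by cell, with R-squared the squared Pearson
#' correlation of `(x, y)` (identical to the OLS coefficient of
#' determination in a simple regression). Note concordance is directional:
#' `concordance(x, y)` and `concordance(y, x)` have different slopes in
#' general.
#'
#' @param x,y paired numeric area vectors (same cells, same order), length
#'   >= 2; `x` must have nonzero variance.
#' @return a [ConcordanceResult].
#' @examples
#' x <- seq(4000, 12000, length.out = 10)
#' r <- concordance(x, 0.97 * x - 50)
#' c(slope(r), intercept(r), rSquared(r))  # 0.97, -50, 1
#' @export
concordance <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    atStop("x and y must be numeric vectors of equal length",
           "adipotrace_validation_error")
  if (length(x) < 2L)
    atStop("concordance needs at least 2 paired cells",
           "adipotrace_validation_error")
  if (anyNA(x) || anyNA(y))
    atStop("paired areas must not contain NA", "adipotrace_validation_error")
  if (stats::var(x) == 0)
    atStop("x has zero variance: the regression slope is undefined",
           "adipotrace_validation_error")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) NA_real_ else stats::cor(x, y)^2
  new("ConcordanceResult", slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      rSquared = if (is.na(r2)) r2 else min(max(r2, 0), 1),
      n = length(x))
}

#' Concordance between two methods in a measurement table
#'
#' Averages repeated runs per cell within each method, pairs cells by
#' `cell_id`, and regresses `yMethod` areas on `xMethod` areas. Cells
#' missing in either method are dropped with a warning.
#'
#' @param df measurement table (see [measurementTable()]).
#' @param xMethod,yMethod method tags, e.g. `"HT"`, `"TM"`.
#' @return a [ConcordanceResult].
#' @export
methodConcordance <- function(df, xMethod, yMethod) {
  if (!is.data.frame(df) || !all(c("cell_id", "method", "area_um2") %in% names(df)))
    atStop("df must have columns cell_id, method, area_um2",
           "adipotrace_validation_error")
  mx <- df[df$method == xMethod, , drop = FALSE]
  my <- df[df$method == yMethod, , drop = FALSE]
  if (!nrow(mx) || !nrow(my))
    atStop(sprintf("no measurements for method pair (%s, %s)", xMethod, yMethod),
           "adipotrace_validation_error")
  ax <- tapply(mx$area_um2, mx$cell_id, mean)
  ay <- tapply(my$area_um2, my$cell_id, mean)
  common <- intersect(names(ax), names(ay))
  dropped <- setdiff(union(names(ax), names(ay)), common)
  if (length(dropped))
    atWarn(sprintf("dropping %d cell(s) missing in one method: %s",
                   length(dropped), paste(dropped, collapse = ", ")),
           "adipotrace_pairing_warning")
  if (length(common) < 2L)
    atStop("fewer than 2 cells shared between the two methods",
           "adipotrace_validation_error")
  concordance(as.numeric(ax[common]), as.numeric(ay[common]))
}
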