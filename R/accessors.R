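# Accessors and show methods.

#' Accessors for raster classes
#'
#' `intensityValues()` returns the numeric intensity matrix of an
#' [ImageGrid]; `maskValues()` the logical matrix of a [BinaryMask];
#' `dim()` works on both.
#'
#' @param x an `ImageGrid` or `BinaryMask`.
#' @return a matrix (or for `dim`, an integer `(height, width)` pair).
#' @name raster-accessors
NULL

#' @rdname raster-accessors
#' @export
setMethod("intensityValues", "ImageGrid", function(x) x@values)

#' @rdname raster-accessors
#' @export
setMethod("maskValues", "BinaryMask", function(x) x@values)

#' @rdname raster-accessors
#' @export
setMethod("dim", "ImageGrid", function(x) dim(x@values))

#' @rdname raster-accessors
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@values))

#' @rdname raster-accessors
#' @export
setMethod("micronsPerPixel", "ScaleCalibration", function(x) x@micronsPerPixel)

setMethod("show", "ImageGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageGrid: %d x %d px, intensity range [%.3f, %.3f]\n",
              d[1L], d[2L], min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask: %d x %d px, %.1f%% foreground\n",
              d[1L], d[2L], 100 * mean(object@values)))
})

setMethod("show", "ScaleCalibration", function(object) {
  cat(sprintf("ScaleCalibration: %g um/px (area factor %g um^2/px^2)\n",
              object@micronsPerPixel, object@micronsPerPixel^2))
})

setMethod("show", "TransformParams", function(object) {
  cat(sprintf(paste0("TransformParams: shadows %.3g, lowLevelIn %.3g, ",
                     "binaryThreshold %.3g, despeckle radius %d x %d passes\n"),
              object@shadows, object@lowLevelIn, object@binaryThreshold,
              object@despeckleRadius, object@despecklePasses))
})

#' Accessors for measurement geometry
#'
#' @param x a [TracedRegion], [PolygonTrace], [EllipseApprox] or
#'   [CellMeasurement].
#' @return the requested component; see each class for details.
#' @name geometry-accessors
NULL

#' @rdname geometry-accessors
#' @export
setMethod("interiorPixels", "TracedRegion", function(x) x@pixels)

#' @rdname geometry-accessors
#' @export
setMethod("boundaryCoords", "TracedRegion", function(x) x@boundary)

#' @rdname geometry-accessors
#' @export
setMethod("areaPx", "TracedRegion", function(x) x@areaPx)

#' @rdname geometry-accessors
#' @export
setMethod("perimeterPx", "TracedRegion", function(x) x@perimeterPx)

#' @rdname geometry-accessors
#' @export
setMethod("touchesBorder", "TracedRegion", function(x) x@touchesBorder)

#' @rdname geometry-accessors
#' @export
setMethod("cellLabel", "TracedRegion", function(x) x@label)

#' @rdname geometry-accessors
#' @export
setMethod("polygonVertices", "PolygonTrace", function(x) x@vertices)

#' @rdname geometry-accessors
#' @export
setMethod("cellLabel", "PolygonTrace", function(x) x@label)

#' @rdname geometry-accessors
#' @export
setMethod("semiMajor", "EllipseApprox", function(x) x@a)

#' @rdname geometry-accessors
#' @export
setMethod("semiMinor", "EllipseApprox", function(x) x@b)

#' @rdname geometry-accessors
#' @export
setMethod("ellipseCenter", "EllipseApprox", function(x) x@center)

#' @rdname geometry-accessors
#' @export
setMethod("cellLabel", "EllipseApprox", function(x) x@label)

setMethod("show", "TracedRegion", function(object) {
  cat(sprintf(paste0("TracedRegion '%s': %d px interior, %d boundary px, ",
                     "perimeter %.1f px%s\n"),
              object@label, object@areaPx, nrow(object@boundary),
              object@perimeterPx,
              if (object@touchesBorder) " [touches border]" else ""))
})

setMethod("show", "PolygonTrace", function(object) {
  cat(sprintf("PolygonTrace '%s': %d vertices, area %.1f px^2\n",
              object@label, nrow(object@vertices), polygonArea(object)))
})

setMethod("show", "EllipseApprox", function(object) {
  cat(sprintf("EllipseApprox '%s': A = %.2f px, B = %.2f px, area %.1f px^2\n",
              object@label, object@a, object@b, ellipseArea(object)))
})

#' Accessors for CellMeasurement
#'
#' @param x a [CellMeasurement].
#' @return the requested field.
#' @name measurement-accessors
NULL

#' @rdname measurement-accessors
#' @export
setMethod("areaPx", "CellMeasurement", function(x) x@areaPx)

#' @rdname measurement-accessors
#' @export
setMethod("areaUm2", "CellMeasurement", function(x) x@areaUm2)

#' @rdname measurement-accessors
#' @export
setMethod("cellLabel", "CellMeasurement", function(x) x@cellId)

#' @rdname measurement-accessors
#' @export
setMethod("quantMethod", "CellMeasurement", function(x) x@method)

#' @rdname measurement-accessors
#' @export
setMethod("runIndex", "CellMeasurement", function(x) x@runIndex)

#' @rdname measurement-accessors
#' @export
setMethod("geometryOf", "CellMeasurement", function(x) x@geometry)

#' @rdname measurement-accessors
#' @export
setMethod("qualityFlags", "CellMeasurement", function(x) x@flags)

#' @rdname measurement-accessors
#' @export
setMethod("micronsPerPixel", "CellMeasurement", function(x) x@micronsPerPixel)

setMethod("show", "CellMeasurement", function(object) {
  fl <- if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]") else ""
  cat(sprintf("CellMeasurement '%s' %s run %d: %.1f px^2 = %.1f um^2%s\n",
              object@cellId, object@method, object@runIndex,
              object@areaPx, object@areaUm2, fl))
})

#' Accessors for summary statistics classes
#'
#' @param x a [SizeHistogram] or [ConcordanceResult].
#' @return the requested component.
#' @name summary-accessors
NULL

#' @rdname summary-accessors
#' @export
setMethod("binEdges", "SizeHistogram", function(x) x@binEdges)

#' @rdname summary-accessors
#' @export
setMethod("binCounts", "SizeHistogram", function(x) x@counts)

#' @rdname summary-accessors
#' @export
setMethod("slope", "ConcordanceResult", function(x) x@slope)

#' @rdname summary-accessors
#' @export
setMethod("intercept", "ConcordanceResult", function(x) x@intercept)

#' @rdname summary-accessors
#' @export
setMethod("rSquared", "ConcordanceResult", function(x) x@rSquared)

#' @rdname summary-accessors
#' @export
setMethod("nPairs", "ConcordanceResult", function(x) x@n)

setMethod("show", "SizeHistogram", function(object) {
  nb <- length(object@counts)
  cat(sprintf("SizeHistogram: %d bins over [%g, %g] um^2, %d cells (%d outside range)\n",
              nb, object@binEdges[1L], object@binEdges[nb + 1L],
              sum(object@counts), object@nOutside))
})

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("ConcordanceResult: slope %.4f, intercept %.2f um^2, R^2 %.4f (n = %d)\n",
              object@slope, object@intercept, object@rSquared, object@n))
})

#' Accessors for synthetic ground truth
#'
#' @param x an [AdiposeTruth].
#' @param cell a cell id (character) or index.
#' @return `nCells()`: the number of cells; `trueAreas()`: named vector of
#'   true interior areas in px^2; `trueInterior()`: integer `(row, col)`
#'   matrix of one cell's interior pixels; `hasGap()`: named logical vector.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setMethod("nCells", "AdiposeTruth", function(x) nrow(x@cells))

#' @rdname truth-accessors
#' @export
setMethod("trueAreas", "AdiposeTruth", function(x) {
  stats::setNames(x@cells$true_area_px, x@cells$cell_id)
})

#' @rdname truth-accessors
#' @export
setMethod("hasGap", "AdiposeTruth", function(x) {
  stats::setNames(x@cells$has_gap, x@cells$cell_id)
})

.truthIndex <- function(x, cell) {
  i <- if (is.character(cell)) match(cell, x@cells$cell_id) else as.integer(cell)
  if (is.na(i) || i < 1L || i > nrow(x@cells))
    atStop(sprintf("unknown cell '%s'", as.character(cell)),
           "adipotrace_validation_error")
  i
}

#' @rdname truth-accessors
#' @export
setMethod("trueInterior", "AdiposeTruth", function(x, cell) {
  i <- .truthIndex(x, cell)
  idx <- x@interiors[[i]]
  h <- x@dim[1L]
  cbind(row = (idx - 1L) %% h + 1L, col = (idx - 1L) %/% h + 1L)
})

setMethod("show", "AdiposeTruth", function(object) {
  cat(sprintf("AdiposeTruth: %d cells in %d x %d px, areas %d-%d px^2, %d gapped\n",
              nrow(object@cells), object@dim[1L], object@dim[2L],
              min(object@cells$true_area_px), max(object@cells$true_area_px),
              sum(object@cells$has_gap)))
})
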