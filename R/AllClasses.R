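# S4 classes for rasters, transform parameters, measurement geometry and
# summary statistics. Validity methods enforce the invariants that the rest
# of the package relies on; constructors are the exported user surface.

#' ImageGrid: a normalized grayscale intensity raster
#'
#' The unit on which all image operations act. Intensities are stored as a
#' numeric matrix in `[0, 1]` (single channel); RGB inputs are converted by
#' luminance weighting at load time. Coordinates are 1-based `(row, col)`
#' with row increasing downward.
#'
#' @slot values numeric matrix of intensities in `[0, 1]`.
#' @export
setClass("ImageGrid", representation(values = "matrix"))

setValidity("ImageGrid", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (length(v) < 1L) return("image must contain at least one pixel")
  if (anyNA(v)) return("image intensities must not be NA")
  if (min(v) < 0 || max(v) > 1) return("image intensities must lie in [0, 1]")
  TRUE
})

#' @param values numeric matrix of intensities in `[0, 1]`.
#' @rdname ImageGrid-class
#' @return an `ImageGrid` object.
#' @examples
#' img <- ImageGrid(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
ImageGrid <- function(values) {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), nrow = 1L)
  new("ImageGrid", values = matrix(as.numeric(values), nrow(values), ncol(values)))
}

#' BinaryMask: foreground mask of candidate cell interiors
#'
#' Logical raster with the same shape as its source [ImageGrid];
#' `TRUE` marks candidate cell interior (bright lipid lumen), `FALSE`
#' membrane or background.
#'
#' @slot values logical matrix.
#' @export
setClass("BinaryMask", representation(values = "matrix"))

setValidity("BinaryMask", function(object) {
  v <- object@values
  if (!is.logical(v)) return("mask values must be logical")
  if (length(v) < 1L) return("mask must contain at least one pixel")
  if (anyNA(v)) return("mask values must not be NA")
  TRUE
})

#' @param values logical matrix.
#' @rdname BinaryMask-class
#' @return a `BinaryMask` object.
#' @export
BinaryMask <- function(values) {
  if (is.null(dim(values))) values <- matrix(as.logical(values), nrow = 1L)
  new("BinaryMask", values = matrix(as.logical(values), nrow(values), ncol(values)))
}

#' ScaleCalibration: microns-per-pixel scale factor
#'
#' Converts pixel measurements to physical units. Areas scale with the
#' square of `micronsPerPixel`.
#'
#' @slot micronsPerPixel positive scalar, microns per pixel edge.
#' @export
setClass("ScaleCalibration", representation(micronsPerPixel = "numeric"))

setValidity("ScaleCalibration", function(object) {
  m <- object@micronsPerPixel
  if (length(m) != 1L || !is.finite(m) || m <= 0)
    return("micronsPerPixel must be a single positive finite number")
  TRUE
})

#' @param micronsPerPixel positive scalar, microns per pixel edge.
#' @rdname ScaleCalibration-class
#' @return a `ScaleCalibration` object.
#' @examples
#' calib <- ScaleCalibration(0.5)
#' areaPxToUm2(12345, calib)  # 3086.25
#' @export
ScaleCalibration <- function(micronsPerPixel) {
  if (is(micronsPerPixel, "ScaleCalibration")) return(micronsPerPixel)
  if (!is.numeric(micronsPerPixel) || length(micronsPerPixel) != 1L ||
      !is.finite(micronsPerPixel) || micronsPerPixel <= 0)
    atStop("micronsPerPixel must be a single positive number",
           "adipotrace_validation_error")
  new("ScaleCalibration", micronsPerPixel = as.numeric(micronsPerPixel))
}

#' TransformParams: knobs of the three-step trace-mode transform
#'
#' Parameters of the transform applied before trace mode:
#' a piecewise-linear levels/shadows stretch, binarization, and an iterated
#' disc majority despeckle. Defaults are the tool's published operating
#' point: shadows 0.15, low level in 0.9, binary threshold 0.8, despeckle
#' radius 5 px, 5 passes.
#'
#' @slot shadows intensity in `[0, 1)`; inputs at or below map to 0.
#' @slot lowLevelIn intensity in `(0, 1]`; inputs at or above map to 1.
#' @slot binaryThreshold intensity in `(0, 1)`; mask is `value >= threshold`.
#' @slot despeckleRadius integer pixel radius of the majority disc (0 = off).
#' @slot despecklePasses integer number of majority-filter passes (>= 1).
#' @export
setClass("TransformParams", representation(
  shadows = "numeric", lowLevelIn = "numeric", binaryThreshold = "numeric",
  despeckleRadius = "integer", despecklePasses = "integer"))

setValidity("TransformParams", function(object) {
  s <- object@shadows; l <- object@lowLevelIn; b <- object@binaryThreshold
  if (length(s) != 1L || length(l) != 1L || length(b) != 1L)
    return("all parameters must be scalars")
  if (!is.finite(s) || s < 0 || s >= 1) return("shadows must lie in [0, 1)")
  if (!is.finite(l) || l <= 0 || l > 1) return("lowLevelIn must lie in (0, 1]")
  if (s >= l) return("shadows must be strictly less than lowLevelIn")
  if (!is.finite(b) || b <= 0 || b >= 1)
    return("binaryThreshold must lie strictly in (0, 1)")
  if (object@despeckleRadius < 0L) return("despeckleRadius must be >= 0")
  if (object@despecklePasses < 1L) return("despecklePasses must be >= 1")
  TRUE
})

#' @param shadows,lowLevelIn,binaryThreshold,despeckleRadius,despecklePasses
#'   see slot descriptions.
#' @rdname TransformParams-class
#' @return a `TransformParams` object.
#' @examples
#' TransformParams()  # published defaults
#' @export
TransformParams <- function(shadows = 0.15, lowLevelIn = 0.9,
                            binaryThreshold = 0.8, despeckleRadius = 5L,
                            despecklePasses = 5L) {
  obj <- try(new("TransformParams", shadows = as.numeric(shadows),
                 lowLevelIn = as.numeric(lowLevelIn),
                 binaryThreshold = as.numeric(binaryThreshold),
                 despeckleRadius = as.integer(despeckleRadius),
                 despecklePasses = as.integer(despecklePasses)), silent = TRUE)
  if (inherits(obj, "try-error"))
    atStop(paste("invalid transform parameters:",
                 attr(obj, "condition")$message),
           "adipotrace_validation_error")
  obj
}

#' TracedRegion: trace-mode geometry for one cell
#'
#' Produced by [measureCellTM()]: the 4-connected interior pixel set filled
#' from the seed, plus the ordered closed interior boundary found by
#' Moore-neighbor contour following.
#'
#' @slot pixels integer matrix `(row, col)` of interior pixels, sorted in
#'   column-major order (deterministic regardless of seed).
#' @slot boundary integer matrix `(row, col)`, ordered closed cycle
#'   (first vertex not repeated).
#' @slot areaPx interior pixel count.
#' @slot perimeterPx contour length: 1 per 4-neighbor step, sqrt(2) per
#'   diagonal step, including closure; 0 for a single-pixel region.
#' @slot label cell identifier.
#' @slot touchesBorder `TRUE` if any interior pixel lies on the image edge
#'   (the cell's true extent may be cropped).
#' @export
setClass("TracedRegion", representation(
  pixels = "matrix", boundary = "matrix", areaPx = "numeric",
  perimeterPx = "numeric", label = "character", touchesBorder = "logical"))

setValidity("TracedRegion", function(object) {
  if (nrow(object@pixels) < 1L) return("region must contain >= 1 pixel")
  if (object@areaPx != nrow(object@pixels))
    return("areaPx must equal the interior pixel count")
  if (nrow(object@boundary) < 1L) return("boundary must be non-empty")
  TRUE
})

#' PolygonTrace: hand-traced polygon for one cell
#'
#' Ordered vertices of a manually traced cell perimeter; the polygon is
#' closed implicitly (last vertex connects to first). A duplicated final
#' vertex equal to the first (a "double-click to finish") is dropped by the
#' constructor.
#'
#' @slot vertices numeric matrix with columns `(row, col)`, >= 3 rows, no
#'   two consecutive vertices identical.
#' @slot label cell identifier.
#' @export
setClass("PolygonTrace", representation(vertices = "matrix", label = "character"))

setValidity("PolygonTrace", function(object) {
  v <- object@vertices
  if (ncol(v) != 2L) return("vertices must have two columns (row, col)")
  if (nrow(v) < 3L) return("a polygon needs at least 3 vertices")
  d <- rbind(diff(v), v[1L, , drop = FALSE] - v[nrow(v), , drop = FALSE])
  if (any(rowSums(abs(d)) == 0))
    return("no two consecutive vertices may be identical")
  TRUE
})

#' @param vertices numeric matrix (or two-column data.frame) of `(row, col)`
#'   vertices in trace order.
#' @param label cell identifier.
#' @rdname PolygonTrace-class
#' @return a `PolygonTrace` object.
#' @examples
#' sq <- PolygonTrace(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
#' polygonArea(sq)  # 1
#' @export
PolygonTrace <- function(vertices, label = "cell") {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L)
    atStop("vertices must have two columns (row, col)",
           "adipotrace_validation_error")
  # tolerate a closing vertex duplicating the first (double-click convention)
  if (nrow(v) >= 2L && all(v[nrow(v), ] == v[1L, ])) v <- v[-nrow(v), , drop = FALSE]
  obj <- try(new("PolygonTrace", vertices = v, label = as.character(label)),
             silent = TRUE)
  if (inherits(obj, "try-error"))
    atStop(paste("invalid polygon:", attr(obj, "condition")$message),
           "adipotrace_validation_error")
  obj
}

#' EllipseApprox: ellipse-approximation geometry for one cell
#'
#' Built from the two clicked endpoints of the major axis and a semi-minor
#' length; the semi-minor axis is perpendicular to the major axis through its
#' midpoint. `B > A` is rejected (the axes would be mislabeled).
#'
#' @slot p1,p2 numeric `(row, col)` endpoints of the major axis.
#' @slot center midpoint of `p1 p2`.
#' @slot a semi-major length in px, `|p2 - p1| / 2`.
#' @slot b semi-minor length in px, `0 < b <= a`.
#' @slot label cell identifier.
#' @export
setClass("EllipseApprox", representation(
  p1 = "numeric", p2 = "numeric", center = "numeric",
  a = "numeric", b = "numeric", label = "character"))

setValidity("EllipseApprox", function(object) {
  if (object@a <= 0) return("semi-major axis must be positive")
  if (object@b <= 0 || object@b > object@a)
    return("semi-minor axis must satisfy 0 < b <= a")
  TRUE
})

#' CellMeasurement: one cell x one method x one run
#'
#' The atomic measurement record: areas in px^2 and um^2, the geometry that
#' produced them, and bookkeeping labels. Collections of these are
#' summarized by [measurementTable()], [repeatability()] and
#' [concordance()].
#'
#' @slot cellId cell identifier.
#' @slot method one of `"TM"`, `"HT"`, `"EA"`; must match the geometry class.
#' @slot runIndex repeat-run index (>= 1).
#' @slot areaPx area in square pixels.
#' @slot areaUm2 area in square microns (`areaPx * micronsPerPixel^2`).
#' @slot micronsPerPixel calibration used.
#' @slot geometry [TracedRegion], [PolygonTrace] or [EllipseApprox].
#' @slot flags character vector of quality flags (e.g. `"touches_border"`,
#'   `"self_intersecting"`); empty when clean.
#' @export
setClass("CellMeasurement", representation(
  cellId = "character", method = "character", runIndex = "integer",
  areaPx = "numeric", areaUm2 = "numeric", micronsPerPixel = "numeric",
  geometry = "ANY", flags = "character"))

setValidity("CellMeasurement", function(object) {
  if (!object@method %in% c("TM", "HT", "EA"))
    return("method must be one of TM, HT, EA")
  want <- c(TM = "TracedRegion", HT = "PolygonTrace", EA = "EllipseApprox")
  if (!is(object@geometry, want[[object@method]]))
    return(sprintf("method %s requires %s geometry", object@method,
                   want[[object@method]]))
  if (object@areaPx < 0) return("areaPx must be >= 0")
  if (abs(object@areaUm2 - object@areaPx * object@micronsPerPixel^2) >
      1e-8 * max(1, object@areaUm2))
    return("areaUm2 must equal areaPx * micronsPerPixel^2")
  if (object@runIndex < 1L) return("runIndex must be >= 1")
  TRUE
})

#' SizeHistogram: adipocyte size distribution
#'
#' Counts of cell areas per size bin. Bins are half-open `[e_i, e_{i+1})`
#' with the last bin closed at the top; out-of-range areas are excluded and
#' reported via `nOutside`.
#'
#' @slot binEdges strictly increasing numeric edges (n+1 for n bins), um^2.
#' @slot counts integer counts per bin.
#' @slot nOutside number of areas falling outside `[first, last]` edges.
#' @export
setClass("SizeHistogram", representation(
  binEdges = "numeric", counts = "integer", nOutside = "integer"))

setValidity("SizeHistogram", function(object) {
  if (length(object@binEdges) < 2L) return("need at least two bin edges")
  if (any(diff(object@binEdges) <= 0))
    return("bin edges must be strictly increasing")
  if (length(object@counts) != length(object@binEdges) - 1L)
    return("counts must have one entry per bin")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  TRUE
})

#' ConcordanceResult: pairwise method agreement summary
#'
#' Ordinary least-squares fit `y = slope * x + intercept` over per-cell
#' areas paired by cell id, with R-squared the squared Pearson correlation
#' (equal to the OLS coefficient of determination for a simple regression).
#' Concordance is directional: regressing y on x and x on y give different
#' slopes.
#'
#' @slot slope dimensionless regression slope.
#' @slot intercept intercept in um^2.
#' @slot rSquared squared Pearson correlation, in `[0, 1]` (NA if y is
#'   constant).
#' @slot n number of paired cells.
#' @export
setClass("ConcordanceResult", representation(
  slope = "numeric", intercept = "numeric", rSquared = "numeric",
  n = "integer"))

setValidity("ConcordanceResult", function(object) {
  if (object@n < 2L) return("concordance needs at least 2 paired cells")
  r2 <- object@rSquared
  if (!is.na(r2) && (r2 < -1e-12 || r2 > 1 + 1e-12))
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' SyntheticSpec: parameters of the adipose-histology simulator
#'
#' Describes a synthetic H&E-like field: bright lipid-vacuole interiors
#' (intensity ~0.95) ringed by thin dark membranes (~0.10) on a mid-grey
#' background (~0.55), with optional membrane gap arcs, background speckle
#' artifacts and additive Gaussian intensity noise. Cells are placed without
#' overlap by rejection sampling. Defaults emulate a measurement session on
#' one region of interest: 15 cells (the standard per-sample protocol) with
#' equivalent radii 38-55 px, i.e. areas of roughly 4500-9500 um^2 at
#' 1 um/px, the common adipocyte size range.
#'
#' @slot height,width image dimensions in pixels.
#' @slot nCells number of cells (>= 1).
#' @slot radiusRange `(min, max)` base cell radius in px.
#' @slot membraneThickness membrane ridge thickness in px (>= 1).
#' @slot gapProbability chance in `[0, 1]` that a cell's membrane has a gap.
#' @slot gapArc angular width (radians) of a membrane gap.
#' @slot speckleCount number of small dark/bright background artifacts.
#' @slot noiseSd standard deviation of additive Gaussian intensity noise.
#' @slot rngSeed integer seed; output is fully reproducible from it.
#' @export
setClass("SyntheticSpec", representation(
  height = "integer", width = "integer", nCells = "integer",
  radiusRange = "numeric", membraneThickness = "integer",
  gapProbability = "numeric", gapArc = "numeric", speckleCount = "integer",
  noiseSd = "numeric", rngSeed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@nCells < 1L) return("nCells must be >= 1")
  r <- object@radiusRange
  if (length(r) != 2L || any(r <= 0) || r[1L] > r[2L])
    return("radiusRange must be positive (min, max) with min <= max")
  if (object@membraneThickness < 1L) return("membraneThickness must be >= 1")
  if (object@gapProbability < 0 || object@gapProbability > 1)
    return("gapProbability must lie in [0, 1]")
  if (object@gapArc <= 0 || object@gapArc > pi)
    return("gapArc must lie in (0, pi]")
  if (object@speckleCount < 0L) return("speckleCount must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  need <- 2 * (r[2L] + object@membraneThickness)
  if (object@height < need || object@width < need)
    return("image dimensions must be >= 2 * (max radius + membraneThickness)")
  TRUE
})

#' @param height,width,nCells,radiusRange,membraneThickness,gapProbability,gapArc,speckleCount,noiseSd,rngSeed
#'   see slot descriptions.
#' @rdname SyntheticSpec-class
#' @return a `SyntheticSpec` object.
#' @examples
#' spec <- SyntheticSpec(height = 256, width = 256, nCells = 3,
#'                       radiusRange = c(25, 35))
#' @export
SyntheticSpec <- function(height = 1024L, width = 1024L, nCells = 15L,
                          radiusRange = c(38, 55), membraneThickness = 4L,
                          gapProbability = 0, gapArc = 0.6,
                          speckleCount = 30L, noiseSd = 0.02, rngSeed = 1L) {
  obj <- try(new("SyntheticSpec", height = as.integer(height),
                 width = as.integer(width), nCells = as.integer(nCells),
                 radiusRange = as.numeric(radiusRange),
                 membraneThickness = as.integer(membraneThickness),
                 gapProbability = as.numeric(gapProbability),
                 gapArc = as.numeric(gapArc),
                 speckleCount = as.integer(speckleCount),
                 noiseSd = as.numeric(noiseSd),
                 rngSeed = as.integer(rngSeed)), silent = TRUE)
  if (inherits(obj, "try-error"))
    atStop(paste("invalid synthetic spec:", attr(obj, "condition")$message),
           "adipotrace_validation_error")
  obj
}

#' AdiposeTruth: ground truth of a synthetic field
#'
#' Per-cell ground truth emitted by [simulateAdipose()]: centers, exact
#' rasterized interior pixel sets (pairwise disjoint), true areas and gap
#' flags, plus each cell's radial outline function so that reference
#' hand-trace polygons and true ellipse axes can be derived.
#'
#' @slot dim image `(height, width)`.
#' @slot cells data.frame: `cell_id`, `center_row`, `center_col`,
#'   `base_radius`, `has_gap`, `gap_angle`, `true_area_px`.
#' @slot interiors list of sorted linear pixel indices, one per cell.
#' @slot shapes list of radial-outline descriptors
#'   (`r0`, `irregularity`, harmonic coefficients `ak`, `bk` for k = 2..5).
#' @export
setClass("AdiposeTruth", representation(
  dim = "integer", cells = "data.frame", interiors = "list", shapes = "list"))

setValidity("AdiposeTruth", function(object) {
  n <- nrow(object@cells)
  if (length(object@interiors) != n || length(object@shapes) != n)
    return("interiors and shapes must have one entry per cell")
  if (any(object@cells$true_area_px != lengths(object@interiors)))
    return("true_area_px must equal the interior pixel count")
  all_idx <- unlist(object@interiors, use.names = FALSE)
  if (anyDuplicated(all_idx)) return("cell interiors must be pairwise disjoint")
  TRUE
})
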