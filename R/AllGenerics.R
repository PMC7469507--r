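# Generics for the accessor surface. Slot access from user code is
# discouraged; these are the stable API.

#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))

#' @export
setGeneric("micronsPerPixel", function(x) standardGeneric("micronsPerPixel"))

#' @export
setGeneric("areaPx", function(x) standardGeneric("areaPx"))

#' @export
setGeneric("areaUm2", function(x) standardGeneric("areaUm2"))

#' @export
setGeneric("cellLabel", function(x) standardGeneric("cellLabel"))

#' @export
setGeneric("quantMethod", function(x) standardGeneric("quantMethod"))

#' @export
setGeneric("runIndex", function(x) standardGeneric("runIndex"))

#' @export
setGeneric("geometryOf", function(x) standardGeneric("geometryOf"))

#' @export
setGeneric("qualityFlags", function(x) standardGeneric("qualityFlags"))

#' @export
setGeneric("interiorPixels", function(x) standardGeneric("interiorPixels"))

#' @export
setGeneric("boundaryCoords", function(x) standardGeneric("boundaryCoords"))

#' @export
setGeneric("perimeterPx", function(x) standardGeneric("perimeterPx"))

#' @export
setGeneric("touchesBorder", function(x) standardGeneric("touchesBorder"))

#' @export
setGeneric("polygonVertices", function(x) standardGeneric("polygonVertices"))

#' @export
setGeneric("semiMajor", function(x) standardGeneric("semiMajor"))

#' @export
setGeneric("semiMinor", function(x) standardGeneric("semiMinor"))

#' @export
setGeneric("ellipseCenter", function(x) standardGeneric("ellipseCenter"))

#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @export
setGeneric("slope", function(x) standardGeneric("slope"))

#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @export
setGeneric("trueAreas", function(x) standardGeneric("trueAreas"))

#' @export
setGeneric("trueInterior", function(x, cell) standardGeneric("trueInterior"))

#' @export
setGeneric("hasGap", function(x) standardGeneric("hasGap"))
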