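# Manual benchmark modes: hand-trace polygon area and ellipse approximation.

#' Polygon area of a hand trace (shoelace formula)
#'
#' Absolute value of the shoelace sum over the closed vertex cycle;
#' independent of orientation, vertex-cycle rotation and translation.
#' Self-intersecting traces are accepted with a warning (class
#' `adipotrace_selfintersect_warning`) -- operators occasionally cross a
#' vertex pair -- and the shoelace value is still reported.
#'
#' @param poly a [PolygonTrace], or a numeric `(row, col)` vertex matrix.
#' @return area in square pixels.
#' @examples
#' polygonArea(rbind(c(0, 0), c(0, 4), c(3, 0)))  # 6
#' @export
polygonArea <- function(poly) {
  if (!is(poly, "PolygonTrace")) poly <- PolygonTrace(poly)
  v <- poly@vertices
  if (.selfIntersects(v))
    atWarn(sprintf("polygon '%s' is self-intersecting; shoelace area reported",
                   poly@label),
           "adipotrace_selfintersect_warning")
  .shoelace(v)
}

.shoelace <- function(v) {
  y <- v[, 1L]; x <- v[, 2L]
  yn <- c(y[-1L], y[1L]); xn <- c(x[-1L], x[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# proper crossing test between non-adjacent edges; shared endpoints of
# adjacent edges are not intersections
.selfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  a <- v
  b <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  cross <- function(o, p, q) {
    (p[2L] - o[2L]) * (q[1L] - o[1L]) - (p[1L] - o[1L]) * (q[2L] - o[2L])
  }
  for (i in 1L:(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
      p1 <- a[i, ]; p2 <- b[i, ]; q1 <- a[j, ]; q2 <- b[j, ]
      d1 <- cross(q1, q2, p1); d2 <- cross(q1, q2, p2)
      d3 <- cross(p1, p2, q1); d4 <- cross(p1, p2, q2)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Build an ellipse approximation from clicked axes
#'
#' The user clicks the two endpoints of the major axis; the semi-minor axis
#' is perpendicular to it through the midpoint. `A = |p2 - p1| / 2` is the
#' semi-major length; `b` is the semi-minor length and must satisfy
#' `0 < b <= A` -- a larger `b` means the axes were mislabeled and is
#' rejected rather than silently swapped.
#'
#' @param p1,p2 numeric `(row, col)` endpoints of the major axis.
#' @param b semi-minor length in pixels.
#' @param label cell identifier.
#' @return an [EllipseApprox].
#' @examples
#' e <- makeEllipse(c(0, 0), c(0, 20), b = 5)
#' semiMajor(e)      # 10
#' ellipseCenter(e)  # (0, 10)
#' @export
makeEllipse <- function(p1, p2, b, label = "cell") {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L || anyNA(p1) || anyNA(p2))
    atStop("p1 and p2 must be (row, col) coordinate pairs",
           "adipotrace_validation_error")
  if (all(p1 == p2))
    atStop("major-axis endpoints must be distinct",
           "adipotrace_validation_error")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    atStop("semi-minor length b must be a positive number",
           "adipotrace_validation_error")
  a <- sqrt(sum((p2 - p1)^2)) / 2
  if (b > a && b <= a * (1 + 1e-9)) b <- a  # round-trip noise, not mislabeling
  if (b > a)
    atStop(sprintf(paste0("axes mislabeled: semi-minor b = %g exceeds ",
                          "semi-major A = %g; A must be the longer axis"),
                   b, a),
           "adipotrace_validation_error")
  new("EllipseApprox", p1 = p1, p2 = p2, center = (p1 + p2) / 2,
      a = a, b = as.numeric(b), label = as.character(label))
}

#' Ellipse-approximation area
#'
#' The classic approximation `Area = pi * A * B` with `A` and `B` the
#' semi-major and semi-minor axes. Exact for a true ellipse; for an
#' irregular adipocyte it may over- or under-estimate depending on the
#' chosen axes.
#'
#' @param e an [EllipseApprox].
#' @return area in square pixels.
#' @examples
#' ellipseArea(makeEllipse(c(0, 0), c(0, 20), b = 10))  # 100 * pi
#' @export
ellipseArea <- function(e) {
  stopifnot(is(e, "EllipseApprox"))
  pi * e@a * e@b
}

#' Measure one cell by hand trace
#'
#' @param poly a [PolygonTrace] (or vertex matrix).
#' @param calib a [ScaleCalibration] or microns-per-pixel scalar.
#' @param runIndex repeat-run index.
#' @return a [CellMeasurement] with method `"HT"`. A self-intersecting
#'   trace is measured with a warning and flagged `"self_intersecting"`.
#' @export
measureCellHT <- function(poly, calib = 1, runIndex = 1L) {
  if (!is(poly, "PolygonTrace")) poly <- PolygonTrace(poly)
  calib <- ScaleCalibration(calib)
  flags <- character(0)
  apx <- withCallingHandlers(
    polygonArea(poly),
    adipotrace_selfintersect_warning = function(w) {
      flags <<- "self_intersecting"
      invokeRestart("muffleWarning")
    })
  if (length(flags))
    atWarn(sprintf("polygon '%s' is self-intersecting; shoelace area reported",
                   poly@label),
           "adipotrace_selfintersect_warning")
  new("CellMeasurement", cellId = poly@label, method = "HT",
      runIndex = as.integer(runIndex), areaPx = apx,
      areaUm2 = areaPxToUm2(apx, calib),
      micronsPerPixel = micronsPerPixel(calib),
      geometry = poly, flags = flags)
}

#' Measure one cell by ellipse approximation
#'
#' @param e an [EllipseApprox] from [makeEllipse()].
#' @param calib a [ScaleCalibration] or microns-per-pixel scalar.
#' @param runIndex repeat-run index.
#' @return a [CellMeasurement] with method `"EA"`.
#' @export
measureCellEA <- function(e, calib = 1, runIndex = 1L) {
  stopifnot(is(e, "EllipseApprox"))
  calib <- ScaleCalibration(calib)
  apx <- ellipseArea(e)
  new("CellMeasurement", cellId = e@label, method = "EA",
      runIndex = as.integer(runIndex), areaPx = apx,
      areaUm2 = areaPxToUm2(apx, calib),
      micronsPerPixel = micronsPerPixel(calib),
      geometry = e, flags = character(0))
}
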