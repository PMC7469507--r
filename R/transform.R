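# The three-step transform that precedes trace mode:
# levels/shadows stretch -> binarization -> iterated majority despeckle.

#' Levels/shadows contrast stretch
#'
#' Piecewise-linear intensity remap: values at or below `shadows` map to 0,
#' values at or above `lowLevelIn` map to 1, values in between are mapped
#' linearly. This saturates bright lipid lumens against dark membranes so
#' that a single global threshold separates them. Monotone non-decreasing in
#' the input intensity.
#'
#' @param img an [ImageGrid].
#' @param shadows lower input endpoint, in `[0, 1)`.
#' @param lowLevelIn upper input endpoint, in `(0, 1]`; must exceed
#'   `shadows`.
#' @return an [ImageGrid] with stretched intensities.
#' @examples
#' img <- ImageGrid(matrix(c(0.15, 0.525, 0.9), 1, 3))
#' intensityValues(adjustLevels(img))  # 0, 0.5, 1
#' @export
adjustLevels <- function(img, shadows = 0.15, lowLevelIn = 0.9) {
  stopifnot(is(img, "ImageGrid"))
  if (!is.numeric(shadows) || !is.numeric(lowLevelIn) ||
      length(shadows) != 1L || length(lowLevelIn) != 1L ||
      !is.finite(shadows) || !is.finite(lowLevelIn) ||
      shadows < 0 || lowLevelIn > 1 || shadows >= lowLevelIn)
    atStop("require 0 <= shadows < lowLevelIn <= 1",
           "adipotrace_validation_error")
  v <- (img@values - shadows) / (lowLevelIn - shadows)
  ImageGrid(pmin(pmax(v, 0), 1))
}

#' Binarize an image at a global threshold
#'
#' A pixel is foreground (`TRUE`, candidate cell interior) iff its intensity
#' is greater than or equal to `threshold`. The comparison is inclusive so
#' that pixels saturated to 1 by [adjustLevels()] always remain foreground.
#' Lowering the threshold never turns a foreground pixel off.
#'
#' @param img an [ImageGrid].
#' @param threshold intensity strictly inside `(0, 1)`.
#' @return a [BinaryMask] of the same dimensions.
#' @export
binarize <- function(img, threshold = 0.8) {
  stopifnot(is(img, "ImageGrid"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1)
    atStop("threshold must lie strictly in (0, 1)",
           "adipotrace_validation_error")
  BinaryMask(img@values >= threshold)
}

# disc offsets (dy, dx) for a given integer radius, cached per radius
.discOffsets <- local({
  cache <- list()
  function(r) {
    key <- as.character(r)
    if (is.null(cache[[key]])) {
      g <- expand.grid(dy = -r:r, dx = -r:r)
      cache[[key]] <<- as.matrix(g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE])
    }
    cache[[key]]
  }
})

#' Despeckle a binary mask by iterated disc majority filtering
#'
#' Each pass replaces every pixel by the majority vote of the mask over a
#' disc-shaped neighborhood of the given pixel radius (the disc contains all
#' offsets with `dy^2 + dx^2 <= radius^2`, including the center). Ties
#' (exactly half foreground) resolve to foreground. At the image edge the
#' neighborhood is the intersection of the disc with the image. Radius 0 is
#' the identity for any number of passes.
#'
#' Majority filtering removes isolated speckles and fills small holes, but
#' iterating it also moves region boundaries approximately by mean
#' curvature: strongly curved foreground boundaries erode slightly (on the
#' order of a few tenths of a percent of area for adipocyte-scale cells at
#' the default radius/passes). See the package vignette for measurements.
#'
#' @param mask a [BinaryMask].
#' @param radius integer disc radius in pixels (>= 0).
#' @param passes number of filter passes (>= 1).
#' @return a despeckled [BinaryMask].
#' @export
despeckle <- function(mask, radius = 5L, passes = 5L) {
  stopifnot(is(mask, "BinaryMask"))
  radius <- as.integer(radius); passes <- as.integer(passes)
  if (is.na(radius) || radius < 0L)
    atStop("radius must be a non-negative integer", "adipotrace_validation_error")
  if (is.na(passes) || passes < 1L)
    atStop("passes must be a positive integer", "adipotrace_validation_error")
  if (radius == 0L) return(mask)

  m <- mask@values
  h <- nrow(m); w <- ncol(m); r <- radius
  off <- .discOffsets(r)
  rows <- (1L:h) + r; cols <- (1L:w) + r

  # neighborhood sizes (disc clipped to image): constant across passes
  vpad <- matrix(0L, h + 2L * r, w + 2L * r)
  vpad[rows, cols] <- 1L
  valid <- matrix(0L, h, w)
  for (k in seq_len(nrow(off)))
    valid <- valid + vpad[rows + off[k, 1L], cols + off[k, 2L]]

  cur <- matrix(as.integer(m), h, w)
  for (p in seq_len(passes)) {
    pad <- matrix(0L, h + 2L * r, w + 2L * r)
    pad[rows, cols] <- cur
    cnt <- matrix(0L, h, w)
    for (k in seq_len(nrow(off)))
      cnt <- cnt + pad[rows + off[k, 1L], cols + off[k, 2L]]
    cur <- matrix(as.integer(2L * cnt >= valid), h, w)  # ties -> TRUE
  }
  BinaryMask(cur == 1L)
}

#' Run the full trace-mode transform
#'
#' Applies exactly [adjustLevels()], then [binarize()], then [despeckle()]
#' in that order, with the parameters in `params`. Deterministic: identical
#' inputs yield bit-identical masks.
#'
#' @param img an [ImageGrid].
#' @param params a [TransformParams]; the default is the published operating
#'   point (shadows 0.15, low level in 0.9, threshold 0.8, despeckle radius
#'   5, 5 passes).
#' @return a [BinaryMask] in which `TRUE` marks candidate cell interiors.
#' @examples
#' img <- ImageGrid(matrix(1, 8, 8))
#' all(maskValues(transformPipeline(img)))  # TRUE: saturation is preserved
#' @export
transformPipeline <- function(img, params = TransformParams()) {
  stopifnot(is(img, "ImageGrid"), is(params, "TransformParams"))
  lev <- adjustLevels(img, params@shadows, params@lowLevelIn)
  bin <- binarize(lev, params@binaryThreshold)
  despeckle(bin, params@despeckleRadius, params@despecklePasses)
}
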