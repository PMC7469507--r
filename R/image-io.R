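# Image ingestion and calibration.

# Rec. 601 luminance weights for RGB -> gray. Fixed so results are
# reproducible bit-for-bit across platforms.
.LUMA <- c(0.299, 0.587, 0.114)

#' Load a histology image as a normalized grayscale raster
#'
#' Reads a TIFF, PNG or JPEG image and returns an [ImageGrid] with
#' intensities on a `[0, 1]` scale. Integer 8/16-bit samples are divided by
#' their type maximum (the underlying readers already do this); RGB images
#' are converted to grayscale by Rec. 601 luminance weighting
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is ignored.
#'
#' Whole-slide formats are out of scope: export regions of interest at
#' constant magnification first, and supply the microns-per-pixel of that
#' export as the calibration.
#'
#' @param path path to a readable TIFF/PNG/JPEG file.
#' @return an [ImageGrid].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(c(0, 1, 128 / 255, 64 / 255), 2, 2), f)
#' loadImage(f)
#' @export
loadImage <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    atStop(sprintf("cannot read image '%s': file does not exist",
                   as.character(path)[1L]),
           "adipotrace_input_error")
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    tif = , tiff = tiff::readTIFF,
    png = png::readPNG,
    jpg = , jpeg = jpeg::readJPEG,
    atStop(sprintf("cannot read image '%s': unsupported extension '%s' (use TIFF/PNG/JPEG)",
                   path, ext), "adipotrace_input_error"))
  arr <- tryCatch(reader(path), error = function(e)
    atStop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
           "adipotrace_input_error"))
  if (is.list(arr)) arr <- arr[[1L]]  # multi-page TIFF: first page
  v <- if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch >= 3L) {
      .LUMA[1L] * arr[, , 1L] + .LUMA[2L] * arr[, , 2L] + .LUMA[3L] * arr[, , 3L]
    } else {
      arr[, , 1L]  # gray(+alpha) stored as planes
    }
  } else {
    arr
  }
  if (is.null(dim(v)) || any(dim(v) < 1L) || length(v) < 1L)
    atStop(sprintf("image '%s' has zero area", path),
           "adipotrace_validation_error")
  # numeric safety only; readers already return [0, 1]
  ImageGrid(pmin(pmax(v, 0), 1))
}

#' Convert a pixel area to square microns
#'
#' `area_um2 = area_px * micronsPerPixel^2`: linear in the pixel area and
#' quadratic in the calibration.
#'
#' @param areaPx area in square pixels (>= 0; vectorized).
#' @param calib a [ScaleCalibration] or a bare microns-per-pixel scalar.
#' @return area(s) in square microns.
#' @examples
#' areaPxToUm2(100, ScaleCalibration(2))   # 400
#' areaPxToUm2(12345, 0.5)                 # 3086.25
#' @export
areaPxToUm2 <- function(areaPx, calib) {
  calib <- ScaleCalibration(calib)
  if (!is.numeric(areaPx) || any(!is.finite(areaPx)) || any(areaPx < 0))
    atStop("areaPx must be non-negative and finite",
           "adipotrace_validation_error")
  areaPx * micronsPerPixel(calib)^2
}
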