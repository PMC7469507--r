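# Batch runs: measure a whole annotation file against an image, export
# results, overlays, histograms and a reproducibility record; compare
# methods across result files. Per-cell failures never abort a run: each
# cell row is either complete in results.csv or absent with a logged
# reason in errors.csv.

.METHOD_COLORS <- c(TM = "blue", HT = "red", EA = "yellow")

#' Measure all annotated cells in an image
#'
#' Runs one quantification method over every cell in an annotation table
#' and writes the standard export set to `outDir`:
#' \itemize{
#'   \item `results.csv` -- `cell_id,method,run_index,area_px,area_um2,flags`
#'     (byte-identical across reruns of an identical configuration);
#'   \item `errors.csv` -- per-cell failures (leaks, bad seeds), only if any;
#'   \item `run_params.json` -- machine-readable record of every parameter,
#'     sufficient to reproduce the run exactly;
#'   \item `run.log` -- per-cell timestamps and warnings;
#'   \item `histogram.csv` / `histogram.png` -- size distribution (6 bins
#'     by default);
#'   \item `overlay.png` -- outlines over the image, colored by method
#'     (TM blue, HT red, EA yellow).
#' }
#'
#' @param image an [ImageGrid] or a path to a TIFF/PNG/JPEG file.
#' @param method `"tm"`, `"ht"` or `"ea"`.
#' @param annotations annotation data.frame or CSV path: seeds for tm
#'   ([readSeedCSV()]), vertices for ht ([readVertexCSV()]), ellipses for
#'   ea ([readEllipseCSV()]).
#' @param micronsPerPixel calibration scalar (> 0), microns per pixel.
#' @param outDir output directory (created if needed).
#' @param params a [TransformParams] (tm only).
#' @param overlay write `overlay.png`?
#' @param maxAreaFrac trace-mode leak guard as a fraction of image area.
#' @param runIndex repeat-run index recorded in the results.
#' @param histogramBins bin count for the size histogram.
#' @return invisibly, a list with `results` (data.frame), `errors`
#'   (data.frame), `measurements` (list of [CellMeasurement]), `files`
#'   (written paths) and `ok` (`TRUE` if no cell failed).
#' @export
runMeasure <- function(image, method = c("tm", "ht", "ea"), annotations,
                       micronsPerPixel, outDir, params = TransformParams(),
                       overlay = TRUE, maxAreaFrac = 0.25, runIndex = 1L,
                       histogramBins = 6L) {
  method <- match.arg(method)
  calib <- ScaleCalibration(micronsPerPixel)
  imagePath <- if (is.character(image)) image else NA_character_
  img <- if (is.character(image)) loadImage(image) else image
  stopifnot(is(img, "ImageGrid"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  annotPath <- if (is.character(annotations)) annotations else NA_character_
  ann <- if (is.character(annotations)) {
    switch(method, tm = readSeedCSV(annotations),
           ht = readVertexCSV(annotations), ea = readEllipseCSV(annotations))
  } else annotations

  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  logLine <- function(...) writeLines(sprintf(...), logCon)
  logLine("run start %s | method=%s mpp=%g", format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
          method, micronsPerPixel(calib))

  mask <- NULL
  if (method == "tm") {
    mask <- transformPipeline(img, params)
    logLine("transform done %s", format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"))
  }
  d <- dim(img)
  maxAreaPx <- maxAreaFrac * d[1L] * d[2L]

  cellIds <- switch(method,
    tm = ann$cell_id,
    ht = unique(ann$cell_id),
    ea = ann$cell_id)

  measurements <- list()
  errs <- data.frame(cell_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (id in cellIds) {
    res <- tryCatch(withCallingHandlers({
      switch(method,
        tm = {
          rowi <- ann[ann$cell_id == id, , drop = FALSE][1L, ]
          measureCellTM(mask, c(rowi$row, rowi$col), label = id,
                        calib = calib, maxAreaPx = maxAreaPx,
                        runIndex = runIndex)
        },
        ht = {
          vs <- ann[ann$cell_id == id, , drop = FALSE]
          vs <- vs[order(vs$vertex_index), , drop = FALSE]
          measureCellHT(PolygonTrace(cbind(vs$row, vs$col), label = id),
                        calib = calib, runIndex = runIndex)
        },
        ea = {
          rowi <- ann[ann$cell_id == id, , drop = FALSE][1L, ]
          measureCellEA(makeEllipse(c(rowi$p1_row, rowi$p1_col),
                                    c(rowi$p2_row, rowi$p2_col),
                                    b = rowi$b, label = id),
                        calib = calib, runIndex = runIndex)
        })
    }, warning = function(w) {
      logLine("warning | cell=%s | %s", id, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    if (inherits(res, "error")) {
      errs <- rbind(errs, data.frame(cell_id = id,
                                     reason = conditionMessage(res),
                                     stringsAsFactors = FALSE))
      logLine("cell %s FAILED %s | %s", id,
              format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), conditionMessage(res))
    } else {
      measurements[[length(measurements) + 1L]] <- res
      logLine("cell %s done %s | area_px=%g", id,
              format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), areaPx(res))
    }
  }

  results <- measurementTable(measurements)
  files <- character(0)

  resPath <- file.path(outDir, "results.csv")
  write.csv(results, resPath, row.names = FALSE)
  files <- c(files, resPath)

  if (nrow(errs)) {
    errPath <- file.path(outDir, "errors.csv")
    write.csv(errs, errPath, row.names = FALSE)
    files <- c(files, errPath)
  }

  parPath <- file.path(outDir, "run_params.json")
  jsonlite::write_json(list(
    tool = "adipotrace", version = as.character(packageVersion("adipotrace")),
    image = imagePath, annotations = annotPath, method = method,
    microns_per_pixel = micronsPerPixel(calib), run_index = runIndex,
    max_area_frac = maxAreaFrac, histogram_bins = histogramBins,
    transform = if (method == "tm") list(
      shadows = params@shadows, low_level_in = params@lowLevelIn,
      binary_threshold = params@binaryThreshold,
      despeckle_radius = params@despeckleRadius,
      despeckle_passes = params@despecklePasses) else NULL),
    parPath, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, parPath)

  if (nrow(results) && length(unique(results$area_um2)) > 1L) {
    hst <- sizeHistogram(results$area_um2, nBins = histogramBins)
    hPath <- file.path(outDir, "histogram.csv")
    write.csv(data.frame(bin_low = binEdges(hst)[-length(binEdges(hst))],
                         bin_high = binEdges(hst)[-1L],
                         count = binCounts(hst)),
              hPath, row.names = FALSE)
    files <- c(files, hPath, .plotHistogramPNG(hst, file.path(outDir, "histogram.png"),
                                               toupper(method)))
  } else {
    logLine("histogram skipped: fewer than two distinct areas")
  }

  if (isTRUE(overlay)) {
    oPath <- file.path(outDir, "overlay.png")
    writeOverlayPNG(img, measurements, oPath)
    files <- c(files, oPath)
  }

  logLine("run end %s | %d cells measured, %d failed",
          format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), nrow(results), nrow(errs))
  invisible(list(results = results, errors = errs,
                 measurements = measurements, files = files,
                 ok = nrow(errs) == 0L))
}

.plotHistogramPNG <- function(hst, path, methodLabel) {
  grDevices::png(path, width = 640L, height = 480L)
  on.exit(grDevices::dev.off(), add = TRUE)
  e <- binEdges(hst)
  labs <- sprintf("%.0f-%.0f", e[-length(e)], e[-1L])
  graphics::barplot(binCounts(hst), names.arg = labs, las = 2,
                    col = "grey70", border = "grey30",
                    ylab = "cells", cex.names = 0.8,
                    main = sprintf("Adipocyte size distribution (%s)", methodLabel))
  graphics::title(xlab = expression(paste("area (", mu, m^2, ")")), line = 4.5)
  path
}

#' Draw measurement outlines over the image
#'
#' Writes a PNG of the grayscale image with each measured cell outlined and
#' labeled in its method color: trace mode blue, hand trace red, ellipse
#' approximation yellow.
#'
#' @param img an [ImageGrid].
#' @param measurements list of [CellMeasurement] objects.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeOverlayPNG <- function(img, measurements, path) {
  stopifnot(is(img, "ImageGrid"))
  d <- dim(img)
  grDevices::png(path, width = d[2L], height = d[1L])
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, d[2L] + 0.5), ylim = c(d[1L] + 0.5, 0.5),
                        asp = 1, xaxs = "i", yaxs = "i")
  graphics::rasterImage(grDevices::as.raster(intensityValues(img)),
                        0.5, d[1L] + 0.5, d[2L] + 0.5, 0.5)
  for (m in measurements) {
    col <- .METHOD_COLORS[[quantMethod(m)]]
    g <- geometryOf(m)
    xy <- switch(quantMethod(m),
      TM = {
        b <- boundaryCoords(g)
        rbind(b, b[1L, , drop = FALSE])
      },
      HT = {
        v <- polygonVertices(g)
        rbind(v, v[1L, , drop = FALSE])
      },
      EA = {
        th <- seq(0, 2 * pi, length.out = 181L)
        u <- (g@p2 - g@p1) / sqrt(sum((g@p2 - g@p1)^2))
        vperp <- c(-u[2L], u[1L])
        ctr <- ellipseCenter(g)
        cbind(ctr[1L] + semiMajor(g) * cos(th) * u[1L] +
                semiMinor(g) * sin(th) * vperp[1L],
              ctr[2L] + semiMajor(g) * cos(th) * u[2L] +
                semiMinor(g) * sin(th) * vperp[2L])
      })
    graphics::lines(xy[, 2L], xy[, 1L], col = col, lwd = 1.5)
    graphics::text(mean(xy[, 2L]), mean(xy[, 1L]), labels = cellLabel(m),
                   col = col, cex = 0.8)
  }
  invisible(path)
}

#' Compare quantification methods across result files
#'
#' Reads two or three `results.csv` exports (or equivalent data.frames),
#' computes per-cell repeatability and pairwise method concordance in the
#' canonical orientation HT-TM, HT-EA, TM-EA (x-method first), and writes
#' `repeatability.csv`, `concordance.csv` and one scatter plot with fitted
#' trendline per pair.
#'
#' @param results character vector of CSV paths, or a list of data.frames
#'   with columns `cell_id`, `method`, `run_index`, `area_um2`.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with `concordance` (data.frame),
#'   `repeatability` (data.frame) and `files`.
#' @export
runCompare <- function(results, outDir) {
  tabs <- lapply(results, function(r) {
    if (is.character(r)) {
      if (!file.exists(r))
        atStop(sprintf("results file '%s' does not exist", r),
               "adipotrace_input_error")
      read.csv(r, stringsAsFactors = FALSE)
    } else as.data.frame(r)
  })
  df <- do.call(rbind, lapply(tabs, function(x)
    x[, c("cell_id", "method", "run_index", "area_um2"), drop = FALSE]))
  if (!nrow(df))
    atStop("no measurements to compare", "adipotrace_validation_error")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  methods <- intersect(c("HT", "TM", "EA"), unique(df$method))
  pairOrder <- list(c("HT", "TM"), c("HT", "EA"), c("TM", "EA"))
  pairOrder <- Filter(function(p) all(p %in% methods), pairOrder)
  if (!length(pairOrder))
    atStop("need at least two methods sharing cells to compare",
           "adipotrace_validation_error")

  rows <- list(); files <- character(0)
  for (p in pairOrder) {
    cr <- methodConcordance(df, p[1L], p[2L])
    rows[[length(rows) + 1L]] <- data.frame(
      method_x = p[1L], method_y = p[2L], slope = slope(cr),
      intercept = intercept(cr), r_squared = rSquared(cr), n = nPairs(cr),
      stringsAsFactors = FALSE)
    files <- c(files, .plotConcordancePNG(df, p, cr,
      file.path(outDir, sprintf("scatter_%s_%s.png", p[1L], p[2L]))))
  }
  conc <- do.call(rbind, rows)
  concPath <- file.path(outDir, "concordance.csv")
  write.csv(conc, concPath, row.names = FALSE)

  rep <- repeatability(df)
  repPath <- file.path(outDir, "repeatability.csv")
  write.csv(rep, repPath, row.names = FALSE)

  invisible(list(concordance = conc, repeatability = rep,
                 files = c(files, concPath, repPath)))
}

.plotConcordancePNG <- function(df, p, cr, path) {
  ax <- tapply(df$area_um2[df$method == p[1L]], df$cell_id[df$method == p[1L]], mean)
  ay <- tapply(df$area_um2[df$method == p[2L]], df$cell_id[df$method == p[2L]], mean)
  common <- intersect(names(ax), names(ay))
  grDevices::png(path, width = 560L, height = 560L)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(ax[common], ay[common], pch = 21, bg = "grey",
                 xlab = sprintf("%s area (um^2)", p[1L]),
                 ylab = sprintf("%s area (um^2)", p[2L]),
                 main = sprintf("%s vs %s: slope %.3f, R^2 %.3f",
                                p[2L], p[1L], slope(cr), rSquared(cr)))
  graphics::abline(intercept(cr), slope(cr), col = "blue", lwd = 2)
  graphics::abline(0, 1, col = "grey60", lty = 2)
  path
}
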