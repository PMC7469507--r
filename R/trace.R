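# Trace mode: seed-click flood fill + Moore-neighbor interior boundary
# tracing. This is the semi-automated measurement path: the user supplies
# one point per cell, everything else is computed.

#' Flood-fill the cell interior from a seed click
#'
#' Returns the 4-connected component of foreground (`TRUE`) pixels
#' containing the seed. The fill uses an explicit frontier queue (never
#' call-stack recursion), so arbitrarily large regions cannot overflow.
#' Because the component is a set, the result is identical for every seed
#' inside the same cell -- the property that makes trace mode perfectly
#' repeatable.
#'
#' @param mask a [BinaryMask] (typically from [transformPipeline()]).
#' @param seed `(row, col)` integer pixel, 1-based, inside the image.
#' @param maxAreaPx guard against membrane-gap leaks: if the component grows
#'   beyond this many pixels, a "leak detected" error of class
#'   `adipotrace_leak_error` is raised (the cell should then be measured by
#'   hand trace or ellipse approximation instead). Default unlimited.
#' @return integer matrix with columns `(row, col)`, sorted in column-major
#'   order (deterministic regardless of seed position).
#' @examples
#' m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
#' nrow(fillFromSeed(BinaryMask(m), c(5, 5)))  # 25
#' @export
fillFromSeed <- function(mask, seed, maxAreaPx = Inf) {
  stopifnot(is(mask, "BinaryMask"))
  v <- mask@values
  h <- nrow(v); w <- ncol(v)
  seed <- as.integer(round(seed))
  if (length(seed) != 2L || anyNA(seed) ||
      seed[1L] < 1L || seed[1L] > h || seed[2L] < 1L || seed[2L] > w)
    atStop(sprintf("seed (%s) is outside the %d x %d image",
                   paste(seed, collapse = ", "), h, w),
           "adipotrace_validation_error")
  if (!v[seed[1L], seed[2L]])
    atStop(sprintf(paste0("seed (%d, %d) is not inside a cell: the clicked ",
                          "pixel is membrane or background"),
                   seed[1L], seed[2L]),
           "adipotrace_seed_error")

  tv <- as.vector(v)
  visited <- logical(h * w)
  start <- (seed[2L] - 1L) * h + seed[1L]
  visited[start] <- TRUE
  frontier <- start
  n <- 1L
  while (length(frontier)) {
    row <- (frontier - 1L) %% h + 1L
    nb <- c(frontier[row > 1L] - 1L,          # up
            frontier[row < h] + 1L,           # down
            frontier[frontier > h] - h,       # left
            frontier[frontier <= h * (w - 1L)] + h)  # right
    nb <- unique(nb[tv[nb] & !visited[nb]])
    visited[nb] <- TRUE
    n <- n + length(nb)
    if (n > maxAreaPx)
      atStop(sprintf(paste0("leak detected: region from seed (%d, %d) exceeds ",
                            "%d px; a membrane gap likely lets the fill ",
                            "escape -- fall back to hand trace or ellipse ",
                            "approximation for this cell"),
                     seed[1L], seed[2L], as.integer(maxAreaPx)),
             "adipotrace_leak_error")
    frontier <- nb
  }
  idx <- which(visited)
  cbind(row = (idx - 1L) %% h + 1L, col = (idx - 1L) %/% h + 1L)
}

# clockwise Moore neighborhood in (row, col) with row increasing downward,
# starting from "up": up, up-right, right, down-right, down, down-left,
# left, up-left
.MOORE <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                   1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                 ncol = 2L, byrow = TRUE)

#' Trace the ordered interior boundary of a pixel region
#'
#' A region pixel is a boundary pixel if any of its 4-neighbors is outside
#' the region (pixels beyond the image edge are outside every region, so no
#' image dimensions are needed). The outer boundary is returned as an
#' ordered closed cycle by Moore-neighbor contour following, clockwise,
#' starting from the topmost-then-leftmost boundary pixel, with Jacob's
#' stopping criterion. Consecutive cycle pixels are 8-adjacent and the last
#' is 8-adjacent to the first; on thin one-pixel-wide protrusions a pixel
#' may legitimately appear twice in the cycle.
#'
#' @param pixels integer matrix `(row, col)` of a non-empty 4-connected
#'   pixel set (e.g. from [fillFromSeed()]).
#' @return integer matrix `(row, col)`: the ordered closed boundary cycle
#'   (the starting pixel is not repeated at the end). A single-pixel region
#'   yields a cycle of length 1.
#' @export
traceBoundary <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) != 2L)
    atStop("pixels must be a non-empty (row, col) matrix",
           "adipotrace_validation_error")
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) == 1L) return(pixels)

  # membership lookup on a padded local grid
  rmin <- min(pixels[, 1L]); cmin <- min(pixels[, 2L])
  lr <- pixels[, 1L] - rmin + 2L
  lc <- pixels[, 2L] - cmin + 2L
  H <- max(lr) + 1L; W <- max(lc) + 1L
  inset <- matrix(FALSE, H, W)
  inset[cbind(lr, lc)] <- TRUE

  # start: topmost, then leftmost
  sr <- min(lr); sc <- min(lc[lr == sr])
  cur <- c(sr, sc)
  bk0 <- c(sr, sc - 1L)  # left neighbor: outside by construction
  bk <- bk0
  path <- matrix(0L, 4L * nrow(pixels) + 8L, 2L)
  path[1L, ] <- cur
  np <- 1L
  repeat {
    d <- bk - cur
    i <- which(.MOORE[, 1L] == d[1L] & .MOORE[, 2L] == d[2L])
    found <- FALSE
    for (step in 1L:8L) {
      j <- (i + step - 1L) %% 8L + 1L
      cand <- cur + .MOORE[j, ]
      if (inset[cand[1L], cand[2L]]) {
        jprev <- (i + step - 2L) %% 8L + 1L
        bk <- cur + .MOORE[jprev, ]
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (cannot happen for n >= 2 connected)
    # Jacob's criterion: back at the start, entering from the same backtrack
    if (cur[1L] == sr && cur[2L] == sc && bk[1L] == bk0[1L] && bk[2L] == bk0[2L])
      break
    np <- np + 1L
    if (np > nrow(path)) break  # safety net; unreachable for valid input
    path[np, ] <- cur
  }
  out <- path[seq_len(np), , drop = FALSE]
  out[, 1L] <- out[, 1L] + rmin - 2L
  out[, 2L] <- out[, 2L] + cmin - 2L
  colnames(out) <- c("row", "col")
  out
}

# contour length: 1 per 4-step, sqrt(2) per diagonal, including closure
.perimeterOf <- function(boundary) {
  n <- nrow(boundary)
  if (n < 2L) return(0)
  nxt <- rbind(boundary[-1L, , drop = FALSE], boundary[1L, , drop = FALSE])
  d <- abs(nxt - boundary)
  sum(ifelse(d[, 1L] + d[, 2L] == 2L, sqrt(2), 1))
}

#' Measure one cell in trace mode
#'
#' Composes [fillFromSeed()] and [traceBoundary()]: fills the 4-connected
#' bright interior from the seed, traces its interior boundary, counts
#' interior pixels as the area (boundary pixels are part of the region) and
#' calibrates to square microns. Deterministic: any seed inside the same
#' cell gives the identical region, area and boundary.
#'
#' @param mask a [BinaryMask] from [transformPipeline()].
#' @param seed `(row, col)` pixel inside the cell.
#' @param label cell identifier.
#' @param calib a [ScaleCalibration] or microns-per-pixel scalar.
#' @param maxAreaPx leak guard passed to [fillFromSeed()]; the default
#'   allows a region up to 25% of the image area before declaring a
#'   membrane-gap leak.
#' @param runIndex repeat-run index for bookkeeping.
#' @return a [CellMeasurement] with a [TracedRegion] geometry. Regions
#'   touching the image border are measured but flagged
#'   (`"touches_border"`), since their true extent is unknown.
#' @export
measureCellTM <- function(mask, seed, label = "cell", calib = 1,
                          maxAreaPx = NULL, runIndex = 1L) {
  stopifnot(is(mask, "BinaryMask"))
  calib <- ScaleCalibration(calib)
  d <- dim(mask)
  if (is.null(maxAreaPx)) maxAreaPx <- 0.25 * d[1L] * d[2L]
  px <- fillFromSeed(mask, seed, maxAreaPx = maxAreaPx)
  bnd <- traceBoundary(px)
  touches <- any(px[, 1L] == 1L | px[, 1L] == d[1L] |
                 px[, 2L] == 1L | px[, 2L] == d[2L])
  region <- new("TracedRegion", pixels = px, boundary = bnd,
                areaPx = nrow(px), perimeterPx = .perimeterOf(bnd),
                label = as.character(label), touchesBorder = touches)
  new("CellMeasurement", cellId = as.character(label), method = "TM",
      runIndex = as.integer(runIndex), areaPx = as.numeric(nrow(px)),
      areaUm2 = areaPxToUm2(nrow(px), calib),
      micronsPerPixel = micronsPerPixel(calib),
      geometry = region,
      flags = if (touches) "touches_border" else character(0))
}
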