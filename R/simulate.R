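# Synthetic adipose histology with exact ground truth. The generator
# emulates what the transform + trace pipeline must cope with in real H&E
# fields: bright lipid lumens, thin dark membranes, membrane gaps, small
# stain/debris speckles and sensor noise. Intensity levels (background
# ~0.55, interior ~0.95, membrane ~0.10) are chosen so the published
# default transform parameters (shadows 0.15, low level in 0.9, threshold
# 0.8) separate interior from membrane and background.

.INTERIOR_I <- 0.95
.MEMBRANE_I <- 0.10
.BACKGROUND_I <- 0.55

# run expr with a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# radial outline r(theta) of one cell; shape$ak/bk are harmonics k = 2..5
# normalized so the perturbation peaks at +/- irregularity
.shapeRadius <- function(shape, theta) {
  r <- rep(shape$r0, length(theta))
  if (shape$irregularity > 0) {
    p <- 0
    for (k in 2:5)
      p <- p + shape$ak[k - 1L] * cos(k * theta) + shape$bk[k - 1L] * sin(k * theta)
    r <- shape$r0 * (1 + shape$irregularity * p)
  }
  pmax(r, 2)
}

#' Simulate an adipose histology field with ground truth
#'
#' Generates an H&E-like image of non-overlapping adipocytes -- bright
#' lipid-vacuole interiors ringed by thin dark membranes on a mid-grey
#' background -- together with the exact rasterized interior pixel set of
#' every cell. Optional features emulate sub-optimal tissue: membrane gap
#' arcs (deteriorated membranes, through which a trace-mode fill escapes),
#' small dark/bright background speckles (artifacts) and additive Gaussian
#' intensity noise. Fully reproducible from `rngSeed`; the caller's RNG
#' state is left untouched.
#'
#' With `irregularity = 0` cells are discs with radii drawn uniformly from
#' `radiusRange`. With `irregularity > 0` cell outlines are star-convex
#' shapes `r(theta) = r0 * (1 + irregularity * p(theta))`, where `p` is a
#' random harmonic perturbation (orders 2-5) normalized to peak at 1 --
#' non-elliptical contours on which ellipse approximation degrades while
#' trace mode still follows the boundary.
#'
#' @param spec a [SyntheticSpec].
#' @param irregularity radial perturbation amplitude in `[0, 0.9]`;
#'   0 gives discs.
#' @return a list with elements `image` (an [ImageGrid]) and `truth`
#'   (an [AdiposeTruth]).
#' @examples
#' sim <- simulateAdipose(SyntheticSpec(height = 256, width = 256,
#'                                      nCells = 3, radiusRange = c(25, 35),
#'                                      noiseSd = 0, speckleCount = 0))
#' sim$truth
#' @export
simulateAdipose <- function(spec, irregularity = 0) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (!is.numeric(irregularity) || length(irregularity) != 1L ||
      !is.finite(irregularity) || irregularity < 0 || irregularity > 0.9)
    atStop("irregularity must lie in [0, 0.9]", "adipotrace_validation_error")
  .withSeed(spec@rngSeed, .simulateAdipose(spec, irregularity))
}

.simulateAdipose <- function(spec, irregularity) {
  h <- spec@height; w <- spec@width
  t <- spec@membraneThickness
  img <- matrix(.BACKGROUND_I, h, w)

  # ---- draw shapes and place them without overlap (rejection sampling)
  shapes <- vector("list", spec@nCells)
  centers <- matrix(0, spec@nCells, 2L)
  outer_r <- numeric(spec@nCells)
  attempts <- 0L
  max_attempts <- 200L * spec@nCells
  for (i in seq_len(spec@nCells)) {
    r0 <- runif(1L, spec@radiusRange[1L], spec@radiusRange[2L])
    sh <- list(r0 = r0, irregularity = irregularity,
               ak = numeric(4L), bk = numeric(4L))
    if (irregularity > 0) {
      ak <- rnorm(4L); bk <- rnorm(4L)
      th <- seq(0, 2 * pi, length.out = 720L)
      p <- 0
      for (k in 2:5) p <- p + ak[k - 1L] * cos(k * th) + bk[k - 1L] * sin(k * th)
      m <- max(abs(p))
      if (m > 0) { ak <- ak / m; bk <- bk / m }
      sh$ak <- ak; sh$bk <- bk
    }
    ro <- r0 * (1 + irregularity) + t
    margin <- ceiling(ro) + 2L
    if (2L * margin >= min(h, w))
      atStop("cells too large for the image: reduce radii or enlarge the field",
             "adipotrace_generation_error")
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        atStop(paste0("could not place all cells without overlap after ",
                      max_attempts, " attempts: use fewer or smaller cells"),
               "adipotrace_generation_error")
      cr <- sample(margin:(h - margin), 1L)
      cc <- sample(margin:(w - margin), 1L)
      if (i == 1L) break
      prev <- seq_len(i - 1L)
      dd <- sqrt((centers[prev, 1L] - cr)^2 + (centers[prev, 2L] - cc)^2)
      if (all(dd > outer_r[prev] + ro + 3)) break
    }
    centers[i, ] <- c(cr, cc)
    outer_r[i] <- ro
    shapes[[i]] <- sh
  }

  gapped <- runif(spec@nCells) < spec@gapProbability
  gap_angle <- runif(spec@nCells, -pi, pi)

  # ---- rasterize cells
  interiors <- vector("list", spec@nCells)
  for (i in seq_len(spec@nCells)) {
    cr <- centers[i, 1L]; cc <- centers[i, 2L]
    ext <- ceiling(outer_r[i]) + 1L
    rr <- max(1L, cr - ext):min(h, cr + ext)
    cl <- max(1L, cc - ext):min(w, cc + ext)
    DY <- matrix(rr - cr, length(rr), length(cl))
    DX <- matrix(cl - cc, length(rr), length(cl), byrow = TRUE)
    D <- sqrt(DY^2 + DX^2)
    TH <- atan2(DY, DX)
    RT <- matrix(.shapeRadius(shapes[[i]], as.vector(TH)), length(rr), length(cl))
    interior <- D <= RT
    membrane <- !interior & D <= RT + t
    sub <- img[rr, cl]
    sub[membrane] <- .MEMBRANE_I
    if (gapped[i]) {
      ad <- atan2(sin(TH - gap_angle[i]), cos(TH - gap_angle[i]))
      sub[membrane & abs(ad) <= spec@gapArc / 2] <- .INTERIOR_I
    }
    sub[interior] <- .INTERIOR_I
    img[rr, cl] <- sub
    gidx <- outer(rr, (cl - 1L) * h, "+")
    interiors[[i]] <- sort(gidx[interior])
  }

  # ---- background speckles (dark debris / bright tears), kept clear of
  # cells so the ground truth stays exact
  for (s in seq_len(spec@speckleCount)) {
    for (try in 1:50) {
      pr <- sample.int(h, 1L); pc <- sample.int(w, 1L)
      dd <- sqrt((centers[, 1L] - pr)^2 + (centers[, 2L] - pc)^2)
      if (all(dd > outer_r + 4)) break
      if (try == 50L) pr <- NA_integer_
    }
    if (is.na(pr)) next
    brad <- sample(c(0.5, 1, 1.5), 1L)       # 1 / 5 / 9 px blobs
    ival <- sample(c(0.10, 0.90), 1L)
    rr <- max(1L, pr - 2L):min(h, pr + 2L)
    cl <- max(1L, pc - 2L):min(w, pc + 2L)
    DY <- matrix(rr - pr, length(rr), length(cl))
    DX <- matrix(cl - pc, length(rr), length(cl), byrow = TRUE)
    sub <- img[rr, cl]
    sub[DY^2 + DX^2 <= brad^2] <- ival
    img[rr, cl] <- sub
  }

  # ---- intensity noise
  if (spec@noiseSd > 0)
    img <- pmin(pmax(img + rnorm(h * w, 0, spec@noiseSd), 0), 1)

  cells <- data.frame(
    cell_id = sprintf("C%02d", seq_len(spec@nCells)),
    center_row = centers[, 1L], center_col = centers[, 2L],
    base_radius = vapply(shapes, function(s) s$r0, numeric(1)),
    has_gap = gapped, gap_angle = gap_angle,
    true_area_px = lengths(interiors), stringsAsFactors = FALSE)

  truth <- new("AdiposeTruth", dim = c(h, w), cells = cells,
               interiors = interiors, shapes = shapes)
  list(image = ImageGrid(img), truth = truth)
}

#' Ground-truth table of a synthetic field
#'
#' @param truth an [AdiposeTruth].
#' @return the per-cell data.frame (`cell_id`, `center_row`, `center_col`,
#'   `base_radius`, `has_gap`, `gap_angle`, `true_area_px`).
#' @export
truthTable <- function(truth) {
  stopifnot(is(truth, "AdiposeTruth"))
  truth@cells
}

#' Reference ellipse axes of a synthetic cell
#'
#' Derives the axes an ideal operator would click for the ellipse
#' approximation: the major axis is the longest diameter of the true
#' outline through the center (`2A = max over theta of
#' r(theta) + r(theta + pi)`), and the semi-minor length is the
#' half-diameter perpendicular to it. For a disc this is the diameter in
#' any direction and EA is exact up to rasterization; for irregular
#' outlines pi*A*B deviates from the true area -- the geometric reason EA
#' degrades with shape irregularity.
#'
#' @param truth an [AdiposeTruth].
#' @param cell cell id or index.
#' @return an [EllipseApprox] labeled with the cell id.
#' @export
truthAxes <- function(truth, cell) {
  stopifnot(is(truth, "AdiposeTruth"))
  i <- .truthIndex(truth, cell)
  sh <- truth@shapes[[i]]
  ctr <- c(truth@cells$center_row[i], truth@cells$center_col[i])
  th <- seq(0, pi, length.out = 1024L)[-1024L]
  r1 <- .shapeRadius(sh, th)
  r2 <- .shapeRadius(sh, th + pi)
  k <- which.max(r1 + r2)
  thA <- th[k]
  A1 <- r1[k]; A2 <- r2[k]
  B <- (.shapeRadius(sh, thA + pi / 2) + .shapeRadius(sh, thA + 3 * pi / 2)) / 2
  p1 <- ctr + A1 * c(sin(thA), cos(thA))
  p2 <- ctr + A2 * c(sin(thA + pi), cos(thA + pi))
  makeEllipse(p1, p2, b = min(B, sqrt(sum((p2 - p1)^2)) / 2),
              label = truth@cells$cell_id[i])
}

#' Reference hand-trace polygon of a synthetic cell
#'
#' Places `nVertices` polygon vertices on the true cell outline, optionally
#' offset to the mid-membrane or outer membrane edge (where an operator
#' traces the visible dark ridge) and optionally radially jittered to
#' emulate operator click variability (jitter draws from the caller's RNG).
#'
#' @param truth an [AdiposeTruth].
#' @param cell cell id or index.
#' @param nVertices number of polygon vertices (>= 3).
#' @param edge `"inner"` (the lumen boundary, offset 0), `"mid"`
#'   (+ membrane/2) or `"outer"` (+ membrane thickness).
#' @param membraneThickness membrane thickness in px used for the offset
#'   (match the generating [SyntheticSpec]).
#' @param jitterSd standard deviation (px) of radial vertex jitter.
#' @return a [PolygonTrace] labeled with the cell id.
#' @export
truthPolygon <- function(truth, cell, nVertices = 24L,
                         edge = c("mid", "inner", "outer"),
                         membraneThickness = 4, jitterSd = 0) {
  stopifnot(is(truth, "AdiposeTruth"))
  edge <- match.arg(edge)
  i <- .truthIndex(truth, cell)
  sh <- truth@shapes[[i]]
  ctr <- c(truth@cells$center_row[i], truth@cells$center_col[i])
  off <- switch(edge, inner = 0, mid = membraneThickness / 2,
                outer = membraneThickness)
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  R <- .shapeRadius(sh, th) + off
  if (jitterSd > 0) R <- pmax(R + rnorm(nVertices, 0, jitterSd), 1)
  PolygonTrace(cbind(ctr[1L] + R * sin(th), ctr[2L] + R * cos(th)),
               label = truth@cells$cell_id[i])
}

#' Sample interior seed points of a synthetic cell
#'
#' Draws `n` distinct pixels from the cell's true interior (from the
#' caller's RNG), for exercising trace mode with different click positions.
#'
#' @param truth an [AdiposeTruth].
#' @param cell cell id or index.
#' @param n number of distinct seeds.
#' @return integer matrix `(row, col)` with `n` rows.
#' @export
truthSeeds <- function(truth, cell, n = 1L) {
  stopifnot(is(truth, "AdiposeTruth"))
  i <- .truthIndex(truth, cell)
  idx <- truth@interiors[[i]]
  n <- as.integer(n)
  if (n < 1L || n > length(idx))
    atStop("n must be between 1 and the interior size",
           "adipotrace_validation_error")
  pick <- if (length(idx) == 1L) idx else sample(idx, n)
  hh <- truth@dim[1L]
  cbind(row = (pick - 1L) %% hh + 1L, col = (pick - 1L) %/% hh + 1L)
}
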