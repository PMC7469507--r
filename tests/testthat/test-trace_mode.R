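# Seed-click flood fill, boundary tracing and trace-mode measurement.

test_that("flood fill returns exactly the seeded component", {
  m <- matrix(FALSE, 21, 21); m[9:13, 9:13] <- TRUE
  px <- fillFromSeed(BinaryMask(m), c(11, 11))
  expect_equal(nrow(px), 25)
  expect_setequal(pixelKey(px),
                  pixelKey(which(m, arr.ind = TRUE)))
})

test_that("a seed on membrane/background is a clear error", {
  m <- matrix(FALSE, 21, 21); m[9:13, 9:13] <- TRUE
  expect_error(fillFromSeed(BinaryMask(m), c(2, 2)),
               "not inside a cell", class = "adipotrace_seed_error")
  expect_error(fillFromSeed(BinaryMask(m), c(50, 2)),
               class = "adipotrace_validation_error")
})

test_that("fill does not cross a background channel between two cells", {
  m <- discMask(60, 120, 30, 30, 18) | discMask(60, 120, 30, 90, 18)
  m[, 59:60] <- FALSE  # 2-px channel
  px <- fillFromSeed(BinaryMask(m), c(30, 30))
  lab <- oracleComponents(m)
  expect_equal(nrow(px), sum(lab == lab[30, 30], na.rm = TRUE))
  expect_true(all(px[, 2] < 59))
})

test_that("component growth beyond the guard raises a leak error", {
  m <- matrix(TRUE, 50, 50)
  expect_error(fillFromSeed(BinaryMask(m), c(25, 25), maxAreaPx = 100),
               "leak detected", class = "adipotrace_leak_error")
})

test_that("boundary of a 3x3 block is the 8-pixel clockwise ring", {
  px <- which(matrix(TRUE, 3, 3), arr.ind = TRUE)
  b <- traceBoundary(px)
  expect_equal(nrow(b), 8)
  expect_false(any(b[, 1] == 2 & b[, 2] == 2))  # center excluded
  # clockwise from topmost-leftmost
  expect_equal(unname(b[1, ]), c(1, 1))
  expect_equal(unname(b[2, ]), c(1, 2))
})

test_that("a single pixel region yields a cycle of length 1", {
  b <- traceBoundary(cbind(5L, 7L))
  expect_equal(nrow(b), 1)
  expect_equal(unname(b[1, ]), c(5, 7))
})

test_that("disc boundary equals the erosion-based boundary set", {
  m <- discMask(50, 50, 25, 25, 20)
  b <- traceBoundary(which(m, arr.ind = TRUE))
  want <- which(oracleBoundarySet(m), arr.ind = TRUE)
  expect_setequal(unique(pixelKey(b)), pixelKey(want))
})

test_that("boundary cycles are closed chains of 8-adjacent pixels", {
  set.seed(13)
  for (i in 1:6) {
    m <- matrix(FALSE, 40, 40)
    # random blob: union of a few overlapping discs -> 4-connected region
    cr <- sample(12:28, 1); cc <- sample(12:28, 1)
    m <- m | discMask(40, 40, cr, cc, sample(4:9, 1))
    m <- m | discMask(40, 40, cr + sample(-4:4, 1), cc + sample(-4:4, 1),
                      sample(3:8, 1))
    px <- fillFromSeed(BinaryMask(m), c(cr, cc))
    b <- traceBoundary(px)
    nxt <- rbind(b[-1, , drop = FALSE], b[1, , drop = FALSE])
    d <- abs(nxt - b)
    expect_true(all(pmax(d[, 1], d[, 2]) == 1 | (d[, 1] == 0 & d[, 2] == 0)))
  }
})

test_that("trace-mode area of a rasterized disc matches the pixel-count oracle", {
  m <- discMask(128, 128, 64, 64, 50)
  meas <- measureCellTM(BinaryMask(m), c(64, 64), label = "c1", calib = 1,
                        maxAreaPx = Inf)
  expect_equal(areaPx(meas), sum(m))                      # exact pixel count
  expect_equal(areaPx(meas), pi * 50^2, tolerance = 0.02) # rasterization only
  expect_equal(areaUm2(meas), areaPx(meas))
  expect_equal(perimeterPx(geometryOf(meas)), 2 * pi * 50, tolerance = 0.08)
  expect_false(touchesBorder(geometryOf(meas)))
})

test_that("any interior click yields the identical region and area", {
  m <- discMask(80, 80, 40, 40, 25)
  m1 <- measureCellTM(BinaryMask(m), c(40, 40), maxAreaPx = Inf)
  m2 <- measureCellTM(BinaryMask(m), c(22, 46), maxAreaPx = Inf)  # off-center
  expect_identical(interiorPixels(geometryOf(m1)), interiorPixels(geometryOf(m2)))
  expect_identical(areaPx(m1), areaPx(m2))
  # three repeats from arbitrary interior seeds: zero variance
  seeds <- list(c(40, 40), c(30, 30), c(50, 45))
  areas <- vapply(seeds, function(s)
    areaPx(measureCellTM(BinaryMask(m), s, maxAreaPx = Inf)), numeric(1))
  expect_identical(sd(areas), 0)
})

test_that("click invariance holds exhaustively over a small component", {
  m <- matrix(FALSE, 32, 32)
  m <- m | discMask(32, 32, 16, 14, 7) | discMask(32, 32, 18, 20, 6)
  ref <- fillFromSeed(BinaryMask(m), c(16, 14))
  keys <- pixelKey(ref)
  for (k in seq_len(nrow(ref))) {
    got <- fillFromSeed(BinaryMask(m), ref[k, ])
    expect_identical(pixelKey(got), keys)
  }
})

test_that("fill area agrees with component labeling on random masks", {
  set.seed(17)
  for (i in 1:12) {
    m <- matrix(runif(64 * 64) > 0.55, 64, 64)
    lab <- oracleComponents(m)
    tru <- which(m)
    seed_idx <- sample(tru, 1)
    s <- c((seed_idx - 1) %% 64 + 1, (seed_idx - 1) %/% 64 + 1)
    px <- fillFromSeed(BinaryMask(m), s)
    expect_equal(nrow(px), sum(lab == lab[s[1], s[2]], na.rm = TRUE))
  }
})

test_that("regions on the image edge are measured but flagged", {
  m <- matrix(FALSE, 30, 30); m[1:6, 10:15] <- TRUE
  meas <- measureCellTM(BinaryMask(m), c(3, 12))
  expect_true(touchesBorder(geometryOf(meas)))
  expect_identical(qualityFlags(meas), "touches_border")
  expect_equal(areaPx(meas), 36)
})

test_that("trace-mode interior area never exceeds an outer-edge hand trace", {
  sim <- simulateAdipose(SyntheticSpec(height = 400, width = 400, nCells = 4,
                                       radiusRange = c(30, 45), noiseSd = 0,
                                       speckleCount = 0, rngSeed = 21))
  mask <- transformPipeline(sim$image)
  tt <- truthTable(sim$truth)
  for (i in seq_len(nrow(tt))) {
    tm <- measureCellTM(mask, c(tt$center_row[i], tt$center_col[i]))
    ht <- measureCellHT(truthPolygon(sim$truth, i, nVertices = 48,
                                     edge = "outer"))
    expect_lte(areaPx(tm), areaPx(ht))
  }
})
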