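# Synthetic adipose fields: determinism, ground-truth invariants, and
# end-to-end recovery through the transform + trace pipeline.

smallSpec <- function(...) {
  args <- utils::modifyList(
    list(height = 420, width = 420, nCells = 5, radiusRange = c(38, 50),
         noiseSd = 0, speckleCount = 0, gapProbability = 0, rngSeed = 101),
    list(...))
  do.call(SyntheticSpec, args)
}

test_that("the same seed reproduces the field bit for bit", {
  a <- simulateAdipose(smallSpec(noiseSd = 0.03, speckleCount = 15))
  b <- simulateAdipose(smallSpec(noiseSd = 0.03, speckleCount = 15))
  expect_identical(intensityValues(a$image), intensityValues(b$image))
  expect_identical(truthTable(a$truth), truthTable(b$truth))
  c <- simulateAdipose(smallSpec(noiseSd = 0.03, speckleCount = 15,
                                 rngSeed = 102))
  expect_false(identical(intensityValues(a$image), intensityValues(c$image)))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(55); before <- runif(3)
  set.seed(55); invisible(simulateAdipose(smallSpec())); after <- runif(3)
  expect_identical(before, after)
})

test_that("ground-truth interiors are disjoint and match the stated areas", {
  sim <- simulateAdipose(smallSpec())
  tt <- truthTable(sim$truth)
  expect_equal(nCells(sim$truth), 5)
  all_px <- do.call(rbind, lapply(seq_len(5), function(i)
    trueInterior(sim$truth, i)))
  expect_equal(nrow(all_px), sum(tt$true_area_px))
  expect_false(anyDuplicated(paste(all_px[, 1], all_px[, 2])) > 0)
  # interior pixels really carry interior intensity in the clean image
  v <- intensityValues(sim$image)
  expect_true(all(v[all_px] == 0.95))
})

test_that("irregularity 0 produces exact rasterized discs", {
  sim <- simulateAdipose(smallSpec())
  tt <- truthTable(sim$truth)
  for (i in 1:nrow(tt)) {
    want <- which(discMask(420, 420, tt$center_row[i], tt$center_col[i],
                           tt$base_radius[i]), arr.ind = TRUE)
    expect_identical(pixelKey(trueInterior(sim$truth, i)), pixelKey(want))
  }
})

test_that("pipeline + trace mode recovers clean-field areas within 5%", {
  sim <- simulateAdipose(smallSpec())
  mask <- transformPipeline(sim$image)
  tt <- truthTable(sim$truth)
  for (i in 1:nrow(tt)) {
    m <- measureCellTM(mask, c(tt$center_row[i], tt$center_col[i]),
                       label = tt$cell_id[i])
    expect_equal(areaPx(m), tt$true_area_px[i], tolerance = 0.05)
    # the recovered region must lie inside the true interior (+ nothing else)
    got <- interiorPixels(geometryOf(m))
    expect_true(all(pixelKey(got) %in% pixelKey(trueInterior(sim$truth, i))))
  }
})

test_that("a wide membrane gap inflates the component and trips the leak guard", {
  spec <- smallSpec(gapProbability = 1, gapArc = 1.2)
  sim <- simulateAdipose(spec)
  tt <- truthTable(sim$truth)
  expect_true(all(tt$has_gap))
  # binarize without despeckle so the breach geometry is untouched
  mask <- binarize(adjustLevels(sim$image), 0.8)
  lab <- oracleComponents(maskValues(mask))
  for (i in 1:nrow(tt)) {
    s <- c(tt$center_row[i], tt$center_col[i])
    comp_size <- sum(lab == lab[s[1], s[2]], na.rm = TRUE)
    expect_gt(comp_size, tt$true_area_px[i])  # fill escapes through the gap
    expect_error(
      fillFromSeed(mask, s, maxAreaPx = tt$true_area_px[i] + 10),
      "leak detected", class = "adipotrace_leak_error")
  }
})

test_that("infeasible packings fail with a generation error", {
  expect_error(
    simulateAdipose(SyntheticSpec(height = 200, width = 200, nCells = 12,
                                  radiusRange = c(40, 45), rngSeed = 1)),
    class = "adipotrace_generation_error")
})

test_that("speckles and noise keep intensities in [0, 1]", {
  sim <- simulateAdipose(smallSpec(noiseSd = 0.15, speckleCount = 40))
  v <- intensityValues(sim$image)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("irregular outlines expose EA error while TM still traces them", {
  spec <- SyntheticSpec(height = 900, width = 900, nCells = 8,
                        radiusRange = c(38, 50), noiseSd = 0,
                        speckleCount = 0, rngSeed = 77)
  sim <- simulateAdipose(spec, irregularity = 0.4)
  mask <- transformPipeline(sim$image)
  tt <- truthTable(sim$truth)
  tm_err <- ea_err <- numeric(nrow(tt))
  for (i in 1:nrow(tt)) {
    m <- measureCellTM(mask, c(tt$center_row[i], tt$center_col[i]))
    tm_err[i] <- abs(areaPx(m) - tt$true_area_px[i]) / tt$true_area_px[i]
    ea <- ellipseArea(truthAxes(sim$truth, i))
    ea_err[i] <- abs(ea - tt$true_area_px[i]) / tt$true_area_px[i]
  }
  expect_gt(mean(ea_err), mean(tm_err))
  expect_lt(mean(tm_err), 0.05)
})

test_that("reference annotations derive from the truth geometry", {
  sim <- simulateAdipose(smallSpec())
  tt <- truthTable(sim$truth)
  # for a disc, the reference ellipse is the circle of the base radius
  e <- truthAxes(sim$truth, 1)
  expect_equal(semiMajor(e), tt$base_radius[1], tolerance = 1e-6)
  expect_equal(semiMinor(e), semiMajor(e), tolerance = 1e-6)
  expect_equal(ellipseArea(e), pi * tt$base_radius[1]^2, tolerance = 1e-6)
  # inner-edge polygons inscribe the disc; outer-edge ones circumscribe more
  pin <- polygonArea(truthPolygon(sim$truth, 1, nVertices = 60, edge = "inner"))
  pout <- polygonArea(truthPolygon(sim$truth, 1, nVertices = 60, edge = "outer",
                                   membraneThickness = 4))
  expect_lt(pin, pi * tt$base_radius[1]^2)
  expect_gt(pout, pin)
  # seeds are distinct interior pixels
  set.seed(3)
  s <- truthSeeds(sim$truth, 1, n = 3)
  expect_equal(nrow(s), 3)
  expect_true(all(pixelKey(s) %in% pixelKey(trueInterior(sim$truth, 1))))
})
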