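# The three-step transform: levels stretch, binarization, despeckle.

test_that("levels stretch maps the endpoints and midpoint as defined", {
  img <- ImageGrid(matrix(c(0, 0.15, 0.525, 0.9, 1, 0.1), 2, 3))
  out <- intensityValues(adjustLevels(img, 0.15, 0.9))
  expect_equal(out[1, 1], 0)        # below shadows
  expect_equal(out[2, 1], 0)        # at shadows
  expect_equal(out[1, 2], 0.5)      # midpoint of the ramp
  expect_equal(out[2, 2], 1)        # at low level in
  expect_equal(out[1, 3], 1)        # above
  expect_equal(out[2, 3], 0)        # below shadows
})

test_that("levels stretch is monotone non-decreasing and stays in [0, 1]", {
  set.seed(5)
  v <- sort(runif(200))
  for (p in list(c(0.15, 0.9), c(0, 1), c(0.4, 0.5))) {
    out <- intensityValues(adjustLevels(ImageGrid(matrix(v, 1)), p[1], p[2]))
    expect_true(all(diff(as.vector(out)) >= 0))
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(adjustLevels(ImageGrid(matrix(0.5)), 0.9, 0.9),
               class = "adipotrace_validation_error")
  expect_error(adjustLevels(ImageGrid(matrix(0.5)), 0.95, 0.2),
               class = "adipotrace_validation_error")
})

test_that("binarization is inclusive at the threshold", {
  img <- ImageGrid(matrix(c(0.85, 0.8, 0.79), 1, 3))
  m <- maskValues(binarize(img, 0.8))
  expect_identical(as.vector(m), c(TRUE, TRUE, FALSE))
  expect_error(binarize(img, 0), class = "adipotrace_validation_error")
  expect_error(binarize(img, 1), class = "adipotrace_validation_error")
})

test_that("lowering the threshold never turns a foreground pixel off", {
  set.seed(6)
  img <- ImageGrid(matrix(runif(400), 20, 20))
  th <- sort(runif(6, 0.05, 0.95), decreasing = TRUE)
  prev <- maskValues(binarize(img, th[1]))
  for (t in th[-1]) {
    cur <- maskValues(binarize(img, t))
    expect_true(all(cur[prev]))  # monotone growth of the foreground
    prev <- cur
  }
})

test_that("despeckle removes an isolated pixel and fixes saturated masks", {
  m <- matrix(FALSE, 64, 64); m[32, 32] <- TRUE
  expect_false(any(maskValues(despeckle(BinaryMask(m), 5, 1))))
  allt <- BinaryMask(matrix(TRUE, 32, 32))
  expect_true(all(maskValues(despeckle(allt, 5, 5))))
  expect_true(all(maskValues(despeckle(allt, 2, 1))))
})

test_that("despeckle with radius 0 is the identity for any passes", {
  set.seed(7)
  m <- matrix(runif(900) > 0.5, 30, 30)
  for (p in c(1, 3, 7))
    expect_identical(maskValues(despeckle(BinaryMask(m), 0, p)), m)
})

test_that("despeckle matches a brute-force majority-filter oracle", {
  # the scenario of record: a filled disc plus isolated speckles
  set.seed(8)
  m <- discMask(41, 41, 21, 21, 15)
  outside <- which(!discMask(41, 41, 21, 21, 19))
  m[sample(outside, 20)] <- TRUE
  got <- maskValues(despeckle(BinaryMask(m), 5, 5))
  expect_identical(got, oracleMajority(m, 5, 5))
  # speckles gone, disc interior retained (boundary may erode <= radius)
  expect_false(any(got & !discMask(41, 41, 21, 21, 15)))
  expect_true(all(got[discMask(41, 41, 21, 21, 9)]))
  # random masks, including image-edge neighborhoods
  for (i in 1:3) {
    rm <- matrix(runif(576) > 0.45, 24, 24)
    expect_identical(maskValues(despeckle(BinaryMask(rm), 2, 2)),
                     oracleMajority(rm, 2, 2))
  }
})

test_that("the pipeline equals levels -> binarize -> despeckle, hand-derived", {
  # bright disc on a dark ring on a mid background
  img <- matrix(0.5, 41, 41)
  disc <- discMask(41, 41, 21, 21, 15)
  ring <- discMask(41, 41, 21, 21, 18) & !disc
  img[ring] <- 0.1; img[disc] <- 0.95
  # stage-by-stage: 0.5 -> 0.467 (<0.8, off); 0.1 -> 0 (off); 0.95 -> 1 (on);
  # then the majority-filter oracle applied to the binarized stage
  expected <- oracleMajority(disc, 5, 5)
  got <- maskValues(transformPipeline(ImageGrid(img)))
  expect_identical(got, expected)
  expect_false(any(got & ring))
  expect_true(all(got[discMask(41, 41, 21, 21, 9)]))
})

test_that("the pipeline preserves saturation and is deterministic", {
  expect_true(all(maskValues(transformPipeline(ImageGrid(matrix(1, 24, 24))))))
  expect_false(any(maskValues(transformPipeline(ImageGrid(matrix(0, 24, 24))))))
  set.seed(9)
  img <- ImageGrid(matrix(runif(64^2), 64, 64))
  expect_identical(maskValues(transformPipeline(img)),
                   maskValues(transformPipeline(img)))
})

test_that("transform parameter validation enforces the stated ranges", {
  expect_error(TransformParams(shadows = 0.9, lowLevelIn = 0.15),
               class = "adipotrace_validation_error")
  expect_error(TransformParams(binaryThreshold = 1.2),
               class = "adipotrace_validation_error")
  expect_error(TransformParams(despeckleRadius = -1),
               class = "adipotrace_validation_error")
  expect_error(TransformParams(despecklePasses = 0),
               class = "adipotrace_validation_error")
  p <- TransformParams()
  expect_equal(c(p@shadows, p@lowLevelIn, p@binaryThreshold), c(0.15, 0.9, 0.8))
  expect_equal(c(p@despeckleRadius, p@despecklePasses), c(5L, 5L))
})
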