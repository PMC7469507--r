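# Histograms, repeatability and concordance summaries.

test_that("areas fall into half-open bins with a closed last bin", {
  h <- sizeHistogram(c(5000, 8000), edges = c(4500, 7000, 9500))
  expect_equal(binCounts(h), c(1L, 1L))
  # an area exactly on an interior edge belongs to the upper bin
  h2 <- sizeHistogram(c(7000), edges = c(4500, 7000, 9500))
  expect_equal(binCounts(h2), c(0L, 1L))
  # the maximum is kept by the closed last bin
  h3 <- sizeHistogram(c(9500), edges = c(4500, 7000, 9500))
  expect_equal(binCounts(h3), c(0L, 1L))
})

test_that("histogram counts are conserved for any edges", {
  set.seed(31)
  x <- runif(1000)
  h <- sizeHistogram(x, nBins = 6)
  expect_equal(sum(binCounts(h)), 1000L)
  expect_equal(length(binCounts(h)), 6L)
  edges <- c(0.2, 0.35, 0.6, 0.9)
  h2 <- sizeHistogram(x, edges = edges)
  expect_equal(sum(binCounts(h2)), sum(x >= 0.2 & x <= 0.9))
  expect_error(sizeHistogram(x, edges = c(1, 1, 2)),
               class = "adipotrace_validation_error")
  expect_error(sizeHistogram(x, edges = c(3, 2)),
               class = "adipotrace_validation_error")
  expect_error(sizeHistogram(numeric(0)), class = "adipotrace_validation_error")
})

test_that("repeatability reports per-group mean and sample sd", {
  df <- data.frame(
    cell_id = rep(c("c1", "c2"), each = 3),
    method = "TM",
    area_um2 = c(5000, 5000, 5000, 4, 6, 5))
  r <- repeatability(df)
  r1 <- r[r$cell_id == "c1", ]
  expect_equal(r1$mean_um2, 5000)
  expect_equal(r1$sd_um2, 0)        # no variation: identical repeats
  expect_equal(r1$n_runs, 3L)
  r2 <- repeatability(data.frame(cell_id = "c2", method = "HT",
                                 area_um2 = c(4, 6)))
  expect_equal(r2$mean_um2, 5)
  expect_equal(r2$sd_um2, sqrt(2))  # n-1 denominator
})

test_that("repeatability never pools methods and leaves single runs undefined", {
  df <- data.frame(cell_id = "c1", method = c("TM", "TM", "HT"),
                   area_um2 = c(100, 100, 900))
  r <- repeatability(df)
  expect_equal(nrow(r), 2)
  expect_equal(r$mean_um2[r$method == "TM"], 100)
  expect_equal(r$mean_um2[r$method == "HT"], 900)
  expect_true(is.na(r$sd_um2[r$method == "HT"]))  # one run: sd undefined
  expect_equal(r$sd_um2[r$method == "TM"], 0)
})

test_that("repeatability sd is zero iff all repeats are identical", {
  set.seed(37)
  for (i in 1:10) {
    vals <- if (i %% 2) rep(runif(1, 1, 9), 3) else runif(3, 1, 9)
    r <- repeatability(data.frame(cell_id = "c", method = "EA", area_um2 = vals))
    expect_identical(r$sd_um2 == 0, length(unique(vals)) == 1L)
  }
})

test_that("concordance recovers exact linear relations", {
  x <- seq(4000, 12000, length.out = 10)
  r <- concordance(x, x)
  expect_equal(slope(r), 1)
  expect_equal(intercept(r), 0)
  expect_equal(rSquared(r), 1)
  # an under-reading method: slope < 1 with a negative intercept
  r2 <- concordance(x, 0.97 * x - 50)
  expect_equal(slope(r2), 0.97)
  expect_equal(intercept(r2), -50)
  expect_equal(rSquared(r2), 1)
})

test_that("concordance equals a hand-solved normal-equations fit", {
  set.seed(41)
  x <- runif(50, 2000, 15000)
  y <- 0.9 * x + 300 + rnorm(50, 0, 500)
  r <- concordance(x, y)
  o <- oracleOLS(x, y)
  expect_equal(slope(r), o$slope, tolerance = 1e-12)
  expect_equal(intercept(r), o$intercept, tolerance = 1e-12)
  expect_equal(rSquared(r), o$r2, tolerance = 1e-12)
})

test_that("concordance is directional", {
  set.seed(43)
  x <- runif(30, 1000, 9000)
  y <- 0.8 * x + rnorm(30, 0, 800)
  expect_false(isTRUE(all.equal(slope(concordance(x, y)),
                                1 / slope(concordance(y, x)))))
})

test_that("degenerate concordance inputs are rejected", {
  expect_error(concordance(1, 1), class = "adipotrace_validation_error")
  expect_error(concordance(c(5, 5, 5), c(1, 2, 3)),
               "zero variance", class = "adipotrace_validation_error")
  expect_error(concordance(c(1, 2), c(1, NA)),
               class = "adipotrace_validation_error")
})

test_that("method pairing joins by cell id and drops unmatched cells", {
  df <- data.frame(
    cell_id = c("a", "b", "c", "a", "b", "d"),
    method = rep(c("HT", "TM"), each = 3),
    area_um2 = c(10, 20, 30, 11, 19, 99))
  expect_warning(r <- methodConcordance(df, "HT", "TM"),
                 class = "adipotrace_pairing_warning")
  expect_equal(nPairs(r), 2L)
  # runs are averaged per cell before pairing
  df2 <- data.frame(cell_id = c("a", "a", "b", "a", "b"),
                    method = c("HT", "HT", "HT", "TM", "TM"),
                    area_um2 = c(8, 12, 20, 10, 20))
  r2 <- methodConcordance(df2, "HT", "TM")
  expect_equal(slope(r2), 1)
  expect_equal(rSquared(r2), 1)
})

test_that("measurement tables carry ids, methods, areas and flags", {
  m <- measureCellTM(BinaryMask(discMask(40, 40, 20, 20, 10)), c(20, 20),
                     label = "c7", calib = 2)
  df <- measurementTable(list(m))
  expect_equal(df$cell_id, "c7")
  expect_equal(df$method, "TM")
  expect_equal(df$area_um2, 4 * df$area_px)
  expect_equal(df$flags, "")
})
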