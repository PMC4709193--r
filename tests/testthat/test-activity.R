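mkRaster <- function(m) RasterGrid(m, pixelSize = 30)

test_that("loss extraction counts pixels times pixel area by stratum and type", {
  ly <- matrix(0L, 40, 40)
  ly[1:25, 1:40] <- rep(1:10, length.out = 25)   # 1000 loss pixels
  st <- matrix(1L, 40, 40)
  at <- matrix(2L, 40, 40)                        # agriculture
  afd <- extractLoss(mkRaster(ly), mkRaster(st), mkRaster(at))
  expect_equal(sum(afd$ha), 1000 * 0.09)
  expect_equal(afd$type, "agriculture")
  expect_equal(sum(attr(afd, "annualLoss")), 90)

  # empty loss raster
  empty <- extractLoss(mkRaster(matrix(0L, 4, 4)), mkRaster(matrix(1L, 4, 4)),
                       mkRaster(matrix(0L, 4, 4)), period = 1:10)
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(attr(empty, "annualLoss")), 0)

  # unknown attribution code
  bad <- matrix(9L, 40, 40)
  expect_error(extractLoss(mkRaster(ly), mkRaster(st), mkRaster(bad)),
               "unknown attribution")
  # misaligned grids
  expect_error(extractLoss(mkRaster(ly), mkRaster(matrix(1L, 3, 3)),
                           mkRaster(at)), "misaligned")
})

test_that("gain annualization scales by period ratio and types by permit", {
  # 1200 ha gain = 13334 px at 0.09 ha; use exact areas instead: 400 px
  g <- matrix(0L, 40, 40); g[1:10, 1:40] <- 1L     # 400 px = 36 ha
  pm <- matrix(0L, 40, 40)
  pm[1:5, 1:40] <- 2L                               # fiber permit: 200 px
  ar <- annualizeGain(mkRaster(g), mkRaster(pm), sourceYears = 12,
                      refYears = 10)
  expect_equal(sum(ar), 36 * 10 / 12)
  expect_equal(ar[["fiber"]], 18 * 10 / 12)
  expect_equal(ar[["oilpalm"]], 0)
  expect_equal(ar[["native"]], 18 * 10 / 12)
  # linearity in total gain area
  g2 <- matrix(0L, 40, 40); g2[1:20, 1:40] <- 1L
  ar2 <- annualizeGain(mkRaster(g2), mkRaster(pm), 12, 10)
  expect_equal(sum(ar2), 2 * sum(ar))
  # zero gain
  expect_equal(sum(annualizeGain(mkRaster(matrix(0L, 40, 40)),
                                 mkRaster(pm), 12, 10)), 0)
})

test_that("road rule: narrow in-concession corridors are roads, blocks are not", {
  ly <- matrix(0L, 60, 60)
  conc <- matrix(1L, 60, 60)
  ly[10:11, 5:54] <- 1L        # 2 x 50 corridor
  ly[30:39, 20:29] <- 2L       # 10 x 10 block
  lab <- gridValues(classifyLoggingRoads(mkRaster(ly), mkRaster(conc)))
  expect_true(all(lab[10:11, 5:54] == 1L))
  expect_true(all(lab[32:37, 22:27] == 2L))   # block core is conversion
  # same corridor outside the concession: not road
  lab2 <- gridValues(classifyLoggingRoads(mkRaster(ly),
                                          mkRaster(matrix(0L, 60, 60))))
  expect_true(all(lab2 == 0L))
  # partition: every in-concession loss pixel is road or conversion
  expect_true(all(lab[ly > 0] %in% c(1L, 2L)))
  expect_true(all(lab[ly == 0] == 0L))
})

test_that("logging record summaries scale with the completeness convention", {
  recs <- data.frame(permit = 1:10, year = 1, ha = 100, volume_m3 = 3000)
  # 10 permits x 1 yr..., treat as 10 permit-years over tp = 10 with 1 permit
  got <- summarizeLoggingRecords(recs, tp = 10, nPermits = 1,
                                 completeness = 1)
  expect_equal(got$asl, 100)
  expect_equal(got$volume, 3000)
  gotHalf <- summarizeLoggingRecords(recs, tp = 10, nPermits = 2,
                                     completeness = 0.5,
                                     scaleUp = "proportional-total")
  expect_equal(gotHalf$asl, 200)
  # observed-mean scale-up: mean per permit-year times all permit-years
  gotOm <- summarizeLoggingRecords(recs, tp = 10, nPermits = 2,
                                   completeness = 0.5)
  expect_equal(gotOm$asl, 100 * 20 / 10)
  # missing volume retained as partial
  recs$volume_m3[3] <- NA
  gotNA <- summarizeLoggingRecords(recs, tp = 10, nPermits = 1)
  expect_equal(gotNA$asl, 100)
  expect_true(isTRUE(attr(gotNA$volume, "partial")))
  expect_warning(summarizeLoggingRecords(recs[0, ], 10, 1), "no logging")
})

test_that("trend test matches the normal-equation oracle and handles edges", {
  set.seed(17)
  y <- stats::runif(10, 500, 1500)
  got <- trendTest(y)
  oracle <- bruteForceOLS(y)
  expect_equal(got$slope, oracle$slope, tolerance = 1e-9)
  expect_equal(got$r2, oracle$r2, tolerance = 1e-9)
  expect_equal(got$f, oracle$f, tolerance = 1e-9)
  expect_equal(c(got$df1, got$df2), c(1, 8))
  # perfectly linear: R2 = 1; constant: slope 0, R2 = 0
  expect_equal(suppressWarnings(trendTest(seq(100, 1000, by = 100))$r2), 1)
  const <- trendTest(rep(5, 10))
  expect_equal(const$slope, 0)
  expect_equal(const$r2, 0)
  expect_error(trendTest(c(1, 2)), "length")
})

test_that("area conservation: annual series sums to the stratum cross-tab", {
  land <- generateLandscape(smallConfig(seed = 31L))
  afd <- land@activityTruth@afd
  expect_equal(sum(attr(afd, "annualLoss")), sum(afd$ha))
})
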