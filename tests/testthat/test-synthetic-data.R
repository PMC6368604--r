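test_that("degenerate occurrence chains produce all-dry and all-wet years", {
  g <- smallGrid(1L)
  dry <- genRainfall(g, weatherGenParams(p01 = 0, p11 = 0, seasonAmp = 0,
                                         years = 2000:2002), seed = 1)
  expect_true(all(cubeValues(dry$rain) == 0))
  wet <- genRainfall(g, weatherGenParams(p01 = 1, p11 = 1, seasonAmp = 0,
                                         years = 2000:2002), seed = 1)
  yi <- format(cubeTime(wet$rain), "%Y")
  wetDays <- tapply(cubeValues(wet$rain)[1, ] >= 0, yi, sum)
  expect_equal(as.integer(wetDays), c(366L, 365L, 365L))  # 2000 is leap
  expect_true(all(cubeValues(wet$rain) > 0))
})

test_that("stationary wet-day fraction matches the two-state chain and the
           annual total matches its expectation", {
  g <- smallGrid(1L)
  ## p01 = p11 = 0.3 has stationary wet probability 0.3
  rf <- genRainfall(g, weatherGenParams(p01 = 0.3, p11 = 0.3,
                                        gammaShape = 1, gammaScale = 10,
                                        seasonAmp = 0, years = 1901:2100),
                    seed = 11)
  x <- cubeValues(rf$rain)[1, ]
  frac <- mean(x > 0)
  tol <- 3 * sqrt(0.3 * 0.7 / length(x))
  expect_lt(abs(frac - 0.3), tol)
  ## E[annual] = E[wet days] * shape * scale
  yi <- format(cubeTime(rf$rain), "%Y")
  ann <- tapply(x, yi, sum)
  expect_lt(abs(mean(ann) - 365.25 * 0.3 * 10) / (365.25 * 0.3 * 10), 0.05)
})

test_that("generation is deterministic given (seed, pixel, year) and
           independent of grid assembly order", {
  g <- smallGrid(2L)
  p <- weatherGenParams(years = 2000:2003)
  a <- genRainfall(g, p, seed = 7)
  b <- genRainfall(g, p, seed = 7)
  expect_identical(cubeValues(a$rain), cubeValues(b$rain))
  c <- genRainfall(g, p, seed = 8)
  expect_false(identical(cubeValues(a$rain), cubeValues(c$rain)))
})

test_that("heavy-rain-frequency trend responds monotonically to the
           gamma-scale trend over a 3-point sweep", {
  g <- smallGrid(2L)
  slopes <- vapply(c(0, 0.08, 0.16), function(ts) {
    rf <- genRainfall(g, weatherGenParams(p01 = 0.25, p11 = 0.55,
                                          gammaScale = 8, trendScale = ts,
                                          years = 1990:2013), seed = 3)
    clim <- computeClimatology(rf$rain)
    med <- median(trendMap(clim, "heavy_rain_freq",
                           correction = "none")$sen_slope)
    med
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("noiseless vegetation recovers the prescribed woody trajectory
           exactly through the annual VOD minimum", {
  g <- smallGrid(2L)
  rf <- genRainfall(g, weatherGenParams(years = 1992:2012), seed = 5)
  veg <- genVegetation(rf$rain,
                       vegetationGenParams(laiNoiseSd = 0, vodNoiseSd = 0,
                                           woodyTrend = 0.2,
                                           woodyRainCoupling = 0),
                       seed = 5)
  pan <- computeVegetation(veg$lai, veg$vod)
  woody <- panelVar(pan, "woody_cover")
  expect_equal(unname(woody), unname(veg$truth$woodyTrue), tolerance = 1e-12)
  ## linear truth, noiseless: Theil-Sen slope equals the prescribed trend
  tr <- trendMap(pan, "woody_cover", correction = "none")
  expect_equal(tr$sen_slope, rep(0.2, nPixels(g)), tolerance = 1e-9)
  ## and the noiseless annual LAI max equals the generator's target
  expect_equal(unname(panelVar(pan, "lai_max")),
               unname(veg$truth$laiMaxTrue), tolerance = 1e-12)
})

test_that("covariates are deterministic, and independent of the woody trend
           when the cross-correlation is zero", {
  g <- savGrid(latRange = c(-20, -10), lonRange = c(20, 30), cellSize = 0.5)
  expect_equal(nPixels(g), 400)
  a <- genCovariates(g, seed = 21)
  b <- genCovariates(g, seed = 21)
  expect_identical(a, b)
  set.seed(99)
  w <- rnorm(400)
  for (v in c("d_temperature", "d_cloud", "d_population", "d_burned"))
    expect_lt(abs(cor(a[[v]], w)), 0.15)
  ## prescribed coupling is honoured
  cc <- genCovariates(g, seed = 21, crossCor = 0.8, woodyTrendTrue = w)
  expect_gt(cor(cc$d_temperature, w), 0.6)
})

test_that("the full simulation is reproducible end to end from one seed", {
  a <- simulateSavanna(smallGrid(2L), seed = 31, years = 2000:2009)
  b <- simulateSavanna(smallGrid(2L), seed = 31, years = 2000:2009)
  expect_identical(cubeValues(a$rain), cubeValues(b$rain))
  expect_identical(cubeValues(a$lai), cubeValues(b$lai))
  expect_identical(cubeValues(a$vod), cubeValues(b$vod))
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth, b$truth)
})
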