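test_that("window count and center-year indexing follow the moving-window
           convention", {
  set.seed(2)
  ny <- 34
  lai <- rnorm(ny); rain <- rnorm(ny)
  bs <- betaSeries(lai, rain, 1982:2015, window = 15)
  expect_equal(ncol(bs$beta), 20)  # 34 - 15 + 1
  expect_equal(bs$centers[1], 1989)
  expect_equal(bs$centers[20], 2008)
})

test_that("perfect dependence gives beta 1 in every window and a constant
           series has no trend", {
  x <- rnorm(30, 500, 80)
  bs <- betaSeries(x, x, 1986:2015, window = 15)
  expect_equal(as.numeric(bs$beta), rep(1, 16), tolerance = 1e-12)
  bt <- betaTrend(bs)
  expect_equal(bt$sen_slope, 0)
  expect_false(bt$significant_95)
})

test_that("with per-window normalization every beta equals the window
           Pearson correlation and lies in [-1, 1]", {
  set.seed(5)
  ny <- 28
  rain <- rnorm(ny)
  lai <- 0.6 * rain + rnorm(ny, 0, 0.5)
  bs <- betaSeries(lai, rain, seq_len(ny) + 1987, window = 15,
                   normScope = "window")
  for (w in seq_len(ncol(bs$beta))) {
    idx <- w:(w + 14)
    expect_equal(bs$beta[1, w], cor(rain[idx], lai[idx]), tolerance = 1e-12)
  }
  expect_true(all(abs(bs$beta) <= 1 + 1e-12))
})

test_that("shifting all years by a constant leaves every beta unchanged and
           the trend is invariant to monotone re-indexing of windows", {
  set.seed(6)
  ny <- 30
  rain <- rnorm(ny); lai <- 0.4 * rain + rnorm(ny, 0, 0.3)
  b1 <- betaSeries(lai, rain, 1:ny)
  b2 <- betaSeries(lai, rain, 1001:(1000 + ny))
  expect_identical(b1$beta, b2$beta)
  ## MK/Theil-Sen significance is invariant to any monotone re-indexing of
  ## the window axis (slopes rescale, signs and p values do not)
  t1 <- betaTrend(b1)
  b3 <- b1; b3$centers <- b1$centers * 3L
  t3 <- betaTrend(b3)
  expect_equal(t1$p_value, t3$p_value, tolerance = 1e-12)
  expect_equal(sign(t1$sen_slope), sign(t3$sen_slope))
})

test_that("plain MK on the overlapping-window series draws a warning", {
  set.seed(7)
  bs <- betaSeries(rnorm(30), rnorm(30), 1:30)
  expect_warning(betaTrend(bs, correction = "none"), "autocorrelated")
})

test_that("a declining prescribed sensitivity is recovered against the
           effective truth on low-noise synthetic pixels", {
  g <- smallGrid(4L)  # 16 pixels
  sim <- simulateSavanna(g, seed = 909, years = 1982:2015,
                         vparams = list(laiNoiseSd = 0.02))
  clim <- computeClimatology(sim$rain)
  veg <- computeVegetation(sim$lai, sim$vod)
  bs <- betaSeries(panelVar(veg, "lai_max"),
                   panelVar(clim, "annual_rainfall"), panelYears(clim))
  bt <- betaTrend(bs)
  truthEff <- sim$truth$vegetation$betaTrueEffective
  truthSlope <- apply(truthEff, 1L, function(b) theilSen(1982:2015, b))
  ## every low-noise pixel shows the prescribed decline, with slope close
  ## to the effective (normalization-scale) truth
  expect_true(all(bt$sen_slope < 0))
  expect_lt(median(abs(bt$sen_slope - truthSlope) / abs(truthSlope)), 0.35)
})

test_that("reduced-sensitivity fractions count exactly", {
  tr <- data.frame(sen_slope = c(-1, -0.5, 2, 1, -0.1, 0.4),
                   significant_95 = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  fr <- fractionReduced(tr)
  expect_equal(fr$fracReduced, 0.5)
  expect_equal(fr$fracReducedSignificant, 2 / 6)
  fr2 <- fractionReduced(tr, mask = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                         woodyTrend = c(1, -1, 1, 1, 1, 1))
  expect_equal(fr2$fracReduced, 2 / 3)
  expect_equal(fr2$fracJointWoodyIncrease, 1 / 3)
  expect_equal(fr2$fracOfReducedWithWoodyIncrease, 1 / 2)
  expect_error(fractionReduced(tr, mask = rep(FALSE, 6)), "empty mask")
  tr$sen_slope <- -abs(tr$sen_slope)
  expect_equal(fractionReduced(tr)$fracReduced, 1)
})

test_that("a prescribed 60/40 split of declining and increasing
           sensitivity is recovered as an area fraction", {
  g <- savGrid(latRange = c(-14, -9), lonRange = c(20, 25), cellSize = 0.5)
  np <- nPixels(g)  # 100
  declining <- rep(c(TRUE, FALSE), c(60, 40))
  btr <- ifelse(declining, -0.02, 0.02)
  sim <- simulateSavanna(g, seed = 606, years = 1982:2015,
                         vparams = list(beta0 = ifelse(declining, 0.85, 0.15),
                                        betaTrend = btr,
                                        laiNoiseSd = 0.03))
  clim <- computeClimatology(sim$rain)
  veg <- computeVegetation(sim$lai, sim$vod)
  bs <- betaSeries(panelVar(veg, "lai_max"),
                   panelVar(clim, "annual_rainfall"), panelYears(clim))
  fr <- fractionReduced(betaTrend(bs))
  expect_lt(abs(fr$fracReduced - 0.60), 0.05)
})
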