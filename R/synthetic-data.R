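## Stochastic generator for gridded daily rainfall, bi-monthly LAI, monthly
## VOD and environmental covariates with a known ground truth, so that every
## downstream stage (climatology indices, vegetation summaries, sensitivity,
## trends, attribution, agreement) can be validated against prescribed
## trends and sensitivities.

## counter-based stream seed: deterministic per (seed, stream, pixel, year),
## independent of grid size and generation order; all arithmetic stays well
## below 2^53 so the modulus is exact
.streamSeed <- function(seed, stream, pixel, year) {
  v <- (as.double(seed) * 2654435.0 + stream * 97003.0 +
          as.double(pixel) * 15485863.0 + as.double(year) * 104729.0)
  as.integer(v %% 2147483647)
}

.recycle <- function(x, np) {
  if (length(x) == 1L) rep(x, np)
  else if (length(x) == np) x
  else stop("parameter fields must be scalar or one value per pixel")
}

#' Weather generator parameters
#'
#' Two-state Markov occurrence chain (wet-follows-dry probability `p01`,
#' wet-follows-wet `p11`) with gamma-distributed wet-day amounts. Both
#' occurrence probabilities are seasonally modulated by
#' `1 + seasonAmp * cos(2*pi*(doy - seasonPeakDoy)/365.25)` and shifted by
#' `trendWetdays` per year (clipped to [0, 1]); the gamma scale drifts by
#' `trendScale` mm per year, which drives the heavy-event frequency.
#' All fields accept a scalar or one value per pixel.
#'
#' @param p01,p11 base daily occurrence probabilities.
#' @param gammaShape,gammaScale gamma parameters of wet-day amounts (mm).
#' @param trendWetdays additive change in occurrence probability per year.
#' @param trendScale change in gamma scale per year (mm/yr).
#' @param seasonPeakDoy day of year of the rainfall peak.
#' @param seasonAmp seasonal modulation amplitude in [0, 1).
#' @param years inclusive range of simulated years.
#' @return a list of class `WeatherGenParams`.
#' @export
weatherGenParams <- function(p01 = 0.2, p11 = 0.5, gammaShape = 0.9,
                             gammaScale = 9, trendWetdays = 0,
                             trendScale = 0, seasonPeakDoy = 200,
                             seasonAmp = 0.9, years = 1982:2015) {
  stopifnot(all(gammaShape > 0), all(gammaScale > 0),
            all(seasonAmp >= 0 & seasonAmp < 1))
  structure(list(p01 = p01, p11 = p11, gammaShape = gammaShape,
                 gammaScale = gammaScale, trendWetdays = trendWetdays,
                 trendScale = trendScale, seasonPeakDoy = seasonPeakDoy,
                 seasonAmp = seasonAmp, years = years),
            class = "WeatherGenParams")
}

#' Vegetation generator parameters
#'
#' The annual LAI maximum responds to z-scored annual rainfall with a
#' prescribed, linearly drifting sensitivity:
#' `LAI_max = laiMean + laiSd * beta(year) * z(rain) + noise`, where
#' `beta(year) = beta0 + betaTrend * (year - year0)`. Monthly VOD tracks a
#' prescribed woody-cover trajectory `woody(year)/64.46` plus a seasonal
#' herbaceous bump built to vanish at the annual minimum month, plus noise,
#' so the annual VOD minimum recovers the woody signal. The per-pixel woody
#' trend is `woodyTrend + woodyRainCoupling * trendScale(pixel)`, coupling
#' woody change to the driver of heavy-rainfall-frequency change.
#'
#' @param beta0 initial LAI-rainfall sensitivity (z-units per z-unit).
#' @param betaTrend change in sensitivity per year.
#' @param laiMean,laiSd location/scale of annual LAI max (m2/m2).
#' @param laiNoiseSd LAI noise sd (m2/m2).
#' @param woody0 initial woody cover (percent).
#' @param woodyTrend baseline woody-cover trend (percent per year).
#' @param woodyRainCoupling weight linking the woody trend to the pixel's
#'   gamma-scale trend (percent/yr per mm/yr).
#' @param vodNoiseSd VOD noise sd (dimensionless).
#' @param herbAmp amplitude of the herbaceous VOD bump.
#' @param vodCoefficient woody-to-VOD conversion (percent per VOD unit).
#' @param vodYears years with VOD coverage (default the 1992-2012 subset of
#'   the simulated years, mirroring the shorter microwave record).
#' @return a list of class `VegetationGenParams`.
#' @export
vegetationGenParams <- function(beta0 = 0.8, betaTrend = -0.6 / 33,
                                laiMean = 2, laiSd = 0.5, laiNoiseSd = 0.1,
                                woody0 = 15, woodyTrend = 0.2,
                                woodyRainCoupling = 5, vodNoiseSd = 0.01,
                                herbAmp = 0.08, vodCoefficient = 64.46,
                                vodYears = NULL) {
  stopifnot(all(laiNoiseSd >= 0), all(vodNoiseSd >= 0), laiSd > 0)
  structure(list(beta0 = beta0, betaTrend = betaTrend, laiMean = laiMean,
                 laiSd = laiSd, laiNoiseSd = laiNoiseSd, woody0 = woody0,
                 woodyTrend = woodyTrend,
                 woodyRainCoupling = woodyRainCoupling,
                 vodNoiseSd = vodNoiseSd, herbAmp = herbAmp,
                 vodCoefficient = vodCoefficient, vodYears = vodYears),
            class = "VegetationGenParams")
}

.daysInYear <- function(y) {
  if ((y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0) 366L else 365L
}

## one year of daily rainfall for one pixel (caller sets the RNG stream)
.simYear <- function(ndays, p01, p11, shape, scale) {
  u <- runif(ndays)
  wet <- logical(ndays)
  prev <- FALSE
  for (i in seq_len(ndays)) {
    p <- if (prev) p11[i] else p01[i]
    prev <- wet[i] <- u[i] < p
  }
  r <- numeric(ndays)
  nw <- sum(wet)
  if (nw) r[wet] <- rgamma(nw, shape = shape, scale = scale)
  r
}

#' Generate a daily rainfall cube with known trend truth
#'
#' @param grid a [SavGrid-class].
#' @param params a [weatherGenParams()] object (fields scalar or per pixel).
#' @param seed integer master seed; each (pixel, year) gets its own
#'   deterministic stream.
#' @return list with `rain` (daily [GridCube-class], mm/day) and `truth`
#'   (per-pixel data.frame of prescribed parameters and the implied
#'   analytic rainy-day and annual-rainfall trends).
#' @export
genRainfall <- function(grid, params, seed) {
  stopifnot(inherits(params, "WeatherGenParams"), !missing(seed))
  np <- nPixels(grid)
  p01 <- .recycle(params$p01, np); p11 <- .recycle(params$p11, np)
  shp <- .recycle(params$gammaShape, np)
  scl <- .recycle(params$gammaScale, np)
  tw <- .recycle(params$trendWetdays, np)
  ts <- .recycle(params$trendScale, np)
  peak <- .recycle(params$seasonPeakDoy, np)
  amp <- .recycle(params$seasonAmp, np)
  years <- params$years
  ndays <- vapply(years, .daysInYear, integer(1))
  time <- seq(as.Date(sprintf("%d-01-01", years[1])),
              as.Date(sprintf("%d-12-31", years[length(years)])), by = "day")
  stopifnot(length(time) == sum(ndays))
  vals <- matrix(NA_real_, np, length(time))
  off <- c(0L, cumsum(ndays))
  for (p in seq_len(np)) {
    for (k in seq_along(years)) {
      nd <- ndays[k]
      doy <- seq_len(nd)
      f <- 1 + amp[p] * cos(2 * pi * (doy - peak[p]) / 365.25)
      dy <- years[k] - years[1]
      p01d <- pmin(pmax(p01[p] * f + tw[p] * dy, 0), 1)
      p11d <- pmin(pmax(p11[p] * f + tw[p] * dy, 0), 1)
      sclY <- max(scl[p] + ts[p] * dy, 0.01)
      set.seed(.streamSeed(seed, 1L, p, years[k]))
      vals[p, (off[k] + 1L):off[k + 1L]] <-
        .simYear(nd, p01d, p11d, shp[p], sclY)
    }
  }
  ## analytic expectations for the base year: stationary wet fraction of the
  ## (unmodulated) chain is p01/(1 + p01 - p11); an additive shift d moves it
  ## by d/(1 + p01 - p11), giving the implied rainy-day trend
  piWet <- p01 / (1 + p01 - p11)
  rdTrend <- 365.25 * tw / (1 + p01 - p11)
  annTrend <- shp * (scl * rdTrend + 365.25 * piWet * ts)
  truth <- data.frame(pixel = seq_len(np), p01 = p01, p11 = p11,
                      gammaShape = shp, gammaScale = scl,
                      trendWetdays = tw, trendScale = ts,
                      piWet = piWet,
                      true_rainyday_trend = rdTrend,
                      true_annual_rainfall_trend = annTrend)
  list(rain = gridCube(grid, time, vals, "rainfall", "mm/day"),
       truth = truth)
}

## seasonal canopy template on arbitrary days of year, in [base, 1]
.seasonTemplate <- function(doy, peak, base = 0.15) {
  base + (1 - base) * ((1 + cos(2 * pi * (doy - peak) / 365.25)) / 2)^2
}

#' Generate LAI and VOD cubes consistent with a rainfall cube
#'
#' @param rain daily rainfall [GridCube-class] from [genRainfall()].
#' @param params a [vegetationGenParams()] object.
#' @param seed integer master seed (vegetation uses its own streams).
#' @param rainTruth the truth table from [genRainfall()]; required when
#'   `woodyRainCoupling != 0` so the woody trend can be tied to the pixel's
#'   rainfall-trend parameters.
#' @param seasonPeakDoy day of year of the canopy peak (default 200).
#' @return list with `lai` (bi-monthly cube, m2/m2), `vod` (monthly cube),
#'   and `truth`: `betaTrue` and `betaTrueEffective` (pixels x years;
#'   effective = in the units the standardized moving-window regression
#'   estimates, i.e. divided by the realised period sd of normalized LAI),
#'   `woodyTrue` (pixels x VOD years), `woodyTrendTrue`, `laiClipped` count.
#' @export
genVegetation <- function(rain, params, seed, rainTruth = NULL,
                          seasonPeakDoy = 200) {
  stopifnot(inherits(params, "VegetationGenParams"))
  grid <- rain@grid
  np <- nrow(rain@values)
  yi <- as.integer(format(rain@time, "%Y"))
  years <- sort(unique(yi))
  ny <- length(years)
  ## annual rainfall and its per-pixel z-score (the generator-side driver)
  annRain <- t(vapply(seq_len(np), function(p)
    vapply(split(rain@values[p, ], yi), sum, numeric(1)), numeric(ny)))
  zr <- t(apply(annRain, 1L, function(x) (x - mean(x)) / sd(x)))
  zr[!is.finite(zr)] <- 0

  beta0 <- .recycle(params$beta0, np)
  btr <- .recycle(params$betaTrend, np)
  betaTrue <- outer(beta0, rep(1, ny)) + outer(btr, years - years[1])

  wtr <- .recycle(params$woodyTrend, np)
  coup <- .recycle(params$woodyRainCoupling, np)
  if (any(coup != 0)) {
    if (is.null(rainTruth))
      stop("rainTruth is required when woodyRainCoupling != 0")
    wtr <- wtr + coup * rainTruth$trendScale
  }
  w0 <- .recycle(params$woody0, np)

  vodYears <- params$vodYears
  if (is.null(vodYears)) {
    vodYears <- intersect(years, 1992:2012)
    if (!length(vodYears)) vodYears <- years
  }
  nyv <- length(vodYears)
  woodyTrue <- pmin(pmax(outer(w0, rep(1, nyv)) +
                           outer(wtr, vodYears - vodYears[1]), 0), 100)

  ## composite calendars
  laiDoy <- (seq_len(24) - 0.5) * 365.25 / 24
  vodDoy <- (seq_len(12) - 0.5) * 365.25 / 12
  tmplL <- .seasonTemplate(laiDoy, seasonPeakDoy)
  tmplL <- tmplL / max(tmplL)        # peak composite carries LAI_max exactly
  tmplV <- .seasonTemplate(vodDoy, seasonPeakDoy)
  bump <- params$herbAmp * (tmplV - min(tmplV)) / (max(tmplV) - min(tmplV))

  laiVals <- matrix(NA_real_, np, 24L * ny)
  vodVals <- matrix(NA_real_, np, 12L * nyv)
  laiMaxTrue <- matrix(NA_real_, np, ny)
  clipped <- 0L
  for (p in seq_len(np)) {
    set.seed(.streamSeed(seed, 2L, p, 0L))
    lm0 <- params$laiMean + params$laiSd * betaTrue[p, ] * zr[p, ] +
      rnorm(ny, 0, params$laiNoiseSd)
    nneg <- sum(lm0 < 0)
    if (nneg) { clipped <- clipped + nneg; lm0[lm0 < 0] <- 0 }
    laiMaxTrue[p, ] <- lm0
    laiVals[p, ] <- as.vector(outer(tmplL, lm0))
    vodVals[p, ] <- as.vector(outer(bump, rep(1, nyv)) +
                                outer(rep(1, 12L), woodyTrue[p, ] /
                                        params$vodCoefficient)) +
      rnorm(12L * nyv, 0, params$vodNoiseSd)
  }
  if (clipped) message(clipped, " negative LAI values clipped to 0")
  ## the moving-window estimator regresses z-scored LAI on z-scored rain;
  ## dividing the prescribed beta by the realised period sd of the
  ## (unit-free) LAI signal gives the estimand in the estimator's units
  sdL <- apply(laiMaxTrue, 1L, sd) / params$laiSd
  betaEff <- betaTrue / sdL

  laiTime <- as.Date(as.vector(outer(round(laiDoy) - 1L,
                                     as.Date(sprintf("%d-01-01", years)),
                                     "+")), origin = "1970-01-01")
  vodTime <- as.Date(as.vector(outer(round(vodDoy) - 1L,
                                     as.Date(sprintf("%d-01-01", vodYears)),
                                     "+")), origin = "1970-01-01")
  list(lai = gridCube(grid, laiTime, laiVals, "lai", "m2/m2"),
       vod = gridCube(grid, vodTime, vodVals, "vod", ""),
       truth = list(years = years, vodYears = vodYears,
                    betaTrue = betaTrue, betaTrueEffective = betaEff,
                    woodyTrue = woodyTrue, woodyTrendTrue = wtr,
                    laiMaxTrue = laiMaxTrue, laiClipped = clipped))
}

#' Generate environmental covariate fields
#'
#' Draws the non-rainfall explanatory fields used by the attribution stage:
#' dynamic changes (air temperature, cloud cover, population density,
#' burned fraction) and static site variables (soil organic carbon,
#' elevation, sand fraction). Each dynamic field can be given a prescribed
#' cross-correlation with the true woody trend.
#'
#' @param grid a [SavGrid-class].
#' @param seed integer master seed.
#' @param crossCor correlation in [-1, 1] between each dynamic covariate and
#'   `woodyTrendTrue` (default 0 = independent drivers).
#' @param woodyTrendTrue per-pixel true woody trend; required when
#'   `crossCor != 0`.
#' @return data.frame with columns `d_temperature`, `d_cloud`,
#'   `d_population`, `d_burned`, `soc`, `elevation`, `sand`.
#' @export
genCovariates <- function(grid, seed, crossCor = 0, woodyTrendTrue = NULL) {
  np <- nPixels(grid)
  set.seed(.streamSeed(seed, 3L, 0L, 0L))
  mix <- function(mu, sdv) {
    e <- rnorm(np)
    if (crossCor != 0) {
      if (is.null(woodyTrendTrue))
        stop("woodyTrendTrue required when crossCor != 0")
      zw <- (woodyTrendTrue - mean(woodyTrendTrue)) / sd(woodyTrendTrue)
      e <- crossCor * zw + sqrt(1 - crossCor^2) * e
    }
    mu + sdv * e
  }
  data.frame(
    pixel = seq_len(np),
    d_temperature = mix(0.02, 0.01),    # degC per year
    d_cloud = mix(0, 0.1),              # percent cloud cover per year
    d_population = mix(5, 10),          # persons/km2, 2015 - 2000
    d_burned = mix(-0.001, 0.002),      # burned fraction per year
    soc = exp(rnorm(np, log(30), 0.5)), # t/ha
    elevation = runif(np, 100, 1500),   # m
    sand = runif(np, 20, 90))           # percent
}

#' Simulate a complete synthetic savanna dataset
#'
#' Draws per-pixel study conditions (stationary wet-day fraction U(0.06,
#' 0.42) with chain persistence 0.3, gamma scale U(3, 13) mm giving a mean
#' annual rainfall gradient of roughly 100-1900 mm/yr spanning the arid,
#' semi-arid and humid classes; gamma-scale trend
#' N(0.04, 0.03) mm/yr and wet-day-probability trend N(0.001, 0.0015)/yr),
#' then generates rainfall, vegetation and covariates with a shared master
#' seed. Arguments in `wparams`/`vparams` override the corresponding
#' generator defaults (per-pixel vectors allowed).
#'
#' @param grid a [SavGrid-class].
#' @param seed integer master seed.
#' @param years simulated years (default 1982:2015).
#' @param wparams,vparams named lists of overrides for
#'   [weatherGenParams()] / [vegetationGenParams()].
#' @param crossCor covariate cross-correlation, see [genCovariates()].
#' @return list with `rain`, `lai`, `vod` cubes, `covariates` data.frame
#'   and `truth` (list with `rain` table and `vegetation` truth record).
#' @export
simulateSavanna <- function(grid, seed, years = 1982:2015,
                            wparams = list(), vparams = list(),
                            crossCor = 0) {
  np <- nPixels(grid)
  set.seed(.streamSeed(seed, 4L, 0L, 0L))
  piWet <- runif(np, 0.06, 0.42)
  r <- 0.3
  p01 <- piWet * (1 - r)
  p11 <- p01 + r
  wdef <- list(p01 = p01, p11 = p11, gammaShape = 0.9,
               gammaScale = runif(np, 3, 13),
               trendWetdays = rnorm(np, 0.001, 0.0015),
               trendScale = rnorm(np, 0.04, 0.03),
               seasonPeakDoy = 200, seasonAmp = 0.9, years = years)
  wdef[names(wparams)] <- wparams
  wp <- do.call(weatherGenParams, wdef)
  rf <- genRainfall(grid, wp, seed)
  vdef <- list()
  vdef[names(vparams)] <- vparams
  vp <- do.call(vegetationGenParams, vdef)
  veg <- genVegetation(rf$rain, vp, seed, rainTruth = rf$truth)
  cov <- genCovariates(grid, seed, crossCor = crossCor,
                       woodyTrendTrue = veg$truth$woodyTrendTrue)
  list(rain = rf$rain, lai = veg$lai, vod = veg$vod, covariates = cov,
       truth = list(rain = rf$truth, vegetation = veg$truth))
}
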