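## Annual rainfall-climatology indices from daily rainfall.
## Wet-day membership is inclusive (>= 1 mm by default); heavy-rain
## exceedance of the baseline 90th-percentile wet-day amount is strict (>).

#' Annual rainfall total
#'
#' Sums daily rainfall over the aggregation year. Gaps up to `tolerance`
#' (fraction of days missing) are allowed; the sum is then rescaled by
#' `days / present-days`. Larger gaps give a missing total.
#'
#' @param x daily rainfall (mm/day) for one year.
#' @param tolerance maximum tolerated missing fraction (default 0.05).
#' @return annual total in mm, or `NA`.
#' @examples
#' annualRainfall(c(5, 0, 12, 1, 0, 0, 3, 0, 0, 20))  # 41
#' @export
annualRainfall <- function(x, tolerance = 0.05) {
  n <- length(x)
  present <- sum(!is.na(x))
  if (n == 0L || (n - present) / n > tolerance) return(NA_real_)
  sum(x, na.rm = TRUE) * n / present
}

#' Annual count of rainy days
#'
#' Days with rainfall at or above the wet-day threshold (1 mm by default,
#' inclusive).
#'
#' @inheritParams annualRainfall
#' @param wetThreshold wet-day threshold in mm/day (inclusive).
#' @return integer count, or `NA` when too much of the year is missing.
#' @export
rainyDays <- function(x, wetThreshold = 1, tolerance = 0.05) {
  n <- length(x)
  present <- sum(!is.na(x))
  if (n == 0L || (n - present) / n > tolerance) return(NA_integer_)
  sum(x >= wetThreshold, na.rm = TRUE)
}

#' Baseline heavy-rain threshold (90th percentile of wet-day amounts)
#'
#' Pools all wet days (>= `wetThreshold`) of the full baseline record and
#' takes the `percentile` quantile by linear interpolation between order
#' statistics (type 7). Pixels with fewer than `minWetDays` wet days get a
#' missing threshold.
#'
#' @param x daily rainfall over the whole baseline period (mm/day).
#' @param wetThreshold wet-day threshold (mm/day).
#' @param percentile quantile level (default 0.9).
#' @param minWetDays minimum wet-day pool size (default 20).
#' @return threshold in mm/day, or `NA`.
#' @examples
#' heavyRainThreshold(1:100)  # 90.1
#' @export
heavyRainThreshold <- function(x, wetThreshold = 1, percentile = 0.9,
                               minWetDays = 20L) {
  wet <- x[!is.na(x) & x >= wetThreshold]
  if (length(wet) < minWetDays) return(NA_real_)
  unname(quantile(wet, percentile, type = 7))
}

#' Annual heavy-rainfall frequency
#'
#' Count of wet days (>= `wetThreshold`) strictly above the baseline
#' threshold.
#'
#' @inheritParams rainyDays
#' @param threshold baseline heavy-rain threshold (mm/day) from
#'   [heavyRainThreshold()].
#' @return integer count, or `NA` when the threshold or too many days are
#'   missing.
#' @export
heavyRainFreq <- function(x, threshold, wetThreshold = 1, tolerance = 0.05) {
  if (is.na(threshold)) return(NA_integer_)
  n <- length(x)
  present <- sum(!is.na(x))
  if (n == 0L || (n - present) / n > tolerance) return(NA_integer_)
  sum(x >= wetThreshold & x > threshold, na.rm = TRUE)
}

#' Rainfall intensity and inter-annual coefficient of variation
#'
#' `rainfallIntensity` is annual rainfall divided by the number of rainy
#' days (missing when there are none). `cvInterannual` is the sample
#' sd/mean of the annual-rainfall series (needs >= 3 years and a positive
#' mean).
#'
#' @param annual annual rainfall (mm), scalar or vector.
#' @param rainy rainy-day counts matching `annual`.
#' @return intensity in mm/day (same shape as input), or the CV.
#' @export
rainfallIntensity <- function(annual, rainy) {
  out <- ifelse(!is.na(rainy) & rainy > 0, annual / rainy, NA_real_)
  out
}

#' @rdname rainfallIntensity
#' @param annualSeries numeric vector of annual totals across years.
#' @export
cvInterannual <- function(annualSeries) {
  x <- annualSeries[!is.na(annualSeries)]
  if (length(x) < 3L) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  sd(x) / m
}

## split a daily cube's time axis into calendar or July-June years
.yearIndex <- function(time, convention = c("calendar", "july_june")) {
  convention <- match.arg(convention)
  yr <- as.integer(format(time, "%Y"))
  if (convention == "july_june") {
    mo <- as.integer(format(time, "%m"))
    yr <- ifelse(mo >= 7L, yr + 1L, yr)
  }
  yr
}

#' Annual climatology panel from a daily rainfall cube
#'
#' Computes per pixel and year: annual rainfall, rainy days, heavy-rain
#' frequency (relative to the pixel's full-baseline 90th-percentile wet-day
#' amount) and intensity; and per pixel: mean annual rainfall, inter-annual
#' CV and the heavy-rain threshold (as rowData).
#'
#' @param rain daily rainfall [GridCube-class] (mm/day).
#' @param wetThreshold wet-day threshold (mm/day), default 1.
#' @param percentile heavy-rain percentile, default 0.9.
#' @param tolerance per-year missing tolerance.
#' @param yearConvention `"calendar"` (default) or `"july_june"`.
#' @return an [AnnualPanel-class] with assays `annual_rainfall`,
#'   `rainy_days`, `heavy_rain_freq`, `intensity` and rowData columns
#'   `mean_annual_rainfall`, `cv_interannual`, `p90_threshold`.
#' @export
computeClimatology <- function(rain, wetThreshold = 1, percentile = 0.9,
                               tolerance = 0.05,
                               yearConvention = c("calendar", "july_june")) {
  yearConvention <- match.arg(yearConvention)
  yi <- .yearIndex(rain@time, yearConvention)
  years <- sort(unique(yi))
  np <- nrow(rain@values)
  cols <- split(seq_along(yi), yi)
  ann <- rdy <- hvy <- matrix(NA_real_, np, length(years))
  thr <- numeric(np)
  for (p in seq_len(np)) {
    xp <- rain@values[p, ]
    thr[p] <- heavyRainThreshold(xp, wetThreshold, percentile)
    for (k in seq_along(years)) {
      xk <- xp[cols[[as.character(years[k])]]]
      ann[p, k] <- annualRainfall(xk, tolerance)
      rdy[p, k] <- rainyDays(xk, wetThreshold, tolerance)
      hvy[p, k] <- heavyRainFreq(xk, thr[p], wetThreshold, tolerance)
    }
  }
  inten <- rainfallIntensity(ann, rdy)
  mar <- rowMeans(ann, na.rm = TRUE)
  cv <- apply(ann, 1L, cvInterannual)
  AnnualPanel(rain@grid, years,
              assays = list(annual_rainfall = ann, rainy_days = rdy,
                            heavy_rain_freq = hvy, intensity = inten),
              rowData = list(mean_annual_rainfall = mar,
                             cv_interannual = cv, p90_threshold = thr))
}
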