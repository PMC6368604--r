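## Annual vegetation summaries: LAI max, VOD min, and the woody-cover
## transform woody (%) = 64.46 x annual-minimum VOD. The coefficient is a
## configurable default, with calibrateOrigin() available to re-derive it
## from reference woody-cover data by a regression forced through the
## origin (which avoids negative woody-cover estimates).

#' Annual maximum LAI
#'
#' Maximum over the year's composites (bi-monthly cadence: 24 per year).
#' Requires at least `minPresent` non-missing composites.
#'
#' @param x LAI composites for one year (m2/m2).
#' @param minPresent minimum number of composites (default 18).
#' @return the maximum, or `NA`.
#' @export
annualLaiMax <- function(x, minPresent = 18L) {
  if (sum(!is.na(x)) < minPresent) return(NA_real_)
  max(x, na.rm = TRUE)
}

#' Annual minimum VOD
#'
#' Minimum monthly VOD within the year; the seasonal minimum suppresses the
#' herbaceous contribution so the result tracks woody vegetation. Requires
#' at least `minPresent` of 12 months.
#'
#' @param x monthly VOD values for one year (dimensionless).
#' @param minPresent minimum number of months (default 10).
#' @return the minimum, or `NA`.
#' @export
annualVodMin <- function(x, minPresent = 10L) {
  if (sum(!is.na(x)) < minPresent) return(NA_real_)
  min(x, na.rm = TRUE)
}

#' Woody cover from annual minimum VOD
#'
#' Linear transform `woody (\%) = coefficient * vod_min` with the default
#' coefficient 64.46. Values above 100 are reported as-is but flagged (the
#' transform stays exactly linear), via attribute `flagged_gt100`.
#'
#' @param vodMin annual minimum VOD (>= 0; `NA` allowed).
#' @param coefficient percent woody cover per VOD unit (default 64.46).
#' @return woody cover in percent.
#' @examples
#' woodyCoverFromVod(0.5)  # 32.23
#' @export
woodyCoverFromVod <- function(vodMin, coefficient = 64.46) {
  if (any(vodMin < 0, na.rm = TRUE))
    stop("vod_min must be non-negative")
  out <- coefficient * vodMin
  attr(out, "flagged_gt100") <- which(!is.na(out) & out > 100)
  out
}

#' Calibrate the VOD-to-woody-cover coefficient through the origin
#'
#' No-intercept least squares of reference woody cover on annual minimum
#' VOD: `slope = sum(x*y) / sum(x^2)`. The reported r-squared is the
#' uncentered no-intercept definition `1 - sum((y - yhat)^2) / sum(y^2)`,
#' which differs from the centered R2 of an ordinary regression.
#'
#' @param vodMin per-pixel annual minimum VOD.
#' @param woodyRef per-pixel reference woody cover (percent).
#' @return list with `slope`, `rSquared`, `n`.
#' @examples
#' calibrateOrigin(c(1, 2), c(2, 6))$slope  # 2.8
#' @export
calibrateOrigin <- function(vodMin, woodyRef) {
  ok <- !is.na(vodMin) & !is.na(woodyRef)
  x <- vodMin[ok]; y <- woodyRef[ok]
  if (length(x) < 3L) stop("calibrateOrigin needs >= 3 paired pixels")
  if (all(x == 0)) stop("calibrateOrigin: predictor is all zero")
  slope <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  list(slope = slope, rSquared = r2, n = length(x))
}

#' Annual vegetation panel from LAI and VOD cubes
#'
#' Aggregates a bi-monthly LAI cube and a monthly VOD cube (which may cover
#' different year ranges) to annual `lai_max`, `vod_min` and `woody_cover`
#' over the union of years.
#'
#' @param lai bi-monthly LAI [GridCube-class].
#' @param vod monthly VOD [GridCube-class] (same grid).
#' @param coefficient VOD-to-woody coefficient (default 64.46).
#' @param laiMinPresent,vodMinPresent per-year completeness minima.
#' @param yearConvention `"calendar"` or `"july_june"`.
#' @return an [AnnualPanel-class] with assays `lai_max`, `vod_min`,
#'   `woody_cover`.
#' @export
computeVegetation <- function(lai, vod, coefficient = 64.46,
                              laiMinPresent = 18L, vodMinPresent = 10L,
                              yearConvention = c("calendar", "july_june")) {
  yearConvention <- match.arg(yearConvention)
  if (!isTRUE(all.equal(lai@grid@lat, vod@grid@lat)) ||
      !isTRUE(all.equal(lai@grid@lon, vod@grid@lon)))
    stop("LAI and VOD cubes must share a grid")
  yiL <- .yearIndex(lai@time, yearConvention)
  yiV <- .yearIndex(vod@time, yearConvention)
  years <- sort(union(unique(yiL), unique(yiV)))
  np <- nrow(lai@values)
  laiM <- vodM <- matrix(NA_real_, np, length(years))
  colL <- split(seq_along(yiL), yiL)
  colV <- split(seq_along(yiV), yiV)
  for (k in seq_along(years)) {
    ck <- as.character(years[k])
    if (!is.null(colL[[ck]]))
      laiM[, k] <- apply(lai@values[, colL[[ck]], drop = FALSE], 1L,
                         annualLaiMax, minPresent = laiMinPresent)
    if (!is.null(colV[[ck]]))
      vodM[, k] <- apply(vod@values[, colV[[ck]], drop = FALSE], 1L,
                         annualVodMin, minPresent = vodMinPresent)
  }
  woody <- matrix(woodyCoverFromVod(as.vector(vodM), coefficient), np)
  AnnualPanel(lai@grid, years,
              assays = list(lai_max = laiM, vod_min = vodM,
                            woody_cover = woody))
}
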