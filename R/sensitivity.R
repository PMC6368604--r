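## Moving-window sensitivity of vegetation production to annual rainfall:
## beta is the OLS slope of z-scored annual LAI max on z-scored annual
## rainfall inside a sliding window (15 years by default), indexed by the
## window center year. Its long-term Theil-Sen trend, with autocorrelation-
## corrected Mann-Kendall significance, is the headline statistic.

#' Moving-window LAI-rainfall sensitivity series
#'
#' For every full window the two variables are z-scored (over the whole
#' study period per pixel by default, per window optionally) and the OLS
#' slope of LAI on rainfall is recorded at the window's center year
#' (window 1982-1996 is centered on 1989). Under per-window normalization
#' the slope equals the window Pearson correlation and lies in [-1, 1].
#'
#' @param laiMax pixels x years matrix of annual LAI max (or a vector for
#'   one pixel).
#' @param rainfall matching matrix/vector of annual rainfall.
#' @param years integer years (columns).
#' @param window window length in years (default 15).
#' @param normScope `"period"` (default) or `"window"`.
#' @param maxMissing maximum missing year pairs tolerated per window
#'   (default 2).
#' @return list with `beta` (pixels x windows matrix), `centers` (window
#'   center years), `window`, `normScope`.
#' @export
betaSeries <- function(laiMax, rainfall, years, window = 15L,
                       normScope = c("period", "window"), maxMissing = 2L) {
  normScope <- match.arg(normScope)
  if (is.null(dim(laiMax))) laiMax <- matrix(laiMax, nrow = 1L)
  if (is.null(dim(rainfall))) rainfall <- matrix(rainfall, nrow = 1L)
  stopifnot(ncol(laiMax) == length(years),
            all(dim(laiMax) == dim(rainfall)))
  ny <- length(years)
  if (ny < window) stop("need at least `window` years")
  nw <- ny - window + 1L
  centers <- years[seq_len(nw)] + (window - 1L) %/% 2L
  np <- nrow(laiMax)
  beta <- matrix(NA_real_, np, nw)
  for (p in seq_len(np)) {
    zl <- laiMax[p, ]; zrn <- rainfall[p, ]
    if (normScope == "period") {
      zl <- zscore(zl); zrn <- zscore(zrn)
      if (all(is.na(zl)) || all(is.na(zrn))) next
    }
    for (w in seq_len(nw)) {
      idx <- w:(w + window - 1L)
      x <- zrn[idx]; y <- zl[idx]
      ok <- !is.na(x) & !is.na(y)
      if (window - sum(ok) > maxMissing) next
      if (normScope == "window") {
        x <- zscore(x[ok]); y <- zscore(y[ok])
        if (all(is.na(x)) || all(is.na(y))) next
        fit <- olsSlope(x, y)
      } else {
        fit <- olsSlope(x[ok], y[ok])
      }
      beta[p, w] <- fit$slope
    }
  }
  list(beta = beta, centers = centers, window = window,
       normScope = normScope)
}

#' Long-term trend of the sensitivity series
#'
#' Theil-Sen slope plus Mann-Kendall significance of each pixel's beta
#' series. Because overlapping windows make the series serially dependent
#' by construction, the autocorrelation-corrected test is the default and
#' `correction = "none"` draws a warning.
#'
#' @param series result of [betaSeries()].
#' @param correction MK variance correction (see [mannKendall()]).
#' @param alpha significance level.
#' @return data.frame as [trendMap()] (one row per pixel).
#' @export
betaTrend <- function(series, correction = c("hamed_rao", "tfpw", "none"),
                      alpha = 0.05) {
  correction <- match.arg(correction)
  if (correction == "none")
    warning("overlapping windows are autocorrelated by construction; ",
            "the uncorrected MK test overstates significance")
  if (ncol(series$beta) < 8L)
    stop("betaTrend needs at least 8 windows")
  res <- lapply(seq_len(nrow(series$beta)), function(p)
    trendTest(series$beta[p, ], series$centers, correction = correction,
              alpha = alpha))
  cbind(pixel = seq_len(nrow(series$beta)), do.call(rbind, res))
}

#' Area fractions of reduced sensitivity
#'
#' Fraction of included pixels whose fitted sensitivity trend is negative,
#' the same restricted to significant trends, and (optionally) the joint
#' fraction with a positive woody-cover trend.
#'
#' @param trend data.frame from [betaTrend()]/[trendMap()].
#' @param mask optional [PixelMask-class] or logical vector of included
#'   pixels.
#' @param woodyTrend optional per-pixel woody-cover trend (same order).
#' @return list with `fracReduced`, `fracReducedSignificant`, `nIncluded`,
#'   and when `woodyTrend` is given `fracJointWoodyIncrease` (share of
#'   included pixels with declining sensitivity and increasing woody cover)
#'   and `fracOfReducedWithWoodyIncrease`.
#' @export
fractionReduced <- function(trend, mask = NULL, woodyTrend = NULL) {
  inc <- rep(TRUE, nrow(trend))
  if (!is.null(mask))
    inc <- if (is(mask, "PixelMask")) maskInclude(mask) else as.logical(mask)
  if (!any(inc)) stop("empty mask: no included pixels")
  s <- trend$sen_slope[inc]
  ok <- !is.na(s)
  if (!any(ok)) stop("no non-missing trends among included pixels")
  out <- list(
    fracReduced = mean(s[ok] < 0),
    fracReducedSignificant =
      mean(s[ok] < 0 & trend$significant_95[inc][ok] %in% TRUE),
    nIncluded = sum(ok))
  if (!is.null(woodyTrend)) {
    w <- woodyTrend[inc]
    both <- ok & !is.na(w)
    out$fracJointWoodyIncrease <- mean(s[both] < 0 & w[both] > 0)
    red <- both & s < 0
    out$fracOfReducedWithWoodyIncrease <-
      if (any(red)) mean(w[red] > 0) else NA_real_
  }
  out
}
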