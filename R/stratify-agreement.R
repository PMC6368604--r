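## Stratified summaries: 50 mm/yr rainfall-gradient bins, quadrant
## agreement of paired trend-sign maps, and five-number distribution
## summaries per aridity region.

#' Bin per-pixel values along the mean-annual-rainfall gradient
#'
#' Half-open bins `[lo, lo + step)` of MAR; per bin the mean (and sd) of
#' each supplied variable, optionally z-score-normalized across pixels
#' first and optionally min-max rescaled to 0-100 across the bin-mean
#' curve.
#'
#' @param values named list (or single vector) of per-pixel variables.
#' @param mar per-pixel mean annual rainfall (mm/yr).
#' @param step bin width in mm/yr (default 50).
#' @param normalize z-score each variable across pixels first (default
#'   TRUE).
#' @param rescale01 min-max rescale each bin-mean curve to 0-100 (refused
#'   with a warning for zero-range curves).
#' @param minCount bins with fewer pixels are flagged (default 10).
#' @param mask optional [PixelMask-class] or logical vector.
#' @return data.frame: `bin_lo`, `bin_hi`, `count`, `flagged`, then
#'   `mean_<var>` and `sd_<var>` per variable.
#' @export
binByRainfall <- function(values, mar, step = 50, normalize = TRUE,
                          rescale01 = FALSE, minCount = 10L, mask = NULL) {
  stopifnot(step > 0)
  if (!is.list(values)) values <- list(value = values)
  if (!is.null(mask)) {
    inc <- if (is(mask, "PixelMask")) maskInclude(mask) else as.logical(mask)
    mar <- ifelse(inc, mar, NA_real_)
  }
  ok <- !is.na(mar)
  lo <- floor(mar[ok] / step) * step
  edges <- seq(min(lo), max(lo), by = step)
  idx <- match(lo, edges)
  out <- data.frame(bin_lo = edges, bin_hi = edges + step,
                    count = as.integer(tabulate(idx, length(edges))))
  out$flagged <- out$count < minCount
  for (v in names(values)) {
    x <- values[[v]][ok]
    if (normalize) x <- zscore(x)
    mu <- rep(NA_real_, length(edges))
    s <- rep(NA_real_, length(edges))
    ag <- tapply(x, idx, mean, na.rm = TRUE)
    sg <- tapply(x, idx, sd, na.rm = TRUE)
    mu[as.integer(names(ag))] <- ag
    s[as.integer(names(sg))] <- sg
    if (rescale01) {
      rng <- range(mu, na.rm = TRUE)
      if (diff(rng) == 0) {
        warning("zero range for '", v, "': 0-100 rescale refused")
      } else mu <- 100 * (mu - rng[1L]) / diff(rng)
    }
    out[[paste0("mean_", v)]] <- mu
    out[[paste0("sd_", v)]] <- s
  }
  out
}

#' Quadrant agreement of two trend maps
#'
#' Classifies every included pixel by the signs of two per-pixel trends:
#' `pp` (both positive), `pn` (A positive, B negative), `np`, `nn`.
#' Pixels where either trend is exactly zero carry no sign class; they are
#' excluded from the fractions and counted separately. Fractions are over
#' pixel counts (not area-weighted).
#'
#' @param trendA,trendB per-pixel slopes (same length).
#' @param mask optional [PixelMask-class] or logical vector.
#' @return list of class `QuadrantMap`: `class` (factor per pixel, `NA`
#'   outside the mask/coverage), `fractions` (named, sums to 1), `counts`,
#'   `nZero`, `nIncluded`.
#' @export
quadrantAgreement <- function(trendA, trendB, mask = NULL) {
  stopifnot(length(trendA) == length(trendB))
  inc <- rep(TRUE, length(trendA))
  if (!is.null(mask))
    inc <- if (is(mask, "PixelMask")) maskInclude(mask) else as.logical(mask)
  cov <- !is.na(trendA) & !is.na(trendB)
  if (any(inc & !cov))
    warning(sum(inc & !cov), " included pixels lack joint coverage; ",
            "fractions computed on the intersection")
  use <- inc & cov
  cls <- rep(NA_character_, length(trendA))
  cls[use & trendA > 0 & trendB > 0] <- "pp"
  cls[use & trendA > 0 & trendB < 0] <- "pn"
  cls[use & trendA < 0 & trendB > 0] <- "np"
  cls[use & trendA < 0 & trendB < 0] <- "nn"
  zero <- use & (trendA == 0 | trendB == 0)
  counts <- table(factor(cls, levels = c("pp", "pn", "np", "nn")))
  tot <- sum(counts)
  structure(list(class = factor(cls, levels = c("pp", "pn", "np", "nn")),
                 fractions = if (tot) counts / tot else counts * NA_real_,
                 counts = counts, nZero = sum(zero), nIncluded = sum(use)),
            class = "QuadrantMap")
}

#' Five-number distribution summary per region
#'
#' Minimum, first quartile, median, third quartile and maximum of a
#' per-pixel variable within each region (quartiles by linear
#' interpolation). Regions with fewer than `minPixels` pixels are flagged
#' and reported as missing.
#'
#' @param values per-pixel numeric vector (typically a normalized change).
#' @param regions factor from [classifyRegion()] (same length).
#' @param minPixels minimum region size (default 5).
#' @return data.frame: `region`, `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
regionSummary <- function(values, regions, minPixels = 5L) {
  stopifnot(length(values) == length(regions))
  levs <- levels(regions)
  out <- lapply(levs, function(rg) {
    x <- values[regions == rg & !is.na(values)]
    if (length(x) < minPixels)
      return(data.frame(region = rg, n = length(x), min = NA_real_,
                        q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                        max = NA_real_))
    q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    data.frame(region = rg, n = length(x), min = q[1L], q1 = q[2L],
               median = q[3L], q3 = q[4L], max = q[5L])
  })
  do.call(rbind, out)
}
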