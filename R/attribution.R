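## Attribution of woody-cover change: LMG relative-importance decomposition
## of a least-squares model of per-pixel woody trends on 12 standardized
## explanatory variables, grouped driver shares with bootstrap CIs, partial
## (residual-on-residual) regression slopes, and the univariate
## beta_woody-Rainfall sensitivity slopes.

.defaultGroups <- c(
  d_annual_rainfall = "rainfall_climatology",
  d_heavy_rain_freq = "rainfall_climatology",
  d_rainy_days = "rainfall_climatology",
  d_intensity = "rainfall_climatology",
  d_temperature = "T_and_S",
  d_cloud = "T_and_S",
  d_population = "management",
  d_burned = "management",
  mean_annual_rainfall = "static",
  cv_interannual = "static",
  soc = "static",
  elevation = "static",
  sand = "static")

#' Assemble the driver matrix for attribution
#'
#' Combines the response (per-pixel woody-cover trend) with the explanatory
#' columns, drops pixels with any missing value (listwise deletion, count
#' reported), z-scores every column and removes zero-variance predictors
#' with a warning.
#'
#' @param response numeric per-pixel response (woody-cover trend, %/yr).
#' @param drivers data.frame of explanatory columns (one row per pixel).
#' @param groups named character vector mapping driver names to group
#'   labels; defaults cover the standard 12-variable set (+ intensity).
#' @return list of class `DriverMatrix`: `X` (standardized matrix), `y`
#'   (standardized response), `groups`, `nDropped`.
#' @export
buildDriverMatrix <- function(response, drivers, groups = .defaultGroups) {
  stopifnot(length(response) == nrow(drivers))
  drivers <- drivers[, setdiff(names(drivers), "pixel"), drop = FALSE]
  keep <- !is.na(response) & !Reduce(`|`, lapply(drivers, is.na))
  nDropped <- sum(!keep)
  y <- response[keep]
  X <- as.matrix(drivers[keep, , drop = FALSE])
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    warning("zero-variance predictors excluded: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  X <- scale(X)
  if (sd(y) == 0) stop("response has zero variance")
  y <- as.numeric(scale(y))
  gr <- groups[colnames(X)]
  gr[is.na(gr)] <- "other"
  structure(list(X = X, y = y, groups = gr, nDropped = nDropped),
            class = "DriverMatrix")
}

#' Screen collinear predictor pairs
#'
#' Among pairs with `|r| > rMax` the member with the lower absolute
#' marginal correlation to the response is dropped (this is the rule under
#' which a rainfall-intensity change column is removed when it is nearly a
#' copy of the annual-rainfall change). Decisions are reported via message.
#'
#' @param dm a `DriverMatrix` from [buildDriverMatrix()].
#' @param rMax pairwise correlation threshold (default 0.8).
#' @return the screened `DriverMatrix`, with attribute `dropped`.
#' @export
collinearityScreen <- function(dm, rMax = 0.8) {
  X <- dm$X; y <- dm$y
  dropped <- character()
  repeat {
    C <- abs(cor(X))
    diag(C) <- 0
    if (all(C <= rMax, na.rm = TRUE)) break
    ij <- which(C == max(C), arr.ind = TRUE)[1L, ]
    ry <- abs(cor(X[, ij], y))
    loser <- colnames(X)[ij[which.min(ry)]]
    message("collinearity screen: dropping '", loser, "' (|r| = ",
            sprintf("%.3f", max(C)), ")")
    dropped <- c(dropped, loser)
    X <- X[, setdiff(colnames(X), loser), drop = FALSE]
  }
  out <- dm
  out$X <- X
  out$groups <- dm$groups[colnames(X)]
  attr(out, "dropped") <- dropped
  out
}

## R^2 of every predictor subset from the correlation structure:
## R2(S) = r_yS' solve(R_SS) r_yS on standardized variables. Subsets are
## encoded as bitmasks 0 .. 2^p - 1.
.subsetR2 <- function(Rxx, rxy) {
  p <- length(rxy)
  nS <- bitwShiftL(1L, p)
  r2 <- numeric(nS)
  for (m in seq_len(nS - 1L)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    r2[m + 1L] <- sum(rxy[S] * solve(Rxx[S, S, drop = FALSE], rxy[S]))
  }
  r2
}

#' LMG relative-importance decomposition
#'
#' Allocates the model R^2 to predictors by averaging, over all orderings,
#' the increase in R^2 when each predictor enters the model; computed from
#' the covariance structure by subset enumeration with the standard
#' combinatorial weights `1 / (p * choose(p - 1, |S|))`. Shares are
#' reported as percent of the total R^2 (they sum to 100).
#'
#' @param dm a `DriverMatrix` (after [collinearityScreen()] if desired).
#' @return list of class `ImportanceTable`: `table` (data.frame with
#'   `variable`, `group`, `lmg_share`), `groupShares`, `r2`, `n`.
#' @export
lmg <- function(dm) {
  X <- dm$X; y <- dm$y
  p <- ncol(X)
  if (p > 15L) stop("lmg supports at most 15 predictors")
  if (nrow(X) <= 10L * p)
    warning("fewer than 10 pixels per predictor; shares may be unstable")
  Rxx <- cor(X)
  if (inherits(try(solve(Rxx), silent = TRUE), "try-error")) {
    C <- abs(Rxx); diag(C) <- 0
    ij <- which(C == max(C), arr.ind = TRUE)[1L, ]
    stop("singular design; most collinear pair: ",
         paste(colnames(X)[ij], collapse = " ~ "))
  }
  rxy <- as.numeric(cor(X, y))
  r2 <- .subsetR2(Rxx, rxy)
  r2full <- r2[length(r2)]
  if (r2full < 1e-12) stop("degenerate model: R^2 is (numerically) zero")
  bits <- bitwShiftL(1L, 0:(p - 1L))
  sizes <- vapply(0:(bitwShiftL(1L, p) - 1L), function(m)
    sum(bitwAnd(m, bits) != 0L), integer(1))
  w <- 1 / (p * choose(p - 1L, 0:(p - 1L)))
  raw <- numeric(p)
  for (k in seq_len(p)) {
    noK <- which(bitwAnd(0:(bitwShiftL(1L, p) - 1L), bits[k]) == 0L)
    gain <- r2[noK + bits[k]] - r2[noK]
    raw[k] <- sum(w[sizes[noK] + 1L] * gain)
  }
  share <- 100 * raw / r2full
  tab <- data.frame(variable = colnames(X), group = unname(dm$groups),
                    lmg_share = share, stringsAsFactors = FALSE)
  gs <- tapply(tab$lmg_share, tab$group, sum)
  structure(list(table = tab, groupShares = gs, r2 = r2full, n = nrow(X)),
            class = "ImportanceTable")
}

#' Bootstrap confidence intervals for LMG shares
#'
#' Resamples pixels with replacement, recomputes the decomposition per
#' replicate and reports percentile 5-95% intervals for the variable and
#' group shares. Degenerate (singular) replicates are skipped and counted.
#'
#' @param dm a `DriverMatrix`.
#' @param reps bootstrap replicates (default 1000, minimum 200).
#' @param seed integer seed (results are deterministic given it).
#' @param ciLevel two-sided interval mass (default 0.90 for 5-95%).
#' @return list: `table` (variable shares with `boot_mean`, `ci_lo`,
#'   `ci_hi`), `groupTable`, `groupReps` (replicates x groups matrix),
#'   `r2`, `nSkipped`.
#' @export
lmgBootstrap <- function(dm, reps = 1000L, seed = 1L, ciLevel = 0.90) {
  if (reps < 200L) stop("use at least 200 bootstrap replicates")
  base <- lmg(dm)
  p <- ncol(dm$X)
  n <- nrow(dm$X)
  set.seed(seed)
  shares <- matrix(NA_real_, reps, p,
                   dimnames = list(NULL, colnames(dm$X)))
  skipped <- 0L
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    dmb <- dm
    dmb$X <- dm$X[idx, , drop = FALSE]
    dmb$y <- dm$y[idx]
    res <- try(suppressWarnings(lmg(dmb)), silent = TRUE)
    if (inherits(res, "try-error")) { skipped <- skipped + 1L; next }
    shares[b, ] <- res$table$lmg_share
  }
  if (skipped > 0.05 * reps)
    warning(skipped, " of ", reps, " replicates were degenerate")
  a <- (1 - ciLevel) / 2
  qs <- apply(shares, 2L, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  tab <- base$table
  tab$boot_mean <- colMeans(shares, na.rm = TRUE)
  tab$ci_lo <- qs[1L, ]
  tab$ci_hi <- qs[2L, ]
  groups <- unique(unname(dm$groups))
  gReps <- sapply(groups, function(g)
    rowSums(shares[, dm$groups == g, drop = FALSE]))
  gqs <- apply(gReps, 2L, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  gTab <- data.frame(group = groups,
                     share = as.numeric(base$groupShares[groups]),
                     boot_mean = colMeans(gReps, na.rm = TRUE),
                     ci_lo = gqs[1L, ], ci_hi = gqs[2L, ],
                     stringsAsFactors = FALSE)
  list(table = tab, groupTable = gTab, groupReps = gReps, r2 = base$r2,
       nSkipped = skipped)
}

#' Partial-regression and univariate sensitivity slopes
#'
#' Partial slope of the response on each rainfall variable given all other
#' predictors (the residual-on-residual slope, identical to the multiple-
#' regression coefficient) with a t-based confidence interval, plus the
#' univariate OLS slope of the response on each rainfall variable
#' (beta_woody-Rainfall) with its own interval.
#'
#' @param dm a `DriverMatrix`.
#' @param vars predictor names to report (default: the
#'   rainfall-climatology group).
#' @param ciLevel interval mass (default 0.90 for 5-95%).
#' @return data.frame per variable: `partial_slope`, `partial_lo`,
#'   `partial_hi`, `uni_slope`, `uni_lo`, `uni_hi`.
#' @export
partialSlopes <- function(dm, vars = NULL, ciLevel = 0.90) {
  X <- dm$X; y <- dm$y
  if (is.null(vars))
    vars <- colnames(X)[dm$groups == "rainfall_climatology"]
  vars <- intersect(vars, colnames(X))
  fit <- lm(y ~ X)
  sm <- summary(fit)$coefficients
  rn <- paste0("X", vars)
  tq <- qt(1 - (1 - ciLevel) / 2, df = fit$df.residual)
  out <- lapply(vars, function(v) {
    b <- sm[paste0("X", v), 1L]; se <- sm[paste0("X", v), 2L]
    u <- olsSlope(X[, v], y)
    seU <- sqrt(sum((y - u$intercept - u$slope * X[, v])^2) /
                  (length(y) - 2)) / sqrt(sum((X[, v] - mean(X[, v]))^2))
    tqU <- qt(1 - (1 - ciLevel) / 2, df = length(y) - 2)
    data.frame(variable = v,
               partial_slope = b, partial_lo = b - tq * se,
               partial_hi = b + tq * se,
               uni_slope = u$slope, uni_lo = u$slope - tqU * seU,
               uni_hi = u$slope + tqU * seU,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
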