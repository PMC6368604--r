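#' @import methods
#' @importFrom stats acf coef cor lm median na.omit pnorm predict qnorm qt
#'   quantile rgamma rnorm runif sd setNames t.test var
#' @importFrom utils combn read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Regular latitude-longitude grid
#'
#' A uniform lat/lon grid of cell centers. Pixels are enumerated row-major
#' over latitude with longitude varying fastest, i.e. pixel
#' \code{(i_lat - 1) * n_lon + i_lon}.
#'
#' @slot lat numeric, latitude cell centers in degrees north (uniform step).
#' @slot lon numeric, longitude cell centers in degrees east (uniform step).
#' @slot cellSize numeric(1), nominal cell size in degrees.
#'
#' @seealso [savGrid()], [pixelCoords()]
#' @export
setClass("SavGrid", representation(
  lat = "numeric",
  lon = "numeric",
  cellSize = "numeric"
))

.uniformStep <- function(x) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  all(abs(d - d[1L]) < 1e-9) && all(d != 0)
}

setValidity("SavGrid", function(object) {
  msg <- character()
  if (!length(object@lat) || !length(object@lon))
    msg <- c(msg, "grid must have at least one lat and one lon center")
  if (!.uniformStep(object@lat))
    msg <- c(msg, "latitude centers must be uniformly spaced (to 1e-9 deg)")
  if (!.uniformStep(object@lon))
    msg <- c(msg, "longitude centers must be uniformly spaced (to 1e-9 deg)")
  if (any(object@lat < -90 | object@lat > 90))
    msg <- c(msg, "latitudes must lie in [-90, 90]")
  if (any(object@lon < -180 | object@lon >= 180))
    msg <- c(msg, "longitudes must lie in [-180, 180)")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Gridded time-series cube
#'
#' Dense per-pixel time series on a [SavGrid-class]: rows are pixels (in
#' grid enumeration order), columns are time steps. Used for daily rainfall,
#' bi-monthly LAI and monthly VOD.
#'
#' @slot grid a [SavGrid-class].
#' @slot time vector of time stamps (`Date`).
#' @slot values numeric matrix, `nPixels(grid)` x `length(time)`.
#' @slot varname character(1), variable name.
#' @slot units character(1), physical units.
#'
#' @export
setClass("GridCube", representation(
  grid = "SavGrid",
  time = "Date",
  values = "matrix",
  varname = "character",
  units = "character"
))

setValidity("GridCube", function(object) {
  msg <- character()
  np <- length(object@grid@lat) * length(object@grid@lon)
  if (nrow(object@values) != np)
    msg <- c(msg, sprintf("values has %d rows but grid has %d pixels",
                          nrow(object@values), np))
  if (ncol(object@values) != length(object@time))
    msg <- c(msg, "ncol(values) must equal length(time)")
  if (is.unsorted(object@time))
    msg <- c(msg, "time must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Pixel inclusion mask with exclusion provenance
#'
#' @slot grid a [SavGrid-class].
#' @slot include logical vector, one flag per pixel.
#' @slot reason character vector; for excluded pixels one of
#'   `"water"`, `"irrigated"`, `"cropland_gt70"`, `"non_savanna"`;
#'   `NA` for included pixels.
#'
#' @seealso [buildMask()]
#' @export
setClass("PixelMask", representation(
  grid = "SavGrid",
  include = "logical",
  reason = "character"
))

setValidity("PixelMask", function(object) {
  msg <- character()
  np <- length(object@grid@lat) * length(object@grid@lon)
  if (length(object@include) != np)
    msg <- c(msg, "include must have one entry per grid pixel")
  if (length(object@reason) != np)
    msg <- c(msg, "reason must have one entry per grid pixel")
  bad <- !object@include & is.na(object@reason)
  if (any(bad, na.rm = TRUE))
    msg <- c(msg, "every excluded pixel must carry an exclusion reason")
  if (any(object@include & !is.na(object@reason)))
    msg <- c(msg, "included pixels must not carry an exclusion reason")
  ok <- c("water", "irrigated", "cropland_gt70", "non_savanna")
  if (!all(object@reason[!is.na(object@reason)] %in% ok))
    msg <- c(msg, "unknown exclusion reason")
  if (length(msg)) msg else TRUE
})

#' Per-pixel by per-year panel of derived annual variables
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: rows are grid
#' pixels (rowData holds `pixel`, `lat`, `lon` plus any static per-pixel
#' statistics), columns are years, and each assay is one annual variable
#' (e.g. `annual_rainfall`, `rainy_days`, `heavy_rain_freq`, `intensity`,
#' `lai_max`, `vod_min`, `woody_cover`).
#'
#' @seealso [AnnualPanel()], [panelVar()], [panelYears()]
#' @export
setClass("AnnualPanel", contains = "SummarizedExperiment")
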