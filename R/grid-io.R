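#' Construct a regular lat/lon grid
#'
#' @param lat,lon numeric vectors of cell centers (uniform spacing), or use
#'   `latRange`/`lonRange` with `cellSize` to build them.
#' @param cellSize cell size in degrees; defaults to the lat step (or 0.25
#'   for a single row/column).
#' @param latRange,lonRange optional length-2 numeric; centers are laid out
#'   from `min + cellSize/2` upward.
#' @return a [SavGrid-class].
#' @examples
#' g <- savGrid(latRange = c(-10, 10), lonRange = c(20, 40), cellSize = 2.5)
#' nPixels(g)
#' @export
savGrid <- function(lat = NULL, lon = NULL, cellSize = NULL,
                    latRange = NULL, lonRange = NULL) {
  if (is.null(lat)) {
    stopifnot(!is.null(latRange), !is.null(cellSize))
    lat <- seq(min(latRange) + cellSize / 2, max(latRange), by = cellSize)
  }
  if (is.null(lon)) {
    stopifnot(!is.null(lonRange), !is.null(cellSize))
    lon <- seq(min(lonRange) + cellSize / 2, max(lonRange), by = cellSize)
  }
  if (is.null(cellSize))
    cellSize <- if (length(lat) > 1L) abs(diff(lat)[1L])
                else if (length(lon) > 1L) abs(diff(lon)[1L]) else 0.25
  new("SavGrid", lat = as.numeric(lat), lon = as.numeric(lon),
      cellSize = as.numeric(cellSize))
}

#' Number of pixels of a grid
#' @param grid a [SavGrid-class].
#' @return integer pixel count.
#' @export
nPixels <- function(grid) length(grid@lat) * length(grid@lon)

#' Pixel coordinate table
#'
#' @param grid a [SavGrid-class].
#' @return data.frame with columns `pixel`, `lat`, `lon` in the grid's
#'   enumeration order (longitude varying fastest).
#' @export
pixelCoords <- function(grid) {
  co <- expand.grid(lon = grid@lon, lat = grid@lat,
                    KEEP.OUT.ATTRS = FALSE)
  data.frame(pixel = seq_len(nrow(co)), lat = co$lat, lon = co$lon)
}

setMethod("show", "SavGrid", function(object) {
  cat(sprintf("SavGrid: %d lat x %d lon centers (%g deg cells), lat [%g, %g], lon [%g, %g]\n",
              length(object@lat), length(object@lon), object@cellSize,
              min(object@lat), max(object@lat),
              min(object@lon), max(object@lon)))
})

setMethod("show", "GridCube", function(object) {
  cat(sprintf("GridCube '%s' [%s]: %d pixels x %d time steps (%s .. %s)\n",
              object@varname, object@units, nrow(object@values),
              ncol(object@values), min(object@time), max(object@time)))
})

setMethod("show", "PixelMask", function(object) {
  cat(sprintf("PixelMask: %d / %d pixels included\n",
              sum(object@include), length(object@include)))
  if (any(!object@include))
    print(table(reason = object@reason[!object@include]))
})

#' Build a gridded cube
#' @param grid a [SavGrid-class].
#' @param time `Date` vector of time stamps.
#' @param values numeric matrix, pixels x time.
#' @param varname,units metadata strings.
#' @return a [GridCube-class].
#' @export
gridCube <- function(grid, time, values, varname = "value", units = "") {
  new("GridCube", grid = grid, time = as.Date(time),
      values = as.matrix(values), varname = varname, units = units)
}

#' @describeIn gridCube extract the values matrix (pixels x time).
#' @param cube a [GridCube-class].
#' @export
cubeValues <- function(cube) cube@values

#' @describeIn gridCube extract the time stamps.
#' @export
cubeTime <- function(cube) cube@time

#' @describeIn gridCube extract the grid.
#' @export
cubeGrid <- function(cube) cube@grid

## ---- regridding --------------------------------------------------------

## nearest source index for target centers: half-open cells
## [center - s/2, center + s/2), ties toward the lower index
.nearestIndex <- function(src, tgt) {
  step <- if (length(src) > 1L) diff(src)[1L] else 1
  idx <- round((tgt - src[1L]) / step) + 1L
  ## half-open convention: a point exactly on the upper cell edge belongs to
  ## the next cell, except that round() half-to-even must be overridden
  frac <- (tgt - src[1L]) / step
  idx <- floor(frac + 0.5) + 1L
  idx[idx < 1L | idx > length(src)] <- NA_integer_
  as.integer(idx)
}

## bracketing lower index and interpolation weight for 1-d linear interp
.interpIndex <- function(src, tgt) {
  step <- diff(src)[1L]
  pos <- (tgt - src[1L]) / step
  lo <- floor(pos) + 1L
  w <- pos - floor(pos)
  exact <- abs(w) < 1e-12
  out <- lo < 1L | lo + 1L > length(src)
  ## a target exactly on the last center is inside, not outside
  onLast <- out & exact & lo == length(src)
  lo[onLast] <- length(src) - 1L
  w[onLast] <- 1
  out[onLast] <- FALSE
  lo[out] <- NA_integer_
  list(lo = as.integer(lo), w = w)
}

#' Regrid a per-pixel field or cube onto a target grid
#'
#' Nearest-neighbour assignment uses half-open cells with ties broken toward
#' the lower index; bilinear output is the convex combination of the four
#' surrounding source centers and is missing whenever any corner is missing.
#' Targets outside the source bounding box become missing with a warning.
#'
#' @param x numeric vector (one value per source pixel) or a
#'   [GridCube-class].
#' @param source source [SavGrid-class] (ignored when `x` is a cube).
#' @param target target [SavGrid-class].
#' @param method `"nearest"` or `"bilinear"`.
#' @return vector on the target grid, or a regridded [GridCube-class].
#' @examples
#' src <- savGrid(lat = c(0, 1), lon = c(0, 1), cellSize = 1)
#' tgt <- savGrid(lat = 0.5, lon = 0.5, cellSize = 1)
#' regridField(c(0, 1, 2, 3), src, tgt, "bilinear")  # 1.5
#' @export
regridField <- function(x, source, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  validObject(source); validObject(target)
  if (length(x) != nPixels(source))
    stop("field length does not match the source grid")
  nlon <- length(source@lon)
  fld <- matrix(x, nrow = nlon)  # lon x lat
  tg <- expand.grid(lon = target@lon, lat = target@lat,
                    KEEP.OUT.ATTRS = FALSE)
  if (method == "nearest") {
    ilon <- .nearestIndex(source@lon, tg$lon)
    ilat <- .nearestIndex(source@lat, tg$lat)
    out <- rep(NA_real_, nrow(tg))
    ok <- !is.na(ilon) & !is.na(ilat)
    out[ok] <- fld[cbind(ilon[ok], ilat[ok])]
    if (any(!ok)) warning("target pixels outside source bounding box set to missing")
    return(out)
  }
  jlon <- .interpIndex(source@lon, tg$lon)
  jlat <- .interpIndex(source@lat, tg$lat)
  ok <- !is.na(jlon$lo) & !is.na(jlat$lo)
  if (any(!ok)) warning("target pixels outside source bounding box set to missing")
  out <- rep(NA_real_, nrow(tg))
  lo1 <- jlon$lo[ok]; w1 <- jlon$w[ok]
  lo2 <- jlat$lo[ok]; w2 <- jlat$w[ok]
  v00 <- fld[cbind(lo1,      lo2)]
  v10 <- fld[cbind(lo1 + 1L, lo2)]
  v01 <- fld[cbind(lo1,      lo2 + 1L)]
  v11 <- fld[cbind(lo1 + 1L, lo2 + 1L)]
  out[ok] <- (1 - w1) * (1 - w2) * v00 + w1 * (1 - w2) * v10 +
             (1 - w1) * w2 * v01 + w1 * w2 * v11
  out
}

#' @rdname regridField
#' @export
regridCube <- function(x, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  vals <- apply(x@values, 2L, regridField, source = x@grid,
                target = target, method = method)
  gridCube(target, x@time, matrix(vals, ncol = length(x@time)),
           varname = x@varname, units = x@units)
}

## ---- masking and region classification ---------------------------------

#' Build the analysis pixel mask
#'
#' A pixel is included when it is savanna, its cropped percentage is at most
#' 70, and it is neither irrigated nor water. Exclusion reasons are assigned
#' with priority water > irrigated > cropland_gt70 > non_savanna.
#'
#' @param savanna logical per pixel, savanna extent.
#' @param cropFraction numeric per pixel, cropped percentage (0-100).
#' @param irrigated,water logical per pixel.
#' @param grid the common [SavGrid-class].
#' @return a [PixelMask-class].
#' @export
buildMask <- function(savanna, cropFraction, irrigated, water, grid) {
  np <- nPixels(grid)
  lens <- c(length(savanna), length(cropFraction), length(irrigated),
            length(water))
  if (any(lens != np))
    stop("all mask input fields must be on the same grid (", np, " pixels)")
  include <- savanna & cropFraction <= 70 & !irrigated & !water
  reason <- rep(NA_character_, np)
  excl <- !include
  reason[excl & !savanna] <- "non_savanna"
  reason[excl & cropFraction > 70] <- "cropland_gt70"
  reason[excl & irrigated] <- "irrigated"
  reason[excl & water] <- "water"
  new("PixelMask", grid = grid, include = include, reason = reason)
}

#' @describeIn buildMask logical inclusion vector of a mask.
#' @param mask a [PixelMask-class].
#' @export
maskInclude <- function(mask) mask@include

#' @describeIn buildMask exclusion-reason vector (`NA` for included pixels).
#' @export
maskReason <- function(mask) mask@reason

#' Classify pixels into aridity regions by mean annual rainfall
#'
#' Arid: MAR < 300; semi-arid: 300 <= MAR <= 700; humid: MAR > 700 mm/yr;
#' missing MAR gives `unclassified`.
#'
#' @param mar numeric, mean annual rainfall (mm/yr) per pixel; `NA` allowed.
#' @return factor with levels `arid`, `semi_arid`, `humid`, `unclassified`.
#' @examples
#' classifyRegion(c(250, 300, 700, 1800, NA))
#' @export
classifyRegion <- function(mar) {
  if (any(mar < 0, na.rm = TRUE))
    stop("mean annual rainfall must be non-negative")
  lab <- rep("unclassified", length(mar))
  lab[!is.na(mar) & mar < 300] <- "arid"
  lab[!is.na(mar) & mar >= 300 & mar <= 700] <- "semi_arid"
  lab[!is.na(mar) & mar > 700] <- "humid"
  factor(lab, levels = c("arid", "semi_arid", "humid", "unclassified"))
}

## ---- annual panel ------------------------------------------------------

#' Construct an annual panel
#'
#' @param grid a [SavGrid-class].
#' @param years integer vector of years (panel columns).
#' @param assays named list of numeric matrices, each pixels x years.
#' @param rowData optional extra per-pixel columns (static statistics).
#' @return an [AnnualPanel-class].
#' @export
AnnualPanel <- function(grid, years, assays, rowData = NULL) {
  co <- pixelCoords(grid)
  rd <- S4Vectors::DataFrame(co)
  if (!is.null(rowData)) rd <- cbind(rd, S4Vectors::DataFrame(rowData))
  assays <- lapply(assays, function(a) {
    a <- as.matrix(a)
    dimnames(a) <- list(NULL, as.character(years))
    a
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd,
    colData = S4Vectors::DataFrame(year = as.integer(years)),
    metadata = list(grid = grid))
  new("AnnualPanel", se)
}

#' Panel accessors
#'
#' @param panel an [AnnualPanel-class].
#' @param var assay name.
#' @return `panelVar`: pixels x years numeric matrix; `panelYears`: integer
#'   years; `panelGrid`: the [SavGrid-class].
#' @export
panelVar <- function(panel, var) {
  if (!var %in% SummarizedExperiment::assayNames(panel))
    stop("no assay '", var, "' in panel (have: ",
         paste(SummarizedExperiment::assayNames(panel), collapse = ", "), ")")
  SummarizedExperiment::assay(panel, var)
}

#' @rdname panelVar
#' @export
panelYears <- function(panel) SummarizedExperiment::colData(panel)$year

#' @rdname panelVar
#' @export
panelGrid <- function(panel) S4Vectors::metadata(panel)$grid

## ---- plain-text I/O ----------------------------------------------------

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read a gridded cube as long-format CSV
#'
#' Values are serialised with 17 significant digits so that a write/read
#' round trip is bit-exact; coordinates are reconstructed from the unique
#' lat/lon values.
#'
#' @param cube a [GridCube-class].
#' @param path file path.
#' @return `readCubeCSV` returns a [GridCube-class]; `writeCubeCSV` returns
#'   `path` invisibly.
#' @export
writeCubeCSV <- function(cube, path) {
  co <- pixelCoords(cube@grid)
  nt <- length(cube@time)
  df <- data.frame(
    varname = cube@varname, units = cube@units,
    pixel = rep(co$pixel, nt),
    lat = .fmtNum(rep(co$lat, nt)),
    lon = .fmtNum(rep(co$lon, nt)),
    time = as.character(rep(cube@time, each = nrow(co))),
    value = .fmtNum(as.vector(cube@values)),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCubeCSV
#' @export
readCubeCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(lat = "character", lon = "character",
                                value = "character"))
  ## pixel enumeration order (lon fastest) means first-appearance order of
  ## the unique coordinates reproduces the original axes, incl. orientation
  glat <- unique(as.numeric(df$lat)); glon <- unique(as.numeric(df$lon))
  grid <- savGrid(lat = glat, lon = glon)
  times <- sort(unique(as.Date(df$time)))
  vals <- matrix(NA_real_, nPixels(grid), length(times))
  ti <- match(as.Date(df$time), times)
  vals[cbind(df$pixel, ti)] <- as.numeric(df$value)
  gridCube(grid, times, vals, varname = df$varname[1L], units = df$units[1L])
}

#' Write / read an annual panel as a flat per-pixel CSV
#'
#' Long format with columns `pixel, lat, lon, year, variable, value`
#' (assays) plus rows with `year = NA` for static per-pixel columns.
#'
#' @param panel an [AnnualPanel-class].
#' @param path file path.
#' @export
writePanelCSV <- function(panel, path) {
  years <- panelYears(panel)
  co <- as.data.frame(SummarizedExperiment::rowData(panel))
  an <- SummarizedExperiment::assayNames(panel)
  blocks <- lapply(an, function(v) {
    m <- panelVar(panel, v)
    data.frame(pixel = rep(co$pixel, length(years)),
               lat = .fmtNum(rep(co$lat, length(years))),
               lon = .fmtNum(rep(co$lon, length(years))),
               year = rep(years, each = nrow(co)),
               variable = v, value = .fmtNum(as.vector(m)),
               stringsAsFactors = FALSE)
  })
  statics <- setdiff(names(co), c("pixel", "lat", "lon"))
  sblocks <- lapply(statics, function(v)
    data.frame(pixel = co$pixel, lat = .fmtNum(co$lat),
               lon = .fmtNum(co$lon), year = NA_integer_, variable = v,
               value = .fmtNum(as.numeric(co[[v]])),
               stringsAsFactors = FALSE))
  df <- do.call(rbind, c(blocks, sblocks))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePanelCSV
#' @export
readPanelCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(lat = "character", lon = "character",
                                value = "character"))
  df$lat <- as.numeric(df$lat); df$lon <- as.numeric(df$lon)
  df$value <- as.numeric(df$value)
  pix <- !duplicated(df$pixel)
  ord <- order(df$pixel[pix])
  glat <- unique(df$lat[pix][ord]); glon <- unique(df$lon[pix][ord])
  grid <- savGrid(lat = glat, lon = glon)
  ann <- df[!is.na(df$year), ]
  years <- sort(unique(ann$year))
  assays <- lapply(split(ann, ann$variable), function(b) {
    m <- matrix(NA_real_, nPixels(grid), length(years))
    m[cbind(b$pixel, match(b$year, years))] <- b$value
    m
  })
  stat <- df[is.na(df$year), ]
  rowData <- NULL
  if (nrow(stat)) {
    rowData <- lapply(split(stat, stat$variable), function(b) {
      v <- rep(NA_real_, nPixels(grid)); v[b$pixel] <- b$value; v
    })
  }
  AnnualPanel(grid, years, assays, rowData = rowData)
}
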