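test_that("grid validity enforces uniform spacing and coordinate ranges", {
  expect_error(savGrid(lat = c(0, 1, 2.5), lon = 0:1),
               "uniformly spaced")
  expect_error(savGrid(lat = c(0, 1), lon = c(170, 180)), "180")
  g <- savGrid(latRange = c(-10, 10), lonRange = c(0, 10), cellSize = 0.25)
  expect_equal(nPixels(g), 80 * 40)
  co <- pixelCoords(g)
  expect_equal(co$lon[1:2], c(0.125, 0.375))  # lon varies fastest
})

test_that("regridding a constant field is the identity for both methods", {
  src <- savGrid(lat = seq(0, 2, 0.5), lon = seq(10, 12, 0.5))
  tgt <- savGrid(lat = seq(0.25, 1.75, 0.5), lon = seq(10.25, 11.75, 0.5))
  f <- rep(5, nPixels(src))
  expect_true(all(regridField(f, src, tgt, "nearest") == 5))
  expect_true(all(regridField(f, src, tgt, "bilinear") == 5))
})

test_that("bilinear weights collapse on a coincident center and give the
           hand-computed midpoint value", {
  src <- savGrid(lat = c(0, 1), lon = c(0, 1), cellSize = 1)
  ## field [[0,1],[2,3]]: pixel order (lat0,lon0)=0,(lat0,lon1)=1,...
  f <- c(0, 1, 2, 3)
  same <- savGrid(lat = 0, lon = 1, cellSize = 1)
  expect_identical(regridField(f, src, same, "bilinear"), 1)
  mid <- savGrid(lat = 0.5, lon = 0.5, cellSize = 1)
  expect_equal(regridField(f, src, mid, "bilinear"), 1.5)
})

test_that("nearest regridding is idempotent on an identical grid and
           propagates missing corners under bilinear", {
  src <- savGrid(lat = seq(0, 1, 0.25), lon = seq(0, 1, 0.25))
  set.seed(1)
  f <- rnorm(nPixels(src))
  expect_identical(regridField(f, src, src, "nearest"), f)
  f2 <- f; f2[1] <- NA
  tgt <- savGrid(lat = 0.125, lon = 0.125, cellSize = 0.25)
  expect_true(is.na(regridField(f2, src, tgt, "bilinear")))
})

test_that("targets outside the source bounding box become missing with a
           warning", {
  src <- savGrid(lat = c(0, 1), lon = c(0, 1), cellSize = 1)
  out <- savGrid(lat = 5, lon = 5, cellSize = 1)
  expect_warning(v <- regridField(1:4, src, out, "bilinear"), "bounding box")
  expect_true(is.na(v))
})

test_that("cube regridding maps every time slice", {
  src <- savGrid(lat = c(0, 1), lon = c(0, 1), cellSize = 1)
  cube <- gridCube(src, as.Date("2000-01-01") + 0:1,
                   cbind(c(0, 1, 2, 3), c(4, 5, 6, 7)))
  mid <- savGrid(lat = 0.5, lon = 0.5, cellSize = 1)
  rc <- regridCube(cube, mid, "bilinear")
  expect_equal(as.vector(cubeValues(rc)), c(1.5, 5.5))
})

test_that("mask logic follows the strict crop threshold and the reason
           priority order", {
  g <- savGrid(lat = 0, lon = seq(0, 1.25, 0.25), cellSize = 0.25)
  sav <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  crop <- c(71, 70, 0, 0, 80, 90)
  irr <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  wat <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  m <- buildMask(sav, crop, irr, wat, g)
  expect_equal(maskInclude(m), c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(maskReason(m),
               c("cropland_gt70", NA, "non_savanna", "irrigated",
                 "water", "water"))
  ## excluded-by-reason counts sum to the total excluded
  expect_equal(sum(table(maskReason(m))), sum(!maskInclude(m)))
  expect_error(buildMask(sav[1:3], crop, irr, wat, g), "same grid")
})

test_that("aridity classification puts both boundary values in semi_arid
           and rejects negative rainfall", {
  r <- classifyRegion(c(250, 300, 700, 1800, NA, 0))
  expect_equal(as.character(r),
               c("arid", "semi_arid", "semi_arid", "humid",
                 "unclassified", "arid"))
  expect_error(classifyRegion(-5), "non-negative")
})

test_that("cube CSV round trip is bit-exact in values and coordinates", {
  g <- savGrid(lat = c(1.25, 1.0, 0.75), lon = c(30.25, 30.5),
               cellSize = 0.25)  # descending latitude preserved
  set.seed(9)
  v <- matrix(rnorm(6 * 4) * 1e3, 6, 4)
  v[2, 3] <- NA
  cube <- gridCube(g, as.Date("2001-05-01") + 0:3, v, "rainfall", "mm/day")
  f <- tempfile(fileext = ".csv")
  writeCubeCSV(cube, f)
  back <- readCubeCSV(f)
  expect_identical(cubeValues(back), unname(v))
  expect_identical(back@grid@lat, g@lat)
  expect_identical(back@grid@lon, g@lon)
  expect_identical(cubeTime(back), cubeTime(cube))
})

test_that("annual panel CSV round trip preserves assays and statics", {
  g <- smallGrid(3L)
  yrs <- 2000:2004
  set.seed(2)
  pan <- AnnualPanel(g, yrs,
                     assays = list(a = matrix(rnorm(45), 9),
                                   b = matrix(runif(45), 9)),
                     rowData = list(mar = runif(9, 100, 900)))
  f <- tempfile(fileext = ".csv")
  writePanelCSV(pan, f)
  back <- readPanelCSV(f)
  expect_identical(unname(panelVar(back, "a")), unname(panelVar(pan, "a")))
  expect_identical(unname(panelVar(back, "b")), unname(panelVar(pan, "b")))
  expect_identical(panelYears(back), panelYears(pan))
  expect_identical(SummarizedExperiment::rowData(back)$mar,
                   SummarizedExperiment::rowData(pan)$mar)
})
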