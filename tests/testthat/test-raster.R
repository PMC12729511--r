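test_that("ESRI ASCII parsing follows the header and north-up convention", {
  p <- write_asc_fixture(c("ncols 2", "nrows 2", "xllcorner 0",
                           "yllcorner 0", "cellsize 1",
                           "NODATA_value -9999", "1 2", "3 4"))
  g <- read_raster(p)
  expect_equal(g$values[1, ], c(1, 2))        # north row first
  expect_equal(g$values[2, ], c(3, 4))
  cg <- cell_geometry(g$spec, 2, 1)
  expect_equal(c(cg$lon, cg$lat), c(0.5, 0.5))

  # xllcenter accepted and converted to a corner
  p2 <- write_asc_fixture(c("ncols 2", "nrows 2", "XLLCENTER 0.5",
                            "yllcorner 0", "cellsize 1", "1 2", "3 4"))
  expect_equal(read_raster(p2)$spec$x_min, 0)

  # nodata sentinel maps to NA
  p3 <- write_asc_fixture(c("ncols 2", "nrows 1", "xllcorner 0",
                            "yllcorner 0", "cellsize 1",
                            "NODATA_value -9999", "-9999 7"))
  expect_true(is.na(read_raster(p3)$values[1, 1]))
})

test_that("malformed ESRI ASCII inputs raise named errors", {
  p <- write_asc_fixture(c("ncols 2", "xllcorner 0", "yllcorner 0",
                           "cellsize 1", "1 2"))
  expect_error(read_raster(p), "nrows")
  p2 <- write_asc_fixture(c("ncols 2", "nrows 2", "xllcorner 0",
                            "yllcorner 0", "cellsize 1", "1 2", "3"))
  expect_error(read_raster(p2), "non-rectangular")
})

test_that("write/read round-trips both dialects including nodata and zeros", {
  spec <- grid_spec(5, 4, x_min = 100, y_max = 30, dx = 0.5)
  set.seed(1)
  v <- matrix(rnorm(20, sd = 100), 5, 4)
  v[2, 3] <- NA
  g <- raster_grid(spec, v)
  for (ext in c(".asc", ".tif")) {
    p <- tempfile(fileext = ext)
    write_raster(g, p)
    g2 <- read_raster(p)
    expect_equal(g2$values, g$values, tolerance = 1e-6)
    expect_equal(unclass(g2$spec)[1:6], unclass(spec)[1:6])
    expect_true(is.na(g2$values[2, 3]))
  }
  z <- raster_grid(spec, matrix(0, 5, 4))
  p <- tempfile(fileext = ".asc")
  write_raster(z, p)
  expect_true(all(read_raster(p)$values == 0))
})

test_that("cell geometry matches the spherical closed form", {
  # 1-degree cell centered on the equator
  s <- grid_spec(2, 1, x_min = 0, y_max = 1, dx = 1)
  eq <- cell_geometry(s, 1, 1)   # center lat 0.5 -> not exactly equator
  s2 <- grid_spec(1, 1, x_min = 0, y_max = 0.5, dx = 1)
  eq2 <- cell_geometry(s2, 1, 1) # center exactly (0.5, 0)
  expect_equal(eq2$area_km2, (pi * 6371.0088 / 180)^2, tolerance = 1e-9)
  expect_equal(eq2$area_km2, 12364.3, tolerance = 1e-4)
  # same cell at 60 N: exactly half the equatorial area
  s60 <- grid_spec(1, 1, x_min = 0, y_max = 60.5, dx = 1)
  expect_equal(cell_geometry(s60, 1, 1)$area_km2, eq2$area_km2 / 2,
               tolerance = 1e-12)
  # center formula
  s3 <- grid_spec(4, 4, x_min = 100, y_max = 30, dx = 0.5)
  cg <- cell_geometry(s3, 1, 1)
  expect_equal(c(cg$lon, cg$lat), c(100.25, 29.75))
  expect_error(cell_geometry(s3, 5, 1), "out of range")
})

test_that("summed 1-degree global cell areas give the sphere surface", {
  s <- grid_spec(180, 360, x_min = -180, y_max = 90, dx = 1)
  total <- sum(row_areas_km2(s)) * s$n_cols
  expect_equal(total, 5.101e8, tolerance = 0.005)
})

test_that("point extraction is half-open, reports misses, and ignores layer order", {
  spec <- grid_spec(2, 2, x_min = 0, y_max = 2, dx = 1)
  a <- raster_grid(spec, matrix(1:4, 2, 2, byrow = TRUE))
  b <- raster_grid(spec, matrix(c(10, 20, 30, NA), 2, 2, byrow = TRUE))
  st <- raster_stack(list(a = a, b = b))
  pts <- data.frame(lon = c(0.5, 1e-9, -0.5, 1.5),
                    lat = c(1.5, 1.5, 0.5, 0.5))
  ex <- extract_at_points(st, pts)
  expect_equal(ex$a, c(1, 1, NA, 4))
  expect_equal(ex$b, c(10, 10, NA, NA))
  rep <- attr(ex, "report")
  expect_equal(rep$n_outside, 1)
  expect_equal(rep$n_nodata, 1)
  # layer reordering leaves per-layer values unchanged
  ex2 <- extract_at_points(raster_stack(list(b = b, a = a)), pts)
  expect_equal(ex2$a, ex$a)
  expect_equal(ex2$b, ex$b)
})
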