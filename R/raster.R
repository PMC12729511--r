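#' @useDynLib iqzone, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate coef complete.cases cor lm median na.omit optim
#'   pt quantile rnorm runif sd setNames var nlminb fft predict
#' @importFrom utils read.csv write.csv head modifyList
NULL

# mean Earth radius, km (IUGG)
.R_EARTH_KM <- 6371.0088

#' Grid geometry specification
#'
#' Describes a north-up regular lattice of cells in geographic (WGS84)
#' coordinates: the raster geometry shared by every layer of an analysis.
#' `x_min` is the west edge and `y_max` the north edge of the grid; row 1 of
#' the value matrix is the northernmost row. Cell membership is half-open,
#' `[edge, edge + d)`, so a point exactly on a western/northern cell edge
#' belongs to that cell.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param x_min longitude of the west edge (decimal degrees).
#' @param y_max latitude of the north edge (decimal degrees).
#' @param dx,dy cell size in degrees (positive); `dy` defaults to `dx`.
#' @param nodata sentinel value used when the grid is serialized.
#' @param crs CRS tag; only geographic WGS84 (`"EPSG:4326"`) is supported.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, x_min, y_max, dx, dy = dx,
                      nodata = -9999, crs = "EPSG:4326") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, dx > 0, dy > 0,
            x_min >= -180, x_min < 180,
            y_max - n_rows * dy >= -90 - 1e-9, y_max <= 90 + 1e-9)
  if (!identical(crs, "EPSG:4326"))
    stop("only geographic WGS84 ('EPSG:4326') is supported")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 x_min = x_min, y_max = y_max, dx = dx, dy = dy,
                 nodata = nodata, crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, cell %g x %g deg\n",
              x$n_rows, x$n_cols, x$dx, x$dy))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]  (%s)\n",
              x$x_min, x$x_min + x$n_cols * x$dx,
              x$y_max - x$n_rows * x$dy, x$y_max, x$crs))
  invisible(x)
}

same_spec <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_min - b$x_min) < tol && abs(a$y_max - b$y_max) < tol &&
    abs(a$dx - b$dx) < tol && abs(a$dy - b$dy) < tol
}

#' Georeferenced value surface
#'
#' A single raster layer: a `grid_spec` plus an `n_rows x n_cols` numeric
#' matrix with row 1 the northernmost row. Missing cells are `NA` internally;
#' the `nodata` sentinel of the spec is only used on disk.
#'
#' @param spec a [grid_spec()].
#' @param values numeric matrix matching the spec's dimensions.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop(sprintf("values are %d x %d but spec demands %d x %d",
                 nrow(values), ncol(values), spec$n_rows, spec$n_cols))
  storage.mode(values) <- "double"
  if (any(is.infinite(values)))
    stop("raster values must be finite or NA")
  structure(list(spec = spec, values = values), class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("raster_grid %d x %d: %d valid cells", x$spec$n_rows,
              x$spec$n_cols, length(v)))
  if (length(v)) cat(sprintf(", range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Ordered collection of co-registered raster layers
#'
#' @param layers named list of [raster_grid()] objects sharing one spec.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique non-empty names")
  spec <- layers[[1L]]$spec
  for (i in seq_along(layers)) {
    if (!inherits(layers[[i]], "raster_grid"))
      stop("layer '", nm[i], "' is not a raster_grid")
    if (!same_spec(spec, layers[[i]]$spec))
      stop("layer '", nm[i], "' has a different grid_spec")
  }
  structure(list(spec = spec, layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layers on a %d x %d grid\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

# ---- cell geometry ---------------------------------------------------------

#' Cell centers and spherical areas
#'
#' Center of cell (row, col) is `(x_min + (col - 0.5) dx, y_max - (row - 0.5) dy)`
#' (1-based indices). The cell area uses the spherical approximation
#' `dx dy (pi/180)^2 R^2 cos(lat_center)` with R = 6371.0088 km, accurate to
#' well under 1 percent at the cell sizes used here.
#'
#' @param spec a [grid_spec()].
#' @param row,col 1-based cell indices (vectorized, recycled).
#' @return data.frame with columns `lon`, `lat`, `area_km2`.
#' @export
cell_geometry <- function(spec, row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 1L | row > spec$n_rows | col < 1L | col > spec$n_cols))
    stop("cell index out of range")
  lon <- spec$x_min + (col - 0.5) * spec$dx
  lat <- spec$y_max - (row - 0.5) * spec$dy
  area <- spec$dx * spec$dy * (pi / 180)^2 * .R_EARTH_KM^2 * cos(lat * pi / 180)
  data.frame(lon = lon, lat = lat, area_km2 = area)
}

# per-row cell area (constant along a row); returns vector length n_rows
row_areas_km2 <- function(spec) {
  lat <- spec$y_max - (seq_len(spec$n_rows) - 0.5) * spec$dy
  spec$dx * spec$dy * (pi / 180)^2 * .R_EARTH_KM^2 * cos(lat * pi / 180)
}

# lon of column centers / lat of row centers
col_lons <- function(spec) spec$x_min + (seq_len(spec$n_cols) - 0.5) * spec$dx
row_lats <- function(spec) spec$y_max - (seq_len(spec$n_rows) - 0.5) * spec$dy

# map points to (row, col); NA outside the grid. Half-open [edge, edge + d).
point_to_cell <- function(spec, lon, lat) {
  col <- floor((lon - spec$x_min) / spec$dx) + 1
  row <- floor((spec$y_max - lat) / spec$dy) + 1
  # a point exactly on the southern/eastern outer edge is outside
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract layer values at points
#'
#' Nearest-cell lookup under the half-open cell convention. Points outside the
#' grid, or falling on a cell that is nodata in any layer, yield `NA` entries;
#' their counts are attached as the `"report"` attribute.
#'
#' @param stack a [raster_stack()].
#' @param points data.frame with columns `lon`, `lat`.
#' @return data.frame with one row per point and one column per layer, plus
#'   attribute `report` (list with `n_outside`, `n_nodata`).
#' @export
extract_at_points <- function(stack, points) {
  stopifnot(inherits(stack, "raster_stack"),
            all(c("lon", "lat") %in% names(points)))
  rc <- point_to_cell(stack$spec, points$lon, points$lat)
  inside <- !is.na(rc$row)
  idx <- rc$row + (rc$col - 1L) * stack$spec$n_rows  # column-major index
  out <- as.data.frame(lapply(stack$layers, function(g) {
    v <- rep(NA_real_, nrow(points))
    v[inside] <- g$values[idx[inside]]
    v
  }))
  names(out) <- names(stack$layers)
  nodata_hit <- inside & !complete.cases(out)
  attr(out, "report") <- list(n_outside = sum(!inside),
                              n_nodata = sum(nodata_hit))
  out
}

# ---- ESRI ASCII I/O --------------------------------------------------------

read_asc <- function(path) {
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  for (k in need) if (is.null(hdr[[k]]))
    stop("malformed ESRI ASCII header: missing key '", k, "'")
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    stop("malformed ESRI ASCII header: missing key 'xllcorner'")
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    stop("malformed ESRI ASCII header: missing key 'yllcorner'")
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("non-rectangular body: expected %d values, found %d",
                 nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  spec <- grid_spec(nr, nc, x_min = xll, y_max = yll + nr * cs,
                    dx = cs, dy = cs, nodata = nodata)
  raster_grid(spec, m)
}

write_asc <- function(grid, path) {
  s <- grid$spec
  if (abs(s$dx - s$dy) > 1e-12)
    stop("ESRI ASCII requires square cells (dx == dy)")
  hdr <- c(sprintf("ncols %d", s$n_cols),
           sprintf("nrows %d", s$n_rows),
           sprintf("xllcorner %.10g", s$x_min),
           sprintf("yllcorner %.10g", s$y_max - s$n_rows * s$dy),
           sprintf("cellsize %.10g", s$dx),
           sprintf("NODATA_value %.10g", s$nodata))
  m <- grid$values
  m[is.na(m)] <- s$nodata
  body <- apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- minimal single-band GeoTIFF I/O ---------------------------------------
# Little-endian, one sample per pixel, IEEE Float64, single strip, georeferenced
# with ModelPixelScale + ModelTiepoint and a GeoKey directory declaring
# geographic WGS84. Nodata carried in the GDAL_NODATA ASCII tag.

write_gtiff <- function(grid, path) {
  s <- grid$spec
  m <- grid$values
  m[is.na(m)] <- s$nodata
  vals <- as.vector(t(m))                       # row-major, north-up
  con <- file(path, "wb")
  on.exit(close(con))
  # unsigned little-endian integers written byte-wise (tag ids exceed the
  # signed 16-bit range); doubles go through writeBin
  w <- function(x, size) {
    if (size == 8L) return(writeBin(as.double(x), con, size = 8L,
                                    endian = "little"))
    for (xi in as.numeric(x)) {
      bytes <- integer(size)
      for (b in seq_len(size)) { bytes[b] <- xi %% 256; xi <- xi %/% 256 }
      writeBin(as.raw(bytes), con)
    }
  }
  nodata_str <- sprintf("%.10g", s$nodata)
  nodata_raw <- c(charToRaw(nodata_str), as.raw(0L))
  n_tags <- 16L
  # layout: 8 header | ifd (2 + 12*n + 4) | aux data | pixel data
  ifd_off <- 8L
  ifd_len <- 2L + 12L * n_tags + 4L
  aux_off <- ifd_off + ifd_len
  scale_off <- aux_off                    # 3 doubles
  tie_off <- scale_off + 24L              # 6 doubles
  geokey_off <- tie_off + 48L             # 8 shorts * 2 bytes? see below
  geokeys <- as.integer(c(1, 1, 0, 3,     # version, rev, minor, number of keys
                          1024, 0, 1, 2,  # GTModelType = geographic
                          1025, 0, 1, 2,  # GTRasterType = PixelIsPoint? use Area
                          2048, 0, 1, 4326)) # GeographicType = WGS84
  geokeys[11] <- 1L                       # RasterPixelIsArea
  geokey_len <- length(geokeys) * 2L
  nodata_off <- geokey_off + geokey_len
  data_off <- nodata_off + length(nodata_raw)
  if (data_off %% 2L == 1L) data_off <- data_off + 1L
  n_bytes <- length(vals) * 8L

  writeBin(charToRaw("II"), con)
  w(42L, 2)                    # magic
  w(ifd_off, 4)                # first IFD offset
  w(n_tags, 2)
  tag <- function(id, type, count, value) {
    w(as.integer(id), 2); w(as.integer(type), 2); w(as.integer(count), 4)
    # value/offset field is always 4 bytes
    if (type == 3 && count == 1) { w(as.integer(value), 2); w(0L, 2) }
    else w(as.integer(value), 4)
  }
  tag(256, 3, 1, s$n_cols)               # ImageWidth
  tag(257, 3, 1, s$n_rows)               # ImageLength
  tag(258, 3, 1, 64L)                    # BitsPerSample
  tag(259, 3, 1, 1L)                     # Compression = none
  tag(262, 3, 1, 1L)                     # Photometric = BlackIsZero
  tag(273, 4, 1, data_off)               # StripOffsets
  tag(277, 3, 1, 1L)                     # SamplesPerPixel
  tag(278, 3, 1, s$n_rows)               # RowsPerStrip
  tag(279, 4, 1, n_bytes)                # StripByteCounts
  tag(284, 3, 1, 1L)                     # PlanarConfiguration
  tag(339, 3, 1, 3L)                     # SampleFormat = IEEE float
  tag(33550, 12, 3, scale_off)           # ModelPixelScaleTag
  tag(33922, 12, 6, tie_off)             # ModelTiepointTag
  tag(34735, 3, length(geokeys), geokey_off)  # GeoKeyDirectory
  tag(42112, 2, 1, 0L)                   # GDAL_METADATA placeholder (empty)
  tag(42113, 2, length(nodata_raw), nodata_off) # GDAL_NODATA
  w(0L, 4)                               # next IFD = none
  w(c(s$dx, s$dy, 0), 8)                 # pixel scale
  w(c(0, 0, 0, s$x_min, s$y_max, 0), 8)  # tiepoint: raster (0,0) -> (x_min, y_max)
  w(geokeys, 2)
  writeBin(nodata_raw, con)
  pad <- data_off - (nodata_off + length(nodata_raw))
  if (pad > 0) writeBin(as.raw(rep(0L, pad)), con)
  w(vals, 8)
  invisible(path)
}

read_gtiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  rd <- function(off, what, n, size) {
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little",
            signed = !(what == "integer" && size <= 2L))
  }
  if (rawToChar(raw[1:2]) != "II")
    stop("unsupported TIFF: only little-endian files are read")
  if (rd(2, "integer", 1, 2) != 42L) stop("not a TIFF file")
  ifd <- rd(4, "integer", 1, 4)
  n_tags <- rd(ifd, "integer", 1, 2)
  tags <- list()
  for (i in seq_len(n_tags)) {
    off <- ifd + 2L + (i - 1L) * 12L
    id <- rd(off, "integer", 1, 2)
    type <- rd(off + 2, "integer", 1, 2)
    count <- rd(off + 4, "integer", 1, 4)
    tags[[as.character(id)]] <- list(type = type, count = count, voff = off + 8)
  }
  tval <- function(id, default = NULL) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) return(default)
    size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `12` = 8)[[as.character(t$type)]]
    what <- if (t$type == 12) "double" else if (t$type == 2) "raw" else "integer"
    inline <- size * t$count <= 4
    off <- if (inline) t$voff else rd(t$voff, "integer", 1, 4)
    v <- rd(off, what, t$count, size)
    if (t$type == 2) v <- rawToChar(v[v != as.raw(0)]) else v
  }
  nc <- tval(256); nr <- tval(257)
  bps <- tval(258, 32L); fmt <- tval(339, 1L)
  if (is.null(nc) || is.null(nr)) stop("malformed TIFF: missing dimensions")
  if (!fmt[1] %in% 3L || !bps[1] %in% c(32L, 64L))
    stop("unsupported TIFF: need IEEE float samples")
  if (!identical(tval(259, 1L), 1L)) stop("unsupported TIFF: compressed")
  strip_off <- tval(273); strip_cnt <- tval(279)
  scale <- tval(33550); tie <- tval(33922)
  if (is.null(scale) || is.null(tie))
    stop("malformed GeoTIFF: missing georeferencing tags")
  nodata <- suppressWarnings(as.numeric(tval(42113, "-9999")))
  if (is.na(nodata)) nodata <- -9999
  size <- if (bps[1] == 64L) 8L else 4L
  vals <- numeric(0)
  for (i in seq_along(strip_off))
    vals <- c(vals, rd(strip_off[i], "double", strip_cnt[i] / size, size))
  if (length(vals) != nr * nc) stop("malformed TIFF: body size mismatch")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  spec <- grid_spec(nr, nc, x_min = tie[4], y_max = tie[5],
                    dx = scale[1], dy = scale[2], nodata = nodata)
  raster_grid(spec, m)
}

guess_format <- function(path, format) {
  if (!is.null(format) && format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt")) "esri_ascii"
  else if (ext %in% c("tif", "tiff")) "geotiff"
  else stop("cannot guess raster format from extension '", ext, "'")
}

#' Read a raster layer
#'
#' @param path file path.
#' @param format `"esri_ascii"`, `"geotiff"`, or `"auto"` (by extension).
#' @return a [raster_grid()].
#' @export
read_raster <- function(path, format = c("auto", "esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(guess_format(path, format),
         esri_ascii = read_asc(path),
         geotiff = read_gtiff(path))
}

#' Write a raster layer
#'
#' ESRI ASCII files are written with an `xllcorner` header; GeoTIFF output is
#' single-band little-endian Float64 with WGS84 geokeys and a GDAL-style
#' nodata tag.
#'
#' @param grid a [raster_grid()].
#' @param path destination path.
#' @param format `"esri_ascii"`, `"geotiff"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = c("auto", "esri_ascii", "geotiff")) {
  stopifnot(inherits(grid, "raster_grid"))
  format <- match.arg(format)
  switch(guess_format(path, format),
         esri_ascii = write_asc(grid, path),
         geotiff = write_gtiff(grid, path))
  invisible(path)
}
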