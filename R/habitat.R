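# Habitat classification, area ledgers, and centroid-migration summaries.

#' Zoning scheme (class names and break values)
#'
#' Breaks are half-open on the left, `[b_i, b_{i+1})`, with the top class
#' closed at the upper bound. The default is the four-class habitat scheme:
#' non-suitable [0, 0.1), low [0.1, 0.3), moderate [0.3, 0.5), high [0.5, 1].
#'
#' @param breaks strictly increasing break values covering the value range.
#' @param names class names, one fewer than breaks.
#' @return object of class `zoning_scheme`.
#' @export
zoning_scheme <- function(breaks = c(0, 0.1, 0.3, 0.5, 1),
                          names = c("non", "low", "moderate", "high")) {
  stopifnot(all(diff(breaks) > 0), length(names) == length(breaks) - 1)
  structure(list(breaks = breaks, names = names), class = "zoning_scheme")
}

#' Reclassify a suitability surface into zones
#'
#' @param surface a [raster_grid()] with values inside the scheme's range.
#' @param scheme a [zoning_scheme()].
#' @return a `zoning_map`: [raster_grid()] of 1-based class indices with the
#'   scheme attached as attribute `"scheme"`.
#' @export
reclassify <- function(surface, scheme = zoning_scheme()) {
  v <- surface$values
  lo <- scheme$breaks[1]; hi <- scheme$breaks[length(scheme$breaks)]
  bad <- which(is.finite(v) & (v < lo - 1e-12 | v > hi + 1e-12))
  if (length(bad))
    stop(sprintf("value %g at cell %d is outside [%g, %g]",
                 v[bad[1]], bad[1], lo, hi))
  cls <- matrix(findInterval(v, scheme$breaks, rightmost.closed = TRUE),
                nrow(v), ncol(v))
  cls[!is.finite(v)] <- NA_integer_
  out <- raster_grid(surface$spec, cls)
  attr(out, "scheme") <- scheme
  class(out) <- c("zoning_map", class(out))
  out
}

#' Per-class area ledger of a zoning map
#'
#' Cell areas come from the spherical cell geometry; areas are expressed in
#' 1e4 km^2 as in the field's habitat tables. `total_suitable` sums every
#' class above the first (non-suitable) one.
#'
#' @param zones a `zoning_map` from [reclassify()].
#' @param scenario_tag label for the raster set (e.g. `"current"`).
#' @return object of class `area_report`: data.frame (class, cells,
#'   area_1e4km2, fraction) with attributes `total_suitable` and `scenario`.
#' @export
area_report <- function(zones, scenario_tag = "current") {
  scheme <- attr(zones, "scheme")
  stopifnot(!is.null(scheme))
  spec <- zones$spec
  areas <- matrix(row_areas_km2(spec), spec$n_rows, spec$n_cols)
  k <- length(scheme$names)
  cells <- integer(k); a <- numeric(k)
  for (i in seq_len(k)) {
    sel <- zones$values == i
    sel[is.na(sel)] <- FALSE
    cells[i] <- sum(sel)
    a[i] <- sum(areas[sel])
  }
  df <- data.frame(class = scheme$names, cells = cells,
                   area_1e4km2 = a / 1e4,
                   fraction = if (sum(cells) > 0) cells / sum(cells) else 0)
  structure(df, class = c("area_report", "data.frame"),
            total_suitable = sum(df$area_1e4km2[-1]),
            scenario = scenario_tag)
}

#' Sum class areas into a total suitable area
#'
#' Adds the per-class areas of every suitable class (the additivity used in
#' habitat tables: total = high + moderate + low).
#'
#' @param class_areas numeric vector of per-class areas (any consistent unit).
#' @return their sum.
#' @export
total_suitable_area <- function(class_areas) sum(as.numeric(class_areas))

#' Mean center of suitable habitat
#'
#' Area-weighted mean of cell-center coordinates over the cells at or above
#' the suitability threshold (`weighting = "binary"`), optionally further
#' weighted by the suitability value (`weighting = "suitability"`).
#'
#' @param surface a suitability [raster_grid()].
#' @param threshold membership threshold (default 0.1, the lower bound of the
#'   total suitable area).
#' @param weighting `"binary"` (default) or `"suitability"`.
#' @param scenario_tag label carried into the record.
#' @return object of class `centroid_record`: list with `lon`, `lat`,
#'   `threshold`, `weighting`, `scenario`.
#' @export
mean_center <- function(surface, threshold = 0.1,
                        weighting = c("binary", "suitability"),
                        scenario_tag = "current") {
  weighting <- match.arg(weighting)
  spec <- surface$spec
  v <- surface$values
  sel <- which(is.finite(v) & v >= threshold)
  if (!length(sel)) stop("no cells at or above the threshold")
  row <- ((sel - 1L) %% spec$n_rows) + 1L
  col <- ((sel - 1L) %/% spec$n_rows) + 1L
  cg <- cell_geometry(spec, row, col)
  w <- cg$area_km2
  if (weighting == "suitability") w <- w * v[sel]
  structure(list(lon = sum(w * cg$lon) / sum(w),
                 lat = sum(w * cg$lat) / sum(w),
                 threshold = threshold, weighting = weighting,
                 scenario = scenario_tag),
            class = "centroid_record")
}

#' @export
print.centroid_record <- function(x, ...) {
  cat(sprintf("centroid [%s]: %.2f E, %.2f N (p >= %g, %s weighting)\n",
              x$scenario, x$lon, x$lat, x$threshold, x$weighting))
  invisible(x)
}

#' Migration track between consecutive centroids
#'
#' Consecutive haversine distances (R = 6371.0088 km) and initial bearings.
#'
#' @param centroids either a list of `centroid_record`s or a data.frame with
#'   columns `scenario` (or `tag`), `lon`, `lat`, in chronological order.
#' @return data.frame with columns `from`, `to`, `distance_km`, `bearing_deg`.
#' @export
migration_track <- function(centroids) {
  if (is.data.frame(centroids)) {
    df <- centroids
    if (!"scenario" %in% names(df) && "tag" %in% names(df))
      df$scenario <- df$tag
  } else {
    df <- do.call(rbind, lapply(centroids, function(cc)
      data.frame(scenario = cc$scenario, lon = cc$lon, lat = cc$lat)))
  }
  stopifnot(nrow(df) >= 2)
  i <- seq_len(nrow(df) - 1)
  p1 <- cbind(df$lon[i], df$lat[i]); p2 <- cbind(df$lon[i + 1], df$lat[i + 1])
  data.frame(from = df$scenario[i], to = df$scenario[i + 1],
             distance_km = geosphere::distHaversine(p1, p2, r = .R_EARTH_KM),
             bearing_deg = (geosphere::bearing(p1, p2) + 360) %% 360)
}
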