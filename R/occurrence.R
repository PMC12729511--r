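# Occurrence ingestion, spatial rarefaction, and presence/background design
# assembly for the presence-background model.

haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .R_EARTH_KM)
}

#' Read occurrence records from CSV
#'
#' Requires `lon` and `lat` columns (a `species` column is carried through if
#' present). Rows whose coordinates do not parse as finite numbers are dropped
#' and counted in the `"report"` attribute.
#'
#' @param path CSV path.
#' @return An `occurrence_set`: list with `presences` (data.frame lon/lat),
#'   `provenance`, `thinning_radius_km` (NA until [rarefy()] is applied).
#' @export
read_occurrences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("occurrence CSV must have 'lon' and 'lat' columns")
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  ok <- is.finite(lon) & is.finite(lat)
  if (!any(ok)) stop("no records with parsable coordinates")
  occ <- occurrence_set(data.frame(lon = lon[ok], lat = lat[ok]),
                        provenance = if ("species" %in% names(df))
                          df$species[ok] else rep(basename(path), sum(ok)))
  attr(occ, "report") <- list(n_read = nrow(df), n_dropped = sum(!ok))
  occ
}

#' Construct an occurrence set
#'
#' @param presences data.frame with `lon`, `lat`.
#' @param provenance optional per-record source tags.
#' @param thinning_radius_km radius already enforced, or `NA`.
#' @return object of class `occurrence_set`.
#' @export
occurrence_set <- function(presences, provenance = NULL,
                           thinning_radius_km = NA_real_) {
  stopifnot(all(c("lon", "lat") %in% names(presences)),
            all(is.finite(presences$lon)), all(is.finite(presences$lat)))
  structure(list(presences = presences[c("lon", "lat")],
                 provenance = provenance,
                 thinning_radius_km = thinning_radius_km),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records", nrow(x$presences)))
  if (is.finite(x$thinning_radius_km))
    cat(sprintf(", rarefied at %g km", x$thinning_radius_km))
  cat("\n")
  invisible(x)
}

#' Spatially rarefy occurrence records
#'
#' Greedy sequential thinning: records are visited in a deterministic order
#' (sorted by lon then lat; or a seeded shuffle when `seed` is given) and a
#' record is kept iff its great-circle (haversine) distance to every
#' already-kept record is at least `radius_km`. The result satisfies: every
#' pairwise distance >= `radius_km`. Idempotent.
#'
#' @param occ an `occurrence_set`.
#' @param radius_km minimum pairwise distance to enforce (default 10 km).
#' @param seed optional seed for a random visit order; `NULL` (default) uses
#'   the sorted order.
#' @return a rarefied `occurrence_set`.
#' @export
rarefy <- function(occ, radius_km = 10, seed = NULL) {
  stopifnot(inherits(occ, "occurrence_set"), nrow(occ$presences) >= 1)
  p <- occ$presences
  ord <- if (is.null(seed)) {
    order(p$lon, p$lat)
  } else {
    set.seed(seed); sample.int(nrow(p))
  }
  p <- p[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(p))) {
    if (length(keep) == 0L ||
        all(haversine_km(p$lon[i], p$lat[i],
                         p$lon[keep], p$lat[keep]) >= radius_km)) {
      keep <- c(keep, i)
    }
  }
  out <- occurrence_set(p[keep, , drop = FALSE],
                        provenance = occ$provenance[ord][keep],
                        thinning_radius_km = radius_km)
  rownames(out$presences) <- NULL
  out
}

#' Assemble the presence/background design table
#'
#' Background cells are sampled uniformly without replacement from the
#' non-nodata cells of the stack (all of them if fewer than `background_n`).
#' Presence rows are extractions at the presence coordinates; duplicate
#' presence cells are collapsed to one row. Rows with any missing extraction
#' are dropped and counted.
#'
#' @param occ an `occurrence_set` (or data.frame with lon/lat).
#' @param stack a [raster_stack()].
#' @param background_n maximum number of background cells (default 10000).
#' @param seed integer seed for the background sample.
#' @return A `design_table`: data.frame with `label` (1 presence, 0
#'   background), `lon`, `lat`, and one column per layer; attribute `report`
#'   counts dropped rows and collapsed duplicates.
#' @export
assemble_design <- function(occ, stack, background_n = 10000, seed = 1L) {
  pres <- if (inherits(occ, "occurrence_set")) occ$presences else occ
  stopifnot(inherits(stack, "raster_stack"), background_n >= 1)
  spec <- stack$spec

  rc <- point_to_cell(spec, pres$lon, pres$lat)
  cell <- rc$row + (rc$col - 1L) * spec$n_rows
  dup <- duplicated(cell) & !is.na(cell)
  pres <- pres[!dup, , drop = FALSE]
  pvals <- extract_at_points(stack, pres)
  pok <- complete.cases(pvals)
  if (!any(pok)) stop("no presence rows survive extraction")

  first <- stack$layers[[1]]$values
  valid <- which(Reduce(`&`, lapply(stack$layers,
                                    function(g) is.finite(g$values))))
  set.seed(seed)
  bidx <- if (length(valid) > background_n)
    sort(sample(valid, background_n)) else valid
  brow <- ((bidx - 1L) %% spec$n_rows) + 1L
  bcol <- ((bidx - 1L) %/% spec$n_rows) + 1L
  bg <- cell_geometry(spec, brow, bcol)[c("lon", "lat")]
  bvals <- as.data.frame(lapply(stack$layers, function(g) g$values[bidx]))
  names(bvals) <- names(stack$layers)

  design <- rbind(
    cbind(data.frame(label = 1, lon = pres$lon[pok], lat = pres$lat[pok]),
          pvals[pok, , drop = FALSE]),
    cbind(data.frame(label = 0, lon = bg$lon, lat = bg$lat), bvals))
  rownames(design) <- NULL
  if (sum(design$label == 1) < 2)
    stop("need at least 2 presence rows after extraction")
  structure(design, class = c("design_table", "data.frame"),
            report = list(n_presence_dropped = sum(!pok),
                          n_duplicates_collapsed = sum(dup),
                          background_n = nrow(bvals)))
}

design_vars <- function(design) {
  setdiff(names(design), c("label", "lon", "lat"))
}
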