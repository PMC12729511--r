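# Fusion of ecological and quality suitability into the integrated quality
# index, and its Fisher-Jenks natural-breaks classification.

#' Min-max normalize a raster to [0, 1]
#'
#' `(z - min)/(max - min)` over the masked (finite) cells; nodata preserved.
#' Affine transforms of the input give identical output.
#'
#' @param grid a [raster_grid()].
#' @param mask optional logical matrix restricting the min/max computation.
#' @return a [raster_grid()] in `[0, 1]`.
#' @export
normalize01 <- function(grid, mask = NULL) {
  v <- grid$values
  sel <- is.finite(v)
  if (!is.null(mask)) sel <- sel & mask
  r <- range(v[sel])
  if (!is.finite(r[1]) || r[2] <= r[1])
    stop("degenerate value range: need at least 2 distinct finite values")
  out <- (v - r[1]) / (r[2] - r[1])
  out[!is.finite(v)] <- NA_real_
  raster_grid(grid$spec, out)
}

#' Fuse normalized compound surfaces into one quality layer
#'
#' @param grids named list of co-registered [raster_grid()]s in `[0, 1]`.
#' @param rule `"mean"` (default), `"min"`, or `"wmean"`.
#' @param weights weights for `rule = "wmean"` (recycled, normalized).
#' @return a [raster_grid()] in `[0, 1]`; nodata propagates.
#' @export
fuse_quality <- function(grids, rule = c("mean", "min", "wmean"),
                         weights = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(grids) >= 1)
  spec <- grids[[1]]$spec
  for (g in grids) if (!same_spec(spec, g$spec))
    stop("quality grids are not co-registered")
  arr <- vapply(grids, function(g) g$values, grids[[1]]$values)
  dim(arr) <- c(spec$n_rows * spec$n_cols, length(grids))
  out <- switch(rule,
    mean = rowMeans(arr),
    min = do.call(pmin, as.data.frame(arr)),
    wmean = {
      w <- rep_len(if (is.null(weights)) 1 else weights, length(grids))
      as.vector(arr %*% (w / sum(w)))
    })
  raster_grid(spec, matrix(out, spec$n_rows, spec$n_cols))
}

#' Integrated quality index: weighted fusion of ecological and quality layers
#'
#' `C = w_e E + w_q Q` per cell, with `w_e + w_q = 1` (equal weights by
#' default). Nodata in either input propagates.
#'
#' @param E ecological suitability [raster_grid()] in `[0, 1]`.
#' @param Q quality suitability [raster_grid()] in `[0, 1]`.
#' @param w_e,w_q nonnegative weights summing to 1 (default 0.5 each).
#' @return a [raster_grid()] (the integrated index) with the config attached
#'   as attribute `"config"`.
#' @export
integrate_layers <- function(E, Q, w_e = 0.5, w_q = 0.5) {
  if (w_e < 0 || w_q < 0 || abs(w_e + w_q - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1")
  if (!same_spec(E$spec, Q$spec)) stop("E and Q are not co-registered")
  both <- c(E$values[is.finite(E$values)], Q$values[is.finite(Q$values)])
  if (length(both) && (min(both) < -1e-9 || max(both) > 1 + 1e-9))
    stop("E and Q must lie in [0, 1]")
  out <- raster_grid(E$spec, w_e * E$values + w_q * Q$values)
  attr(out, "config") <- list(w_e = w_e, w_q = w_q)
  out
}

#' Fisher-Jenks natural breaks
#'
#' Exact dynamic program minimizing the total within-class sum of squared
#' deviations over contiguous classes of the sorted values; ties between
#' optimal partitions are broken toward the smaller first-class size. When
#' more than `max_n` finite values are supplied, a seeded subsample of that
#' size is classified and its breaks applied to all values.
#'
#' @param values numeric vector (non-finite entries ignored).
#' @param k number of classes (>= 2 distinct values per class required).
#' @param max_n dynamic-program size cap (default 10000).
#' @param seed subsampling seed (default 1).
#' @return object of class `jenks_breaks`: list with `k`, `breaks` (length
#'   `k + 1`, first = min, last = max; class i is `(b_i, b_{i+1}]`, lowest
#'   closed), `ssd`.
#' @export
jenks_breaks <- function(values, k, max_n = 10000, seed = 1L) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < k)
    stop("need at least k distinct finite values")
  sub <- FALSE
  if (length(v) > max_n) {
    set.seed(seed)
    v <- sample(v, max_n)
    sub <- TRUE
  }
  x <- sort(v)
  starts <- .jenks_dp(x, as.integer(k))
  ssd <- attr(starts, "ssd")
  # break values: upper data value of each class (classInt convention)
  uppers <- x[c(starts[-1] - 1L, length(x))]
  br <- c(x[1], uppers)
  structure(list(k = k, breaks = br, ssd = ssd, n_used = length(x),
                 subsampled = sub),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat(sprintf("Fisher-Jenks breaks (k = %d, within-class SSD %.6g%s):\n",
              x$k, x$ssd, if (x$subsampled) ", subsampled" else ""))
  cat(" ", paste(sprintf("%.4g", x$breaks), collapse = " | "), "\n")
  invisible(x)
}

# class index of values under jenks breaks: (b_i, b_{i+1}], lowest class
# absorbs anything <= b_1 (values outside the fitted range clamp to the ends)
jenks_classify <- function(values, jb) {
  inner <- jb$breaks[-c(1, length(jb$breaks))]
  # a value exactly equal to an upper bound belongs to the lower class
  cls <- findInterval(values, inner, left.open = TRUE) + 1L
  cls[!is.finite(values)] <- NA_integer_
  pmin(cls, jb$k)
}

#' Classify an integrated index into quality zones
#'
#' Applies Fisher-Jenks breaks (computed from the index itself when `breaks`
#' is not supplied) and returns the zoning map plus its area ledger. The top
#' class is labeled the core quality region.
#'
#' @param index an integrated-index [raster_grid()] (from
#'   [integrate_layers()]).
#' @param k number of classes when breaks are computed (default 4).
#' @param breaks an existing [jenks_breaks()] object, or `NULL`.
#' @param scenario_tag ledger label.
#' @param ... forwarded to [jenks_breaks()].
#' @return list with `zones` (a `zoning_map`), `areas` (an [area_report()]),
#'   and `breaks`.
#' @export
classify_index <- function(index, k = 4, breaks = NULL,
                           scenario_tag = "integrated", ...) {
  if (is.null(breaks)) breaks <- jenks_breaks(index$values, k, ...)
  k <- breaks$k
  cls <- matrix(jenks_classify(as.vector(index$values), breaks),
                index$spec$n_rows, index$spec$n_cols)
  zones <- raster_grid(index$spec, cls)
  nm <- paste0("Q", seq_len(k))
  nm[k] <- "core"
  scheme <- structure(list(breaks = breaks$breaks, names = nm),
                      class = "zoning_scheme")
  attr(zones, "scheme") <- scheme
  class(zones) <- c("zoning_map", class(zones))
  areas <- area_report(zones, scenario_tag)
  # every class of the integrated scheme counts toward the ledger; total over
  # all classes rather than dropping the first
  attr(areas, "total_suitable") <- sum(areas$area_1e4km2)
  list(zones = zones, areas = areas, breaks = breaks)
}
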