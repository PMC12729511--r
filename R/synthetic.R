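# Synthetic landscapes with known truth: autocorrelated environmental layers,
# a known suitability law, occurrences sampled from it, and compound
# concentrations coupled to two named covariates. Everything is deterministic
# under (scenario, seed).

# unit-sill variogram families, h in range units (gamma(1) ~ sill for exp/gau
# via the practical-range convention used throughout the package)
unit_variogram <- function(family) {
  switch(family,
    spherical = function(h) ifelse(h < 1, 1.5 * h - 0.5 * h^3, 1),
    exponential = function(h) 1 - exp(-3 * h),
    gaussian = function(h) 1 - exp(-3 * h^2),
    stop("unknown variogram family '", family, "'"))
}

#' Define a synthetic scenario
#'
#' A scenario fixes the grid, the environmental layers (deterministic lon/lat
#' gradient plus a stationary Gaussian random field with a stated variogram),
#' the true suitability law (logistic in z-scored layers, linear and squared
#' terms), the number of presences to sample, and the compound sampling design
#' (two coupled covariates plus spatially correlated residual and nugget
#' noise). The defaults mirror the study design at desk scale: a 120 x 120
#' grid, 8 layers of which 5 are informative and 3 are near-duplicates
#' (pairwise r >= 0.9) to exercise collinearity pruning, 170 presences, and 26
#' compound sites.
#'
#' @param spec a [grid_spec()]; default 120 x 120 cells of 0.15 degrees over
#'   a subtropical window (lon 100-118, lat 17-35).
#' @param env_defs list of layer definitions; each a list with `code`,
#'   `family`, `sill`, `range` (cells), `nugget`, `grad_lon`, `grad_lat`,
#'   `base`, and optionally `copy_of`/`copy_sd` for a collinear duplicate.
#' @param truth_coeffs named numeric vector; names are layer codes or
#'   `"code^2"` for squared terms, values coefficients on z-scored layers;
#'   `"(Intercept)"` allowed.
#' @param occurrence_n presences to draw (default 170).
#' @param compound_defs per-compound list: `intercept`, `beta1`, `beta2`
#'   (coefficients on z-scored covariate 1 and 2), `resid_sill`, `resid_range`
#'   (cells), `resid_family`, `nugget_sd` (site measurement noise, mg/g).
#' @param cov1,cov2 codes of the two coupled covariates (a precipitation-like
#'   and an aspect-like layer).
#' @param sample_n number of compound sites (default 26).
#' @param seed integer seed; every generator call derives its stream from it.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(spec = NULL, env_defs = NULL,
                               truth_coeffs = NULL, occurrence_n = 170,
                               compound_defs = NULL,
                               cov1 = "bio18", cov2 = "aspect",
                               sample_n = 26, seed = 20251L) {
  if (is.null(spec))
    spec <- grid_spec(120, 120, x_min = 100, y_max = 35, dx = 0.15)
  if (is.null(env_defs)) env_defs <- default_env_defs()
  if (is.null(truth_coeffs))
    truth_coeffs <- c("(Intercept)" = -6, bio18 = 4, aspect = 4,
                      bio12 = 2, bio06 = 1.5, "bio17^2" = -1.5)
  if (is.null(compound_defs))
    compound_defs <- list(
      quercetin = list(intercept = 3.0, beta1 = 0.9, beta2 = 0.8,
                        resid_sill = 0.10, resid_range = 15,
                        resid_family = "exponential", nugget_sd = 0.15),
      kaempferol = list(intercept = 2.2, beta1 = 0.8, beta2 = 0.8,
                         resid_sill = 0.10, resid_range = 15,
                         resid_family = "exponential", nugget_sd = 0.15))
  stopifnot(occurrence_n >= 10, sample_n >= 4)
  for (d in env_defs)
    stopifnot(d$sill >= 0, d$nugget >= 0, is.null(d$range) || d$range >= 0)
  structure(list(spec = spec, env_defs = env_defs,
                 truth_coeffs = truth_coeffs,
                 occurrence_n = as.integer(occurrence_n),
                 compound_defs = compound_defs,
                 cov1 = cov1, cov2 = cov2,
                 sample_n = as.integer(sample_n), seed = as.integer(seed)),
            class = "synthetic_scenario")
}

default_env_defs <- function() {
  list(
    list(code = "bio06", family = "exponential", sill = 0.5, range = 20,
         nugget = 0, grad_lon = 0.2, grad_lat = 1.0, base = 0),
    list(code = "bio12", family = "exponential", sill = 0.5, range = 20,
         nugget = 0, grad_lon = 0.7, grad_lat = 0.7, base = 0),
    list(code = "bio17", family = "exponential", sill = 0.5, range = 20,
         nugget = 0, grad_lon = -0.8, grad_lat = 0.4, base = 0),
    list(code = "bio18", family = "exponential", sill = 0.4, range = 18,
         nugget = 0, grad_lon = 1.0, grad_lat = 0.2, base = 0),
    list(code = "aspect", family = "exponential", sill = 0.4, range = 18,
         nugget = 0, grad_lon = 0.2, grad_lat = 1.0, base = 0),
    # near-duplicates: informative layer + small independent field
    list(code = "nuis1", copy_of = "bio06", copy_sd = 0.25),
    list(code = "nuis2", copy_of = "bio12", copy_sd = 0.25),
    list(code = "nuis3", copy_of = "bio17", copy_sd = 0.25))
}

# Stationary Gaussian random field on the cell lattice by circulant embedding
# on the torus: exact stationarity, O(n log n). `range` in cell units.
gen_grf <- function(n_rows, n_cols, family, sill, range_cells) {
  if (sill <= 0 || range_cells <= 0)
    return(matrix(0, n_rows, n_cols))
  g <- unit_variogram(family)
  di <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dj <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  h <- sqrt(outer(di^2, dj^2, "+")) / range_cells
  C <- sill * (1 - g(h))                      # covariance on the torus
  lam <- Re(fft(C))
  if (min(lam) < -1e-6 * max(lam))
    stop("non-positive-definite covariance embedding for this variogram")
  lam <- pmax(lam, 0)
  N <- n_rows * n_cols
  eps <- matrix(complex(real = rnorm(N), imaginary = rnorm(N)),
                n_rows, n_cols)
  # with complex standard-normal eps, Re(F* (sqrt(lam) eps)) has covariance
  # N * C, hence the 1/sqrt(N) normalization
  Re(fft(sqrt(lam) * eps, inverse = TRUE)) / sqrt(N)
}

# normalized lon/lat in [-1, 1] across the grid, as matrices
grid_uv <- function(spec) {
  u <- (col_lons(spec) - mean(col_lons(spec))) / (diff(range(col_lons(spec))) / 2)
  v <- (row_lats(spec) - mean(row_lats(spec))) / (diff(range(row_lats(spec))) / 2)
  list(u = matrix(u, spec$n_rows, spec$n_cols, byrow = TRUE),
       v = matrix(v, spec$n_rows, spec$n_cols))
}

#' Generate the environmental layer stack of a scenario
#'
#' Each layer is a deterministic linear gradient in lon/lat plus a stationary
#' Gaussian random field with the stated variogram (circulant embedding on the
#' torus; ranges in cell units) plus iid nugget noise. `copy_of` layers are a
#' named layer plus independent noise, producing the collinear nuisance
#' variables of the default design.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [raster_stack()].
#' @export
gen_env_stack <- function(scenario) {
  spec <- scenario$spec
  set.seed(scenario$seed)
  uv <- grid_uv(spec)
  layers <- list()
  for (d in scenario$env_defs) {
    if (!is.null(d$copy_of)) {
      src <- layers[[d$copy_of]]
      if (is.null(src)) stop("copy_of references unknown layer '", d$copy_of,
                             "' (generation error in layer '", d$code, "')")
      m <- src$values + matrix(rnorm(spec$n_rows * spec$n_cols, sd = d$copy_sd),
                               spec$n_rows, spec$n_cols)
    } else {
      m <- d$base + d$grad_lon * uv$u + d$grad_lat * uv$v +
        gen_grf(spec$n_rows, spec$n_cols, d$family, d$sill, d$range)
      if (d$nugget > 0)
        m <- m + matrix(rnorm(spec$n_rows * spec$n_cols, sd = sqrt(d$nugget)),
                        spec$n_rows, spec$n_cols)
    }
    layers[[d$code]] <- raster_grid(spec, m)
  }
  raster_stack(layers)
}

# z-score a layer over its finite cells
zscore_mat <- function(m) {
  mu <- mean(m, na.rm = TRUE); s <- sd(as.vector(m), na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- 1
  (m - mu) / s
}

#' True suitability surface from a coefficient law
#'
#' Logistic transform of a linear predictor in z-scored layers; term names are
#' layer codes (linear) or `"code^2"` (squared), plus `"(Intercept)"`.
#'
#' @param env a [raster_stack()].
#' @param truth_coeffs named numeric vector of coefficients.
#' @return a [raster_grid()] with values in (0, 1).
#' @export
gen_true_suitability <- function(env, truth_coeffs) {
  spec <- env$spec
  eta <- matrix(0, spec$n_rows, spec$n_cols)
  for (nm in names(truth_coeffs)) {
    b <- truth_coeffs[[nm]]
    if (nm == "(Intercept)") { eta <- eta + b; next }
    sq <- grepl("\\^2$", nm)
    code <- sub("\\^2$", "", nm)
    if (is.null(env$layers[[code]]))
      stop("truth coefficient references unknown layer '", code, "'")
    z <- zscore_mat(env$layers[[code]]$values)
    eta <- eta + b * (if (sq) z^2 else z)
  }
  raster_grid(spec, 1 / (1 + exp(-eta)))
}

#' Sample presence cells proportional to true suitability
#'
#' Cells are drawn without replacement with probability proportional to the
#' truth surface; returned coordinates are cell centers.
#'
#' @param truth a [raster_grid()] with values in `[0, 1]`.
#' @param n number of presences.
#' @param seed integer seed.
#' @return data.frame with columns `lon`, `lat`.
#' @export
sample_occurrences <- function(truth, n, seed) {
  stopifnot(inherits(truth, "raster_grid"))
  v <- as.vector(truth$values)
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("truth surface must lie in [0, 1]")
  ok <- which(is.finite(v) & v > 0)
  n <- as.integer(n)
  if (n == 0L) return(data.frame(lon = numeric(0), lat = numeric(0)))
  if (length(ok) < n) {
    warning("only ", length(ok), " cells with positive truth; returning all")
    n <- length(ok)
  }
  set.seed(seed)
  idx <- ok[sample.int(length(ok), size = n, replace = FALSE, prob = v[ok])]
  spec <- truth$spec
  row <- ((idx - 1L) %% spec$n_rows) + 1L
  col <- ((idx - 1L) %/% spec$n_rows) + 1L
  cg <- cell_geometry(spec, row, col)
  data.frame(lon = cg$lon, lat = cg$lat)
}

#' Generate compound concentration truth and site samples
#'
#' The concentration surface of each compound is
#' `intercept + beta1 z(cov1) + beta2 z(cov2) + spatially correlated residual`,
#' truncated at zero. Site samples are taken at `sample_n` random non-nodata
#' cells and carry additional iid nugget noise (again truncated at zero).
#'
#' @param scenario a [synthetic_scenario()].
#' @param env the scenario's [raster_stack()].
#' @return list with `truth` (named list of [raster_grid()]) and `samples`
#'   (data.frame: lon, lat, one column per compound).
#' @export
gen_compound_samples <- function(scenario, env) {
  spec <- env$spec
  for (cv in c(scenario$cov1, scenario$cov2))
    if (is.null(env$layers[[cv]]))
      stop("covariate layer '", cv, "' not found in the stack")
  z1 <- zscore_mat(env$layers[[scenario$cov1]]$values)
  z2 <- zscore_mat(env$layers[[scenario$cov2]]$values)
  set.seed(scenario$seed + 1L)
  valid <- which(is.finite(z1) & is.finite(z2))
  sites <- sample(valid, scenario$sample_n)
  row <- ((sites - 1L) %% spec$n_rows) + 1L
  col <- ((sites - 1L) %/% spec$n_rows) + 1L
  cg <- cell_geometry(spec, row, col)
  samples <- data.frame(lon = cg$lon, lat = cg$lat)
  truth <- list()
  for (nm in names(scenario$compound_defs)) {
    d <- scenario$compound_defs[[nm]]
    resid <- gen_grf(spec$n_rows, spec$n_cols, d$resid_family, d$resid_sill,
                     d$resid_range)
    conc <- pmax(d$intercept + d$beta1 * z1 + d$beta2 * z2 + resid, 0)
    truth[[nm]] <- raster_grid(spec, conc)
    obs <- conc[sites] + rnorm(length(sites), sd = d$nugget_sd)
    samples[[nm]] <- pmax(obs, 0)
  }
  list(truth = truth, samples = samples)
}

#' Generate the full truth bundle for a scenario
#'
#' @param scenario a [synthetic_scenario()].
#' @return list of class `truth_bundle`: `scenario`, `env`, `true_suitability`,
#'   `presences`, `compound_truth`, `compound_samples`.
#' @export
gen_truth_bundle <- function(scenario) {
  env <- gen_env_stack(scenario)
  truth <- gen_true_suitability(env, scenario$truth_coeffs)
  pres <- sample_occurrences(truth, scenario$occurrence_n,
                             seed = scenario$seed + 2L)
  comp <- gen_compound_samples(scenario, env)
  structure(list(scenario = scenario, env = env, true_suitability = truth,
                 presences = pres, compound_truth = comp$truth,
                 compound_samples = comp$samples),
            class = "truth_bundle")
}

#' Write a truth bundle to a directory
#'
#' Rasters as ESRI ASCII, tables as CSV, truth parameters as JSON; returns a
#' manifest of all paths.
#'
#' @param bundle a `truth_bundle` from [gen_truth_bundle()].
#' @param dir destination directory (created if needed).
#' @return named list of written paths, invisibly classed `bundle_manifest`.
#' @export
write_scenario_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "truth_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (nm in names(bundle$env$layers)) {
    p <- file.path(dir, paste0("env_", nm, ".asc"))
    write_raster(bundle$env$layers[[nm]], p)
    paths[[paste0("env_", nm)]] <- p
  }
  p <- file.path(dir, "true_suitability.asc")
  write_raster(bundle$true_suitability, p); paths$true_suitability <- p
  for (nm in names(bundle$compound_truth)) {
    p <- file.path(dir, paste0("truth_", nm, ".asc"))
    write_raster(bundle$compound_truth[[nm]], p)
    paths[[paste0("truth_", nm)]] <- p
  }
  p <- file.path(dir, "occurrences.csv")
  write.csv(bundle$presences, p, row.names = FALSE); paths$occurrences <- p
  p <- file.path(dir, "compound_samples.csv")
  write.csv(bundle$compound_samples, p, row.names = FALSE)
  paths$compound_samples <- p
  meta <- bundle$scenario
  meta$spec <- unclass(meta$spec)
  p <- file.path(dir, "scenario.json")
  jsonlite::write_json(unclass(meta), p, auto_unbox = TRUE, digits = NA)
  paths$scenario <- p
  invisible(structure(paths, class = "bundle_manifest"))
}
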