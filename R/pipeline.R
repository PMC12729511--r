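# Configuration-driven orchestration of the full analysis:
# simulate -> thin -> select -> fit -> cv -> project -> classify -> centroid
# -> screen -> krige -> integrate, with a machine-readable run manifest.

#' Default run configuration
#'
#' All stage parameters mirror the module defaults: 10 km thinning, 10000
#' background cells, LQH features with regularization multiplier 1 and
#' convergence threshold 1e-5, 10-fold cross-validation, habitat breaks
#' 0.1/0.3/0.5, centroid threshold 0.1 (binary, area-weighted), Spearman
#' alpha 0.05, spherical variograms, equal fusion weights, 4 Jenks classes.
#' A synthetic scenario is declared as the input unless explicit paths are
#' given.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param out_dir artifact directory (default: a fresh temporary directory).
#' @param ... overrides for any configuration entry.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("iqzone_run_"),
                               ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    scenario = NULL,                 # synthetic_scenario or NULL
    occurrences_csv = NULL,          # used instead of the scenario if set
    raster_dir = NULL,
    compounds_csv = NULL,
    compounds = c("quercetin", "kaempferol"),
    thinning_radius_km = 10,
    background_n = 10000,
    feature_classes = c("L", "Q", "H"),
    hinge_knots = 10,
    rm = 1,
    tol = 1e-5,
    max_cycles = 500,
    cv_folds = 10,
    r_threshold = 0.8,
    vif_threshold = 10,
    habitat_breaks = c(0, 0.1, 0.3, 0.5, 1),
    centroid_threshold = 0.1,
    centroid_weighting = "binary",
    alpha = 0.05,
    variogram_family = "spherical",
    w_e = 0.5, w_q = 0.5,
    fusion_rule = "mean",
    jenks_k = 4)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Keys mirror [default_run_config()]; missing keys take their defaults.
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  vals <- yaml::read_yaml(path)
  do.call(default_run_config,
          c(list(seed = if (is.null(vals$seed)) 1L else vals$seed),
            vals[setdiff(names(vals), "seed")]))
}

#' Validate a run configuration
#'
#' Checks every stage precondition and lists violations with the module they
#' come from.
#'
#' @param config a `run_config`.
#' @return object of class `config_report`: list with `valid` and
#'   `violations` (character).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(cond, msg) if (isTRUE(cond)) v <<- c(v, msg)
  add(config$thinning_radius_km < 0,
      "occurrence_prep: thinning radius must be >= 0")
  add(config$background_n < 1, "occurrence_prep: background_n must be >= 1")
  add(config$rm < 0, "maxent_sdm: regularization multiplier must be >= 0")
  add(config$cv_folds < 2, "maxent_sdm: cv_folds must be >= 2")
  add(!all(diff(config$habitat_breaks) > 0),
      "habitat_dynamics: breaks must be strictly increasing")
  add(config$centroid_threshold < 0 || config$centroid_threshold > 1,
      "habitat_dynamics: centroid threshold must be in [0, 1]")
  add(config$alpha <= 0 || config$alpha >= 1,
      "quality_geostat: alpha must be in (0, 1)")
  add(!config$variogram_family %in% c("spherical", "exponential", "gaussian"),
      "quality_geostat: unknown variogram family")
  add(config$w_e < 0 || config$w_q < 0 ||
        abs(config$w_e + config$w_q - 1) > 1e-9,
      "integration_zoning: weights must be nonnegative and sum to 1")
  add(config$jenks_k < 2, "integration_zoning: jenks_k must be >= 2")
  add(is.null(config$scenario) && is.null(config$occurrences_csv),
      "cli_pipeline: either a synthetic scenario or input paths are required")
  structure(list(valid = length(v) == 0, violations = v),
            class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  if (x$valid) cat("configuration valid\n")
  else cat("configuration violations:\n",
           paste0("  - ", x$violations, collapse = "\n"), "\n")
  invisible(x)
}

# fixed per-stage seed derivation from the global seed (kept below 2^31)
stage_seed <- function(seed, stage_index) {
  (as.integer(seed) * 97L + stage_index * 1009L) %% 2147483647L
}

#' Run the full integrated-quality-region pipeline
#'
#' Executes the stages in order, writes every intermediate artifact under the
#' configured output directory, and returns a manifest (also written as JSON)
#' listing each stage's parameters, outputs with MD5 hashes, and warnings.
#' Quality stages are skipped when no compound table is available.
#'
#' @param config a `run_config` from [default_run_config()] /
#'   [read_run_config()].
#' @return the manifest, invisibly; also written to
#'   `file.path(config$out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config) {
  rep_cfg <- validate_config(config)
  if (!rep_cfg$valid)
    stop("invalid configuration:\n", paste(rep_cfg$violations, collapse = "\n"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  warnings_log <- character(0)
  t0 <- proc.time()[["elapsed"]]
  note <- function(stage, params, outputs) {
    hashes <- if (length(outputs))
      as.list(tools::md5sum(unlist(outputs))) else list()
    manifest$stages[[stage]] <<- list(
      stage = stage, params = params,
      outputs = hashes,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  }
  wcatch <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  save_raster <- function(grid, name) {
    p <- file.path(config$out_dir, paste0(name, ".asc"))
    write_raster(grid, p); p
  }
  save_csv <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE); p
  }

  # 1. simulate or load inputs
  if (!is.null(config$scenario)) {
    scen <- config$scenario
    scen$seed <- stage_seed(config$seed, 1L)
    bundle <- wcatch(gen_truth_bundle(scen))
    stack <- bundle$env
    occ <- occurrence_set(bundle$presences)
    compounds_tab <- bundle$compound_samples
    note("simulate", list(seed = scen$seed,
                          grid = c(scen$spec$n_rows, scen$spec$n_cols)),
         list(occ = save_csv(bundle$presences, "occurrences"),
              comp = save_csv(compounds_tab, "compound_samples")))
  } else {
    occ <- read_occurrences(config$occurrences_csv)
    files <- list.files(config$raster_dir, pattern = "\\.(asc|tif|tiff)$",
                        full.names = TRUE)
    layers <- lapply(files, read_raster)
    names(layers) <- tools::file_path_sans_ext(basename(files))
    stack <- raster_stack(layers)
    compounds_tab <- if (!is.null(config$compounds_csv))
      read.csv(config$compounds_csv) else NULL
    note("load", list(occurrences = config$occurrences_csv,
                      rasters = length(layers)), list())
  }

  # 2. thin
  occ <- wcatch(rarefy(occ, radius_km = config$thinning_radius_km))
  note("thin", list(radius_km = config$thinning_radius_km,
                    n_kept = nrow(occ$presences)),
       list(thinned = save_csv(occ$presences, "occurrences_thinned")))

  # 3. design + variable selection
  design <- wcatch(assemble_design(occ, stack,
                                   background_n = config$background_n,
                                   seed = stage_seed(config$seed, 3L)))
  sel <- wcatch(select_variables(design, r_threshold = config$r_threshold,
                                 vif_threshold = config$vif_threshold,
                                 classes = config$feature_classes,
                                 hinge_knots = config$hinge_knots,
                                 rm = config$rm, tol = config$tol,
                                 max_cycles = config$max_cycles))
  note("select_vars", list(r_threshold = config$r_threshold,
                           vif_threshold = config$vif_threshold,
                           final = sel$final_vars),
       list(vifs = save_csv(data.frame(var = names(sel$final_vifs),
                                       vif = as.numeric(sel$final_vifs)),
                            "final_vifs")))

  # 4. fit
  keep <- c("label", "lon", "lat", sel$final_vars)
  design2 <- structure(design[keep], class = class(design),
                       report = attr(design, "report"))
  fit <- wcatch(maxent(design2, vars = sel$final_vars,
                       classes = config$feature_classes,
                       hinge_knots = config$hinge_knots, rm = config$rm,
                       tol = config$tol, max_cycles = config$max_cycles))
  note("fit_sdm", list(rm = config$rm, features = length(fit$lambda),
                       gain = fit$gain, entropy = fit$entropy), list())

  # 5. cross-validate
  cv <- wcatch(evaluate_cv(design2, k = config$cv_folds,
                           seed = stage_seed(config$seed, 5L),
                           classes = config$feature_classes,
                           hinge_knots = config$hinge_knots, rm = config$rm,
                           tol = config$tol, max_cycles = config$max_cycles))
  note("cv", list(k = config$cv_folds, mean_auc = cv$mean_auc),
       list(cv = save_csv(data.frame(fold = seq_along(cv$fold_auc),
                                     auc = cv$fold_auc), "cv_auc")))

  # 6. project
  suit <- wcatch(project_to_raster(fit, stack))
  note("project", list(), list(suitability = save_raster(suit, "suitability")))

  # 7. classify habitat + areas
  scheme <- zoning_scheme(config$habitat_breaks,
                          c("non", "low", "moderate", "high"))
  zones <- wcatch(reclassify(suit, scheme))
  areas <- area_report(zones, "current")
  note("classify", list(breaks = config$habitat_breaks,
                        total_suitable_1e4km2 = attr(areas, "total_suitable")),
       list(zones = save_raster(zones, "habitat_zones"),
            areas = save_csv(as.data.frame(areas), "habitat_areas")))

  # 8. centroid
  cen <- wcatch(mean_center(suit, threshold = config$centroid_threshold,
                            weighting = config$centroid_weighting,
                            scenario_tag = "current"))
  note("centroid", list(threshold = config$centroid_threshold,
                        weighting = config$centroid_weighting,
                        lon = cen$lon, lat = cen$lat), list())

  # 9-11. quality stages
  if (!is.null(compounds_tab)) {
    ext <- extract_at_points(stack, compounds_tab)
    samp <- cbind(compounds_tab, ext)
    screen <- wcatch(spearman_screen(samp, config$compounds,
                                     names(stack$layers),
                                     alpha = config$alpha))
    note("screen", list(alpha = config$alpha,
                        selected = attr(screen, "selected")),
         list(screen = save_csv(as.data.frame(screen), "spearman_screen")))

    qgrids <- list()
    loo <- list()
    for (cmp in config$compounds) {
      sec <- attr(screen, "selected")[[cmp]]
      lmc <- wcatch(fit_lmc(samp, cmp, sec,
                            family = config$variogram_family))
      kg <- wcatch(cokrige_grid(lmc, samp, stack$spec,
                                secondaries_stack = stack))
      loo[[cmp]] <- wcatch(loo_validate(lmc, samp))
      qgrids[[cmp]] <- wcatch(normalize01(kg$prediction))
      note(paste0("krige_", cmp),
           list(secondaries = sec, range_km = lmc$range_km,
                me = loo[[cmp]]$me, rmse = loo[[cmp]]$rmse,
                nrmse = loo[[cmp]]$nrmse),
           list(pred = save_raster(kg$prediction, paste0("kriged_", cmp)),
                se = save_raster(kg$se, paste0("kriged_", cmp, "_se"))))
    }

    Q <- wcatch(fuse_quality(qgrids, rule = config$fusion_rule))
    C <- wcatch(integrate_layers(suit, Q, config$w_e, config$w_q))
    zi <- wcatch(classify_index(C, k = config$jenks_k,
                                seed = stage_seed(config$seed, 11L)))
    note("integrate", list(w_e = config$w_e, w_q = config$w_q,
                           rule = config$fusion_rule, jenks_k = config$jenks_k,
                           breaks = zi$breaks$breaks),
         list(index = save_raster(C, "integrated_index"),
              zones = save_raster(zi$zones, "quality_zones"),
              areas = save_csv(as.data.frame(zi$areas), "quality_areas")))
  } else {
    manifest$stages$integrate <- list(stage = "integrate", skipped = TRUE)
  }

  manifest$warnings <- warnings_log
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
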