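maxent_toy_design <- function() {
  # 3-cell universe with one variable; presences concentrated at the top cell
  structure(data.frame(
    label = c(1, 1, 0, 0, 0),
    lon = c(3, 3, 1, 2, 3), lat = rep(0.5, 5),
    v = c(10, 10, 0, 5, 10)),
    class = c("design_table", "data.frame"))
}

test_that("feature construction matches the stated formulas", {
  d <- data.frame(label = c(1, 0), lon = 0, lat = 0,
                  a = c(0, 4), b = c(1, 3), c = c(2, 2), dd = c(0, 1),
                  e = c(5, -5))
  fs <- build_features(d, vars = c("a", "b", "dd", "e"), classes = "L")
  expect_length(fs$defs, 4)
  X <- feature_matrix(fs, d)
  expect_equal(unname(X[2, 1]), 1)                 # value at the max scales to 1
  # forward hinge at knot 0.5 evaluated at v' = 0.75 gives 0.5
  fs2 <- build_features(d, vars = "a", classes = c("L", "H"), hinge_knots = 1)
  fs2$defs[[2]]$knot <- 0.5
  X2 <- feature_matrix(fs2, data.frame(a = 3))     # v' = 0.75
  expect_equal(unname(X2[1, 2]), 0.5)
  # constant variable: linear feature only, with a warning
  expect_warning(fs3 <- build_features(d, vars = "c"), "constant")
  expect_length(fs3$defs, 1)
})

test_that("extreme regularization shrinks every coefficient to zero", {
  d <- maxent_toy_design()
  fit <- maxent(d, rm = 1e6, classes = "L")
  expect_true(all(fit$lambda == 0))
  expect_equal(fit$objective, -log(3), tolerance = 1e-12)
  expect_equal(fit$entropy, log(3), tolerance = 1e-12)
  # a separating feature earns a positive weight under normal regularization
  fit2 <- maxent(d, rm = 1, classes = "L")
  expect_gt(fit2$lambda[1], 0)
})

test_that("the coordinate-descent solution matches a brute-force 1-D search", {
  d <- maxent_toy_design()
  fit <- maxent(d, rm = 1, classes = "L", tol = 1e-12)
  # independent oracle: maximize the penalized objective over lambda by grid
  # search + golden-section refinement
  f_pres <- c(1, 1); f_bg <- c(0, 0.5, 1)
  beta <- 1 * 1.0 * max(sd(f_pres), 0.001) / sqrt(2)
  obj <- function(l) mean(l * f_pres) - log(sum(exp(l * f_bg))) - beta * abs(l)
  grid <- seq(-30, 30, by = 0.01)
  l0 <- grid[which.max(vapply(grid, obj, numeric(1)))]
  opt <- optimize(obj, c(l0 - 0.02, l0 + 0.02), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$lambda[1]), opt$maximum, tolerance = 1e-3)
  expect_equal(fit$objective, opt$objective, tolerance = 1e-6)
})

test_that("raw predictions normalize over the background and cloglog follows", {
  scen <- small_scenario(seed = 23L)
  b <- gen_truth_bundle(scen)
  d <- assemble_design(occurrence_set(b$presences), b$env, seed = 23L)
  fit <- maxent(d)
  bg <- d[d$label == 0, , drop = FALSE]
  q <- predict(fit, bg, type = "raw")
  expect_equal(sum(q), 1, tolerance = 1e-9)
  p <- predict(fit, bg, type = "cloglog")
  expect_equal(p, 1 - exp(-exp(fit$entropy) * q), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict(fit, bg[, 1:3]), "missing model variable")
})

test_that("cross-validation behaves at the two reference points", {
  scen <- small_scenario(seed = 29L)
  b <- gen_truth_bundle(scen)
  d <- assemble_design(occurrence_set(b$presences), b$env, seed = 29L)
  # AUC on an uninformative design hovers at 1/2
  set.seed(77)
  dn <- d[c("label", "lon", "lat")]
  dn$noise <- rnorm(nrow(dn))
  class(dn) <- class(d)
  cvn <- evaluate_cv(dn, k = 5, seed = 2L, classes = "L")
  expect_lt(abs(cvn$mean_auc - 0.5), 0.06)
  # informative design discriminates
  cv <- evaluate_cv(d, k = 5, seed = 2L)
  expect_gt(cv$mean_auc, 0.75)
  expect_true(all(cv$fold_auc >= 0 & cv$fold_auc <= 1))
  expect_error(evaluate_cv(d, k = 10000), "presence rows")
  # single 75/25 split mode
  cvs <- evaluate_cv(d, seed = 2L, mode = "split")
  expect_length(cvs$fold_auc, 1)
})

test_that("importance credits informative variables and bounds only-gains", {
  scen <- small_scenario(seed = 31L)
  b <- gen_truth_bundle(scen)
  d <- assemble_design(occurrence_set(b$presences), b$env, seed = 31L)
  set.seed(8)
  d$noise <- rnorm(nrow(d))
  vars <- c("bio18", "aspect", "noise")
  vi <- variable_importance(d, vars = vars, classes = c("L", "Q"))
  expect_equal(sum(vi$percent_contribution), 100, tolerance = 0.01)
  expect_true(all(vi$jackknife$gain_only <= vi$full_gain + 0.05))
  expect_lt(vi$jackknife$gain_only[vi$jackknife$var == "noise"], 0.05)
  expect_gt(vi$jackknife$gain_only[vi$jackknife$var == "bio18"], 0.2)
})

test_that("response curves recover a known quadratic optimum", {
  # truth peaked at 0.6 of the variable's range
  set.seed(51)
  n_bg <- 3000
  v_bg <- runif(n_bg)
  truth <- plogis(3 - 30 * (v_bg - 0.6)^2)
  pres_idx <- sample(n_bg, 250, prob = truth)
  d <- structure(data.frame(
    label = c(rep(1, 250), rep(0, n_bg)),
    lon = 0, lat = 0, v = c(v_bg[pres_idx], v_bg)),
    class = c("design_table", "data.frame"))
  fit <- maxent(d)
  rc <- response_curve(fit, "v")
  expect_equal(rc$adaptive_threshold, 0.6, tolerance = 0.1)
  expect_true(nrow(rc$suitable_range) >= 1)
  expect_true(all(rc$suitable_range$lo >= min(v_bg) - 1e-9))
  # a fully shrunk model yields a flat curve
  fit0 <- maxent(d, rm = 1e6)
  rc0 <- response_curve(fit0, "v")
  expect_lt(diff(range(rc0$curve$p)), 1e-9)
})

test_that("raster projection agrees with row predictions and propagates nodata", {
  scen <- small_scenario(seed = 37L)
  b <- gen_truth_bundle(scen)
  env <- b$env
  env$layers$bio12$values[5, 5] <- NA
  d <- assemble_design(occurrence_set(b$presences), env, seed = 37L)
  fit <- maxent(d)
  suit <- project_to_raster(fit, env)
  expect_true(is.na(suit$values[5, 5]))
  ok <- is.finite(suit$values)
  expect_true(all(suit$values[ok] >= 0 & suit$values[ok] <= 1))
  # a cell equal to a design row predicts identically
  row1 <- d[d$label == 0, ][1, ]
  rc <- iqzone:::point_to_cell(env$spec, row1$lon, row1$lat)
  expect_equal(suit$values[rc$row, rc$col],
               predict(fit, row1, type = "cloglog"), tolerance = 1e-12)
})

test_that("AUC ranking is invariant under monotone score transforms", {
  set.seed(61)
  sp <- rnorm(40, 1); sb <- rnorm(200)
  a1 <- iqzone:::rank_auc(sp, sb)
  a2 <- iqzone:::rank_auc(exp(sp), exp(sb))
  a3 <- iqzone:::rank_auc(plogis(sp), plogis(sb))
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})
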