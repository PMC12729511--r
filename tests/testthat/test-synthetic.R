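test_that("environmental layers honor degenerate and stochastic settings", {
  scen <- synthetic_scenario(
    spec = grid_spec(20, 20, x_min = 100, y_max = 30, dx = 0.25),
    env_defs = list(list(code = "flat", family = "exponential", sill = 0,
                         range = 10, nugget = 0, grad_lon = 0, grad_lat = 0,
                         base = 2)),
    truth_coeffs = c(flat = 0), seed = 3L)
  st <- gen_env_stack(scen)
  expect_true(all(st$layers$flat$values == 2))

  # reproducibility: same seed identical, different seed different
  scen2 <- small_scenario(seed = 5L)
  s1 <- gen_env_stack(scen2)
  s2 <- gen_env_stack(scen2)
  expect_identical(s1$layers$bio12$values, s2$layers$bio12$values)
  scen3 <- small_scenario(seed = 6L)
  expect_false(identical(gen_env_stack(scen3)$layers$bio12$values,
                         s1$layers$bio12$values))
})

test_that("generated fields reproduce their variogram sill within 20 percent", {
  # pure field, no gradient: empirical semivariance along rows at lags
  # within the range should track the exponential model
  sill <- 1; rng <- 10
  err <- sapply(1:5, function(seed) {
    scen <- synthetic_scenario(
      spec = grid_spec(100, 100, x_min = 100, y_max = 30, dx = 0.1),
      env_defs = list(list(code = "f", family = "exponential", sill = sill,
                           range = rng, nugget = 0, grad_lon = 0,
                           grad_lat = 0, base = 0)),
      truth_coeffs = c(f = 0), seed = 100L + seed)
    f <- gen_env_stack(scen)$layers$f$values
    g_at <- function(lag) {
      d <- f[, 1:(100 - lag)] - f[, (1 + lag):100]
      mean(d^2) / 2
    }
    model <- sill * (1 - exp(-3 * c(5, 10) / rng))
    mean(abs(c(g_at(5), g_at(10)) / model - 1))
  })
  expect_lt(mean(err), 0.20)
})

test_that("true suitability is the logistic of the stated law", {
  scen <- small_scenario(seed = 2L)
  env <- gen_env_stack(scen)
  # all-zero law -> constant 0.5
  flat <- gen_true_suitability(env, c(bio12 = 0))
  expect_true(all(abs(flat$values - 0.5) < 1e-12))
  # single positive coefficient -> monotone in that layer
  mono <- gen_true_suitability(env, c(bio12 = 1.5))
  expect_equal(cor(as.vector(mono$values), as.vector(env$layers$bio12$values),
                   method = "spearman"), 1)
  # hand-computed logistic values at a few cells
  z <- (env$layers$bio12$values - mean(env$layers$bio12$values)) /
    sd(as.vector(env$layers$bio12$values))
  expect_equal(mono$values[c(1, 77, 1000)],
               plogis(1.5 * z[c(1, 77, 1000)]), tolerance = 1e-12)
  expect_error(gen_true_suitability(env, c(nope = 1)), "unknown layer")
})

test_that("occurrence sampling is truth-proportional without replacement", {
  spec <- grid_spec(10, 10, x_min = 100, y_max = 30, dx = 0.5)
  # indicator truth: the single positive cell is always drawn
  v <- matrix(0, 10, 10); v[3, 7] <- 1
  tr <- raster_grid(spec, v)
  p <- sample_occurrences(tr, 1, seed = 1L)
  expect_equal(unlist(p, use.names = FALSE),
               unlist(cell_geometry(spec, 3, 7)[c("lon", "lat")],
                      use.names = FALSE))
  expect_equal(nrow(sample_occurrences(tr, 0, seed = 1L)), 0)

  # sampled cells are biased toward high truth
  scen <- small_scenario(seed = 4L)
  env <- gen_env_stack(scen)
  truth <- gen_true_suitability(env, scen$truth_coeffs)
  gap <- sapply(1:20, function(s) {
    occ <- sample_occurrences(truth, 100, seed = s)
    ex <- extract_at_points(raster_stack(list(t = truth)), occ)
    mean(ex$t) - mean(truth$values)
  })
  expect_true(all(gap > 0))
})

test_that("compound samples are coupled to the two covariates and nonnegative", {
  scen <- small_scenario(seed = 8L)
  env <- gen_env_stack(scen)
  comp <- gen_compound_samples(scen, env)
  expect_equal(nrow(comp$samples), 26)
  expect_true(all(comp$samples$quercetin >= 0))
  expect_true(all(comp$samples$kaempferol >= 0))

  # noiseless, single-covariate coupling is a monotone map of cov1
  scen2 <- small_scenario(seed = 9L)
  scen2$compound_defs <- list(
    q = list(intercept = 5, beta1 = 1, beta2 = 0, resid_sill = 0,
             resid_range = 10, resid_family = "exponential", nugget_sd = 0))
  comp2 <- gen_compound_samples(scen2, env)
  cov1 <- extract_at_points(env, comp2$samples)$bio18
  expect_equal(cor(comp2$samples$q, cov1, method = "spearman"), 1)
})

test_that("a written bundle re-reads identically and is seed-reproducible", {
  scen <- small_scenario(seed = 12L)
  b <- gen_truth_bundle(scen)
  d1 <- tempfile("bundle1_"); d2 <- tempfile("bundle2_")
  man <- write_scenario_bundle(b, d1)
  # one file per layer + truth + 2 compound truths + 2 tables + metadata
  expect_length(unlist(man),
                length(b$env$layers) + 1 + length(b$compound_truth) + 3)
  rt <- read_raster(man$env_bio12)
  expect_equal(rt$values, b$env$layers$bio12$values, tolerance = 1e-6)
  occ <- read.csv(man$occurrences)
  expect_equal(nrow(occ), nrow(b$presences))
  # regenerating from the recorded seed gives identical files
  write_scenario_bundle(gen_truth_bundle(scen), d2)
  for (f in c("env_bio12.asc", "occurrences.csv", "compound_samples.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
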