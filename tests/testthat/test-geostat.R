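test_that("spearman screen matches closed forms and is rank-invariant", {
  s <- data.frame(lon = 1:4, lat = 1:4,
                  c1 = c(1, 2, 3, 4), v1 = c(2, 1, 4, 3),
                  v2 = exp(c(1, 2, 3, 4)), v3 = c(7, 7, 7, 7))
  scr <- spearman_screen(s, "c1", c("v1", "v2", "v3"))
  expect_equal(scr$rho[scr$variable == "v1"], 0.6)   # 1 - 6*4/(4*15)
  expect_equal(scr$rho[scr$variable == "v2"], 1)     # monotone map of c1
  expect_true("c1~v3" %in% attr(scr, "skipped"))
  # invariance under strictly monotone transforms of either margin
  s2 <- s; s2$c1 <- log(s2$c1 + 1); s2$v1 <- s2$v1^3
  scr2 <- spearman_screen(s2, "c1", "v1")
  expect_equal(scr2$rho, 0.6)
  expect_equal(scr2$p, scr$p[scr$variable == "v1"])
  # cross-check rho and p against the stock test
  set.seed(5)
  x <- rnorm(26); y <- 0.6 * x + rnorm(26)
  s3 <- data.frame(lon = 1:26, lat = 1:26, cc = x, vv = y)
  scr3 <- spearman_screen(s3, "cc", "vv")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(scr3$rho, unname(ct$estimate), tolerance = 1e-12)
})

test_that("empirical semivariograms match their defining sums", {
  # constant field: zero everywhere
  set.seed(1)
  sites <- data.frame(lon = runif(10, 100, 101), lat = runif(10, 25, 26))
  ev <- empirical_variogram(sites, rep(3, 10))
  expect_true(all(ev$gamma[ev$n_pairs > 0] == 0))

  # an isolated close pair with values 0 and 2: its bin reads (0-2)^2/2 = 2
  s4 <- data.frame(lon = c(100, 100.01, 101, 101.5),
                   lat = c(25, 25, 26, 25.2))
  ev4 <- empirical_variogram(s4, c(0, 2, 5, 5), n_lags = 30)
  first <- which(ev4$n_pairs > 0)[1]
  expect_equal(ev4$n_pairs[first], 1)
  expect_equal(ev4$gamma[first], 2)

  # white noise: flat semivariogram at the field variance
  g_by_seed <- sapply(1:20, function(s) {
    set.seed(s)
    st <- data.frame(lon = runif(40, 100, 102), lat = runif(40, 24, 26))
    z <- rnorm(40, sd = 2)
    ev <- empirical_variogram(st, z, n_lags = 5)
    mean(ev$gamma, na.rm = TRUE)
  })
  expect_equal(mean(g_by_seed), 4, tolerance = 0.15)
})

test_that("variogram families evaluate to their closed forms", {
  sph <- variogram_model("spherical", 0.1, 0.9, 50)
  expect_equal(predict(sph, 50), 1.0)                 # sill reached at range
  expect_equal(predict(sph, 0), 0)                    # gamma(0) = 0
  expect_equal(predict(sph, 25), 0.1 + 0.9 * (1.5 * 0.5 - 0.5 * 0.125))
  ex <- variogram_model("exponential", 0.2, 1, 80)
  expect_equal(predict(ex, 80), 0.2 + 1 * (1 - exp(-3)))
  ga <- variogram_model("gaussian", 0, 2, 60)
  expect_equal(predict(ga, 60), 2 * (1 - exp(-3)))
  expect_true(all(diff(predict(sph, seq(0, 200, 1))) >= -1e-12))
})

test_that("noiseless variogram fitting recovers the generating parameters", {
  h <- seq(3, 100, length.out = 15)
  truth <- variogram_model("spherical", 0.1, 0.9, 50)
  emp <- structure(data.frame(h = h, gamma = predict(truth, h),
                              n_pairs = 30L),
                   class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, 0.1, tolerance = 1e-3)
  expect_equal(fit$psill, 0.9, tolerance = 1e-3)
  expect_equal(fit$range_km, 50, tolerance = 1e-3)
  # degenerate input: nugget-only with a warning
  emp0 <- structure(data.frame(h = h, gamma = 0, n_pairs = 10L),
                    class = c("empirical_variogram", "data.frame"))
  expect_warning(f0 <- fit_variogram(emp0), "degenerate")
  expect_equal(f0$psill, 0)
})

test_that("the LMC keeps PSD coefficient matrices and sane cross structure", {
  vm <- variogram_model("exponential", 0.1, 1, 100)
  samp <- grf_at_sites(30, vm, seed = 3)
  # secondary identical to the primary: symmetric 2x2 blocks
  samp$z2 <- samp$z
  lmc <- fit_lmc(samp, "z", "z2", family = "exponential")
  expect_equal(lmc$B1[1, 1], lmc$B1[1, 2], tolerance = 1e-6)
  expect_equal(lmc$B1[1, 1], lmc$B1[2, 2], tolerance = 1e-6)
  expect_gte(min(eigen(lmc$B0)$values), -1e-10)
  expect_gte(min(eigen(lmc$B1)$values), -1e-10)

  # independent fields: cross coefficients near zero relative to the sills
  cross <- sapply(1:8, function(s) {
    a <- grf_at_sites(60, vm, seed = 100 + s)
    b <- grf_at_sites(60, vm, seed = 200 + s)
    a$w <- b$z
    l <- fit_lmc(a, "z", "w", family = "exponential")
    abs(l$B1[1, 2]) / max(l$B1[1, 1], l$B1[2, 2])
  })
  expect_lt(median(cross), 0.35)
})

test_that("ordinary kriging is exact with zero nugget and honors unbiasedness", {
  set.seed(5)
  sites <- data.frame(lon = runif(8, 100, 102), lat = runif(8, 25, 27))
  sites$z <- rnorm(8)
  lmc <- as_lmc(variogram_model("exponential", 0, 1, 80), "z")
  at_sites <- cokrige_points(lmc, sites, sites)
  expect_equal(at_sites$pred, sites$z, tolerance = 1e-8)
  expect_equal(at_sites$se, rep(0, 8), tolerance = 1e-6)
  # constant data predict the constant everywhere
  sites$z <- 3.3
  out <- cokrige_points(lmc, sites, data.frame(lon = 101.2, lat = 26.1))
  expect_equal(out$pred, 3.3, tolerance = 1e-10)
})

test_that("cell solutions match a dense linear-algebra oracle on 5 sites", {
  set.seed(9)
  sites <- data.frame(lon = runif(5, 100, 102), lat = runif(5, 25, 27))
  sites$z <- rnorm(5)
  vm <- variogram_model("spherical", 0.05, 1, 120)
  lmc <- as_lmc(vm, "z")
  targets <- data.frame(lon = c(100.7, 101.9), lat = c(25.5, 26.6))
  got <- cokrige_points(lmc, sites, targets)
  # oracle: assemble and solve the ordinary kriging equations directly from
  # the covariance function C(h) = (c0 + c) - gamma(h), h > 0
  cv <- function(h) ifelse(h <= 0, vm$nugget + vm$psill,
                           (vm$nugget + vm$psill) - predict(vm, h))
  D <- matrix(0, 5, 5)
  for (i in 1:5)
    D[i, ] <- geosphere::distHaversine(cbind(sites$lon[i], sites$lat[i]),
                                       cbind(sites$lon, sites$lat),
                                       r = 6371.0088)
  A <- rbind(cbind(cv(D), 1), c(rep(1, 5), 0))
  for (t in 1:2) {
    d0 <- geosphere::distHaversine(cbind(sites$lon, sites$lat),
                                   cbind(targets$lon[t], targets$lat[t]),
                                   r = 6371.0088)
    w <- solve(A, c(cv(d0), 1))
    pred <- sum(w[1:5] * sites$z)
    se <- sqrt((vm$nugget + vm$psill) - sum(w[1:5] * cv(d0)) - w[6])
    expect_equal(got$pred[t], pred, tolerance = 1e-8)
    expect_equal(got$se[t], se, tolerance = 1e-8)
  }
})

test_that("kriging weights satisfy the unbiasedness constraints", {
  vm <- variogram_model("exponential", 0.1, 1, 100)
  samp <- grf_at_sites(20, vm, seed = 13)
  samp$w <- samp$z * 0.5 + rnorm(20, sd = 0.3)
  lmc <- fit_lmc(samp, "z", "w", family = "exponential")
  sol <- iqzone:::cokrige_solve(lmc, samp[c("lon", "lat")],
                                as.matrix(samp[c("z", "w")]),
                                c(101, 102), c(25.5, 26.5))
  wz <- colSums(sol$weights[1:20, , drop = FALSE])
  ww <- colSums(sol$weights[21:40, , drop = FALSE])
  expect_equal(wz, c(1, 1), tolerance = 1e-10)
  expect_equal(ww, c(0, 0), tolerance = 1e-10)
  expect_true(all(sol$se >= 0))
})

test_that("leave-one-out validation nails a smooth field and centers errors", {
  # near-noiseless smooth trend: tiny LOO errors
  set.seed(17)
  sites <- data.frame(lon = runif(25, 100, 102), lat = runif(25, 25, 27))
  sites$z <- 2 + 0.5 * (sites$lon - 100) + 0.3 * (sites$lat - 25)
  lmc <- as_lmc(variogram_model("gaussian", 0, 1, 500), "z")
  rep <- loo_validate(lmc, sites)
  expect_lt(rep$rmse, 0.02)
  # unbiased predictor on a stationary field: ME near zero across seeds
  vm <- variogram_model("exponential", 0.1, 1, 150)
  mes <- sapply(1:10, function(s)
    loo_validate(as_lmc(vm, "z"), grf_at_sites(30, vm, seed = 300 + s))$me)
  expect_lt(abs(mean(mes)), 0.1)
})
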