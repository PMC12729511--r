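# Shared fixtures: everything is generated in code at test time.

# small desk-scale scenario for unit tests (the acceptance suite uses the
# package default scenario)
small_scenario <- function(seed = 11L, n = 48L) {
  synthetic_scenario(
    spec = grid_spec(n, n, x_min = 100, y_max = 32, dx = 0.25),
    occurrence_n = 120, seed = seed)
}

# write a tiny ESRI ASCII fixture and return its path
write_asc_fixture <- function(lines, path = tempfile(fileext = ".asc")) {
  writeLines(lines, path)
  path
}

# simulate a Gaussian field at scattered sites under an exact variogram
# (dense Cholesky; the oracle route, independent of the package's FFT path)
grf_at_sites <- function(n, vm, seed, lon = c(100, 103), lat = c(24, 27)) {
  set.seed(seed)
  sites <- data.frame(lon = runif(n, lon[1], lon[2]),
                      lat = runif(n, lat[1], lat[2]))
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    d[i, ] <- geosphere::distHaversine(cbind(sites$lon[i], sites$lat[i]),
                                       cbind(sites$lon, sites$lat),
                                       r = 6371.0088)
  C <- (vm$nugget + vm$psill) - predict(vm, d)
  diag(C) <- vm$nugget + vm$psill
  L <- chol(C + diag(1e-10, n))
  sites$z <- as.vector(t(L) %*% rnorm(n))
  sites
}

# exhaustive Fisher-Jenks oracle: enumerate all contiguous partitions,
# first strict improvement wins (same tie-break as the DP)
jenks_brute <- function(x, k) {
  x <- sort(x); n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf; starts <- NULL
  combos <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(combos))) {
    cuts <- c(0, combos[, j], n)
    tot <- sum(vapply(seq_len(k), function(i)
      ssd(x[(cuts[i] + 1):cuts[i + 1]]), numeric(1)))
    if (tot < best - 1e-12) { best <- tot; starts <- cuts[-(k + 1)] + 1 }
  }
  list(ssd = best, starts = starts)
}
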