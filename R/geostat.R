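# Quality-suitability engine: Spearman screening, semivariogram estimation and
# fitting, linear model of coregionalization, ordinary (co-)kriging, and
# leave-one-out validation. Distances in km (haversine), so ranges are in km.

#' Spearman screen of compound-environment associations
#'
#' Tie-corrected Spearman rho from average ranks; two-sided p from the t
#' approximation `t = rho sqrt((n-2)/(1-rho^2))` with `n - 2` df. A variable
#' is selected for a compound when `p < alpha`. Constant vectors are skipped
#' and flagged.
#'
#' @param samples data.frame holding compound and covariate columns.
#' @param compounds compound column names.
#' @param variables covariate column names.
#' @param alpha significance level (default 0.05).
#' @return object of class `correlation_screen`: data.frame (compound,
#'   variable, n, rho, p, selected) plus a `selected` attribute (named list of
#'   selected variables per compound).
#' @export
spearman_screen <- function(samples, compounds, variables, alpha = 0.05) {
  out <- expand.grid(compound = compounds, variable = variables,
                     stringsAsFactors = FALSE)[, 2:1]
  out <- out[order(match(out$compound, compounds)), c("compound", "variable")]
  out$n <- NA_integer_; out$rho <- NA_real_; out$p <- NA_real_
  skipped <- character(0)
  for (i in seq_len(nrow(out))) {
    x <- samples[[out$compound[i]]]; y <- samples[[out$variable[i]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 4) stop("need at least 4 paired observations per test")
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      skipped <- c(skipped, paste0(out$compound[i], "~", out$variable[i]))
      next
    }
    rho <- cor(rank(x[ok]), rank(y[ok]))
    out$n[i] <- n; out$rho[i] <- rho
    out$p[i] <- if (abs(rho) >= 1) 0 else
      2 * pt(abs(rho) * sqrt((n - 2) / (1 - rho^2)), df = n - 2,
             lower.tail = FALSE)
  }
  out$selected <- !is.na(out$p) & out$p < alpha
  sel <- lapply(setNames(compounds, compounds), function(cc)
    out$variable[out$compound == cc & out$selected])
  structure(out, class = c("correlation_screen", "data.frame"),
            selected = sel, alpha = alpha, skipped = skipped)
}

pairwise_km <- function(sites) {
  n <- nrow(sites)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    d[i, ] <- haversine_km(sites$lon[i], sites$lat[i], sites$lon, sites$lat)
  (d + t(d)) / 2   # symmetrize tiny float asymmetry
}

#' Empirical semivariogram
#'
#' `gamma(bin) = sum (z_i - z_j)^2 / (2 N_bin)` over site pairs whose
#' haversine distance falls in the bin. Empty bins are reported with
#' `n_pairs = 0` and excluded from fitting. For a variable pair, the cross
#' semivariogram `sum (u_i - u_j)(v_i - v_j) / (2 N)` is computed instead.
#'
#' @param sites data.frame with `lon`, `lat`.
#' @param values numeric vector (one per site), or a two-column matrix /
#'   data.frame for a cross semivariogram.
#' @param n_lags number of distance bins (default 12).
#' @param max_dist maximum pair distance used; default half the maximum
#'   pairwise distance.
#' @return object of class `empirical_variogram`: data.frame (h, gamma,
#'   n_pairs) with `max_dist` attribute; `h` is the mean pair distance in the
#'   bin.
#' @export
empirical_variogram <- function(sites, values, n_lags = 12, max_dist = NULL) {
  stopifnot(nrow(sites) >= 4)
  v <- as.matrix(values)
  d <- pairwise_km(sites)
  ut <- upper.tri(d)
  h <- d[ut]
  if (is.null(max_dist)) max_dist <- max(h) / 2
  g2 <- if (ncol(v) == 1) (outer(v[, 1], v[, 1], "-")^2)[ut]
        else (outer(v[, 1], v[, 1], "-") * outer(v[, 2], v[, 2], "-"))[ut]
  keep <- h <= max_dist & h > 0
  bin <- findInterval(h[keep], seq(0, max_dist, length.out = n_lags + 1),
                      rightmost.closed = TRUE)
  hm <- gm <- rep(NA_real_, n_lags); np <- integer(n_lags)
  for (b in seq_len(n_lags)) {
    sel <- bin == b
    np[b] <- sum(sel)
    if (np[b] > 0) {
      hm[b] <- mean(h[keep][sel])
      gm[b] <- sum(g2[keep][sel]) / (2 * np[b])
    }
  }
  structure(data.frame(h = hm, gamma = gm, n_pairs = np),
            class = c("empirical_variogram", "data.frame"),
            max_dist = max_dist)
}

#' Variogram model
#'
#' Families (practical-range convention): spherical
#' `c0 + c (1.5 h/a - 0.5 (h/a)^3)` for `h <= a` else `c0 + c`; exponential
#' `c0 + c (1 - exp(-3 h/a))`; gaussian `c0 + c (1 - exp(-3 h^2/a^2))`.
#' `gamma(0) = 0` by convention (the nugget is a discontinuity at the origin).
#'
#' @param family `"spherical"`, `"exponential"`, or `"gaussian"`.
#' @param nugget nugget `c0 >= 0`.
#' @param psill partial sill `c >= 0`.
#' @param range_km range `a > 0` in km.
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget, psill, range_km) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range_km > 0)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range_km = range_km),
            class = "variogram_model")
}

#' Evaluate a variogram model at distances
#' @param object a [variogram_model()].
#' @param h distances in km.
#' @param ... unused.
#' @return semivariance values; 0 at `h = 0`.
#' @export
predict.variogram_model <- function(object, h, ...) {
  g <- unit_variogram(object$family)
  ifelse(h <= 0, 0, object$nugget + object$psill * g(h / object$range_km))
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.4g, partial sill %.4g, range %.4g km\n",
              x$family, x$nugget, x$psill, x$range_km))
  invisible(x)
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with weights `N_bin / h^2`, nonnegativity
#' constraints, multiple starting values. If every empirical value is zero a
#' nugget-only model is returned with a warning.
#'
#' @param empirical an [empirical_variogram()] (rows with `n_pairs = 0`
#'   are ignored).
#' @param family variogram family (default spherical).
#' @return a [variogram_model()] with fit diagnostics in attribute `"fit"`.
#' @export
fit_variogram <- function(empirical,
                          family = c("spherical", "exponential", "gaussian")) {
  family <- match.arg(family)
  e <- empirical[empirical$n_pairs > 0 & is.finite(empirical$gamma), ]
  if (nrow(e) < 3) stop("need at least 3 nonempty bins to fit a variogram")
  if (all(e$gamma <= 0)) {
    warning("degenerate empirical variogram (all zero); nugget-only model")
    out <- variogram_model(family, 0, 0, max(e$h))
    attr(out, "fit") <- list(wss = 0, degenerate = TRUE)
    return(out)
  }
  w <- e$n_pairs / pmax(e$h, 1e-9)^2
  g <- unit_variogram(family)
  wss <- function(th) {
    gm <- th[1] + th[2] * g(e$h / th[3])
    sum(w * (e$gamma - gm)^2)
  }
  smax <- max(e$gamma); hmax <- max(e$h)
  starts <- expand.grid(c0 = c(0, 0.1 * smax, 0.5 * min(e$gamma)),
                        c = c(smax, 0.75 * smax),
                        a = hmax * c(0.2, 0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlminb(as.numeric(starts[i, ]), wss,
             lower = c(0, 0, 1e-6 * hmax),
             upper = c(2 * smax, 10 * smax, 100 * hmax),
             control = list(iter.max = 500, rel.tol = 1e-14, x.tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) stop("variogram fit failed from every start")
  out <- variogram_model(family, best$par[1], best$par[2], best$par[3])
  attr(out, "fit") <- list(wss = best$objective, degenerate = FALSE)
  out
}

# nearest PSD matrix by eigenvalue clipping; returns list(mat, adjustment)
nearest_psd <- function(m) {
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  out <- es$vectors %*% diag(lam, nrow = length(lam)) %*% t(es$vectors)
  dimnames(out) <- dimnames(m)
  list(mat = out, adjustment = sqrt(sum((out - m)^2)))
}

#' Fit a linear model of coregionalization
#'
#' Joint multivariate variogram restricted to a nugget structure plus one
#' shared-family, shared-range structure: `gamma_uv(h) = B0[u,v] 1(h>0) +
#' B1[u,v] g(h/a)`. Direct and cross empirical variograms are computed for
#' every variable pair; for each candidate range the coefficient pair
#' `(B0[u,v], B1[u,v])` is a weighted linear least-squares solve, and the
#' range minimizing total weighted error is kept. `B0` and `B1` are then
#' projected to the nearest positive semi-definite matrices (eigenvalue
#' clipping) and the adjustment magnitude recorded.
#'
#' @param samples data.frame with `lon`, `lat` and the variable columns.
#' @param primary primary variable name (the kriged quantity).
#' @param secondaries character vector of secondary variable names (possibly
#'   empty, giving ordinary kriging).
#' @param family shared variogram family (default spherical).
#' @param n_lags,max_dist forwarded to [empirical_variogram()].
#' @param range_grid candidate ranges in km (default 40 values spanning the
#'   lag window).
#' @return object of class `lmc_model`: `vars` (primary first), `family`,
#'   `range_km`, `B0`, `B1`, `psd_adjustment`.
#' @export
fit_lmc <- function(samples, primary, secondaries = character(0),
                    family = c("spherical", "exponential", "gaussian"),
                    n_lags = 12, max_dist = NULL, range_grid = NULL) {
  family <- match.arg(family)
  vars <- c(primary, secondaries)
  stopifnot(all(vars %in% names(samples)), nrow(samples) >= 4)
  sites <- samples[c("lon", "lat")]
  p <- length(vars)
  emp <- list()
  for (u in seq_len(p)) for (v in u:p) {
    ev <- empirical_variogram(sites, samples[, c(vars[u], vars[v])],
                              n_lags = n_lags, max_dist = max_dist)
    emp[[paste(u, v)]] <- ev[ev$n_pairs > 0 & is.finite(ev$gamma), ]
  }
  hmax <- max(vapply(emp, function(e) max(e$h), numeric(1)))
  if (is.null(range_grid))
    range_grid <- seq(0.1 * hmax, 2 * hmax, length.out = 40)
  g <- unit_variogram(family)
  best <- NULL
  for (a in range_grid) {
    tot <- 0; b0 <- b1 <- matrix(0, p, p)
    for (u in seq_len(p)) for (v in u:p) {
      e <- emp[[paste(u, v)]]
      w <- e$n_pairs / pmax(e$h, 1e-9)^2
      X <- cbind(1, g(e$h / a))
      cf <- tryCatch(solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w),
                                                             e$gamma * sqrt(w))),
                     error = function(err) c(mean(e$gamma), 0))
      b0[u, v] <- b0[v, u] <- cf[1]
      b1[u, v] <- b1[v, u] <- cf[2]
      tot <- tot + sum(w * (e$gamma - X %*% cf)^2)
    }
    if (is.null(best) || tot < best$tot)
      best <- list(tot = tot, a = a, b0 = b0, b1 = b1)
  }
  dimnames(best$b0) <- dimnames(best$b1) <- list(vars, vars)
  p0 <- nearest_psd(best$b0); p1 <- nearest_psd(best$b1)
  structure(list(vars = vars, family = family, range_km = best$a,
                 B0 = p0$mat, B1 = p1$mat,
                 psd_adjustment = p0$adjustment + p1$adjustment,
                 wss = best$tot),
            class = "lmc_model")
}

#' @export
print.lmc_model <- function(x, ...) {
  cat(sprintf("LMC (%s, shared range %.4g km) over %s\n", x$family,
              x$range_km, paste(x$vars, collapse = ", ")))
  cat("B0 (nugget):\n"); print(round(x$B0, 5))
  cat("B1 (structure):\n"); print(round(x$B1, 5))
  if (x$psd_adjustment > 1e-10)
    cat(sprintf("PSD projection adjustment: %.3g\n", x$psd_adjustment))
  invisible(x)
}

#' Wrap a single-variable variogram model as an LMC
#'
#' @param vm a [variogram_model()].
#' @param var variable name (default `"z"`).
#' @return an `lmc_model` equivalent to ordinary kriging with `vm`.
#' @export
as_lmc <- function(vm, var = "z") {
  stopifnot(inherits(vm, "variogram_model"))
  structure(list(vars = var, family = vm$family, range_km = vm$range_km,
                 B0 = matrix(vm$nugget, 1, 1, dimnames = list(var, var)),
                 B1 = matrix(vm$psill, 1, 1, dimnames = list(var, var)),
                 psd_adjustment = 0, wss = NA_real_),
            class = "lmc_model")
}

# covariance between variables u, v at distance d (km) under the LMC:
# C_uv(h) = B0[u,v] 1(h = 0) + B1[u,v] (1 - g(h/a))
lmc_cov <- function(model, u, v, d) {
  g <- unit_variogram(model$family)
  model$B0[u, v] * (d <= 0) + model$B1[u, v] * (1 - g(d / model$range_km))
}

# assemble the ordinary co-kriging system for given data; returns the factor
# pieces needed to solve against many targets at once
cokrige_system <- function(model, sites, data_mat) {
  p <- length(model$vars)
  n <- nrow(sites)
  d <- pairwise_km(sites)
  N <- n * p
  C <- matrix(0, N, N)
  for (u in seq_len(p)) for (v in seq_len(p)) {
    ru <- (u - 1) * n + seq_len(n); rv <- (v - 1) * n + seq_len(n)
    C[ru, rv] <- lmc_cov(model, u, v, d)
  }
  E <- matrix(0, N, p)
  for (v in seq_len(p)) E[(v - 1) * n + seq_len(n), v] <- 1
  A <- rbind(cbind(C, E), cbind(t(E), matrix(0, p, p)))
  z <- as.vector(data_mat)
  list(A = A, z = z, n = n, p = p)
}

# solve the co-kriging system for target points; returns pred + se
cokrige_solve <- function(model, sites, data_mat, target_lon, target_lat) {
  sys <- cokrige_system(model, sites, data_mat)
  n <- sys$n; p <- sys$p
  nt <- length(target_lon)
  # distances site -> target: n x nt
  D0 <- matrix(0, n, nt)
  for (i in seq_len(n))
    D0[i, ] <- haversine_km(sites$lon[i], sites$lat[i], target_lon, target_lat)
  Bm <- matrix(0, n * p + p, nt)
  for (v in seq_len(p))
    Bm[(v - 1) * n + seq_len(n), ] <- lmc_cov(model, 1, v, D0)
  Bm[n * p + 1, ] <- 1                      # primary weights sum to 1
  W <- solve(sys$A, Bm)
  pred <- as.vector(crossprod(W[seq_len(n * p), , drop = FALSE], sys$z))
  C00 <- model$B0[1, 1] + model$B1[1, 1]
  se2 <- C00 - colSums(W[seq_len(n * p), , drop = FALSE] *
                         Bm[seq_len(n * p), , drop = FALSE]) -
    W[n * p + 1, ]
  list(pred = pred, se = sqrt(pmax(se2, 0)),
       weights = W[seq_len(n * p), , drop = FALSE])
}

#' Ordinary co-kriging over a grid
#'
#' Solves the ordinary co-kriging system (unbiasedness: primary weights sum to
#' one, each secondary's weights sum to zero) at every cell center, using
#' covariances from the LMC. With no secondaries this is ordinary kriging.
#' Secondary observations are taken from `samples` columns when present,
#' otherwise extracted from `secondaries_stack` at the sample sites. Cells
#' that are nodata in any stack layer (when a stack is given) propagate to
#' nodata.
#'
#' @param model an [fit_lmc()] / [as_lmc()] model.
#' @param samples data.frame with `lon`, `lat` and data columns.
#' @param spec target [grid_spec()].
#' @param secondaries_stack optional [raster_stack()] supplying secondary
#'   observations and the nodata mask.
#' @return list with `prediction` and `se` ([raster_grid()]s).
#' @export
cokrige_grid <- function(model, samples, spec, secondaries_stack = NULL) {
  dat <- samples
  if (!is.null(secondaries_stack)) {
    need <- setdiff(model$vars, names(dat))
    if (length(need)) {
      ex <- extract_at_points(secondaries_stack, dat)
      for (v in need) dat[[v]] <- ex[[v]]
    }
  }
  stopifnot(all(model$vars %in% names(dat)))
  ok <- complete.cases(dat[model$vars])
  dat <- dat[ok, , drop = FALSE]
  if (nrow(dat) < 4) stop("fewer than 4 complete sample sites")
  cg <- cell_geometry(spec, rep(seq_len(spec$n_rows), spec$n_cols),
                      rep(seq_len(spec$n_cols), each = spec$n_rows))
  sol <- cokrige_solve(model, dat[c("lon", "lat")],
                       as.matrix(dat[model$vars]), cg$lon, cg$lat)
  pm <- matrix(sol$pred, spec$n_rows, spec$n_cols)
  sm <- matrix(sol$se, spec$n_rows, spec$n_cols)
  if (!is.null(secondaries_stack)) {
    mask <- Reduce(`&`, lapply(secondaries_stack$layers,
                               function(g) is.finite(g$values)))
    pm[!mask] <- NA_real_; sm[!mask] <- NA_real_
  }
  list(prediction = raster_grid(spec, pm), se = raster_grid(spec, sm))
}

#' Predict by ordinary co-kriging at arbitrary points
#'
#' @param model an `lmc_model`.
#' @param samples data.frame with `lon`, `lat` and the model's data columns.
#' @param points data.frame with `lon`, `lat`.
#' @return data.frame with `pred`, `se`.
#' @export
cokrige_points <- function(model, samples, points) {
  sol <- cokrige_solve(model, samples[c("lon", "lat")],
                       as.matrix(samples[model$vars]), points$lon, points$lat)
  data.frame(pred = sol$pred, se = sol$se)
}

#' Leave-one-out validation of a (co-)kriging model
#'
#' For each site the primary observation is removed, weights are recomputed
#' with the variogram fixed, and the site is predicted from the remaining
#' data. Reports mean error (ME), root mean square error (RMSE), and the
#' standardized RMSE (root mean of `((zhat - z)/se)^2`), which is close to 1
#' when the kriging standard errors are well calibrated.
#'
#' @param model an `lmc_model`.
#' @param samples data.frame with `lon`, `lat` and data columns.
#' @return object of class `loo_report`: list with `me`, `rmse`, `nrmse`,
#'   and the per-site table.
#' @export
loo_validate <- function(model, samples) {
  stopifnot(nrow(samples) >= 5, all(model$vars %in% names(samples)))
  n <- nrow(samples)
  primary <- model$vars[1]
  pred <- se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train <- samples[-i, , drop = FALSE]
    out <- cokrige_points(model, train, samples[i, c("lon", "lat")])
    pred[i] <- out$pred; se[i] <- out$se
  }
  err <- pred - samples[[primary]]
  tab <- data.frame(lon = samples$lon, lat = samples$lat,
                    observed = samples[[primary]], predicted = pred,
                    se = se, error = err)
  structure(list(me = mean(err), rmse = sqrt(mean(err^2)),
                 nrmse = sqrt(mean((err / pmax(se, 1e-12))^2)),
                 table = tab, compound = primary),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("leave-one-out [%s]: ME %.5f, RMSE %.4f, standardized RMSE %.4f\n",
              x$compound, x$me, x$rmse, x$nrmse))
  invisible(x)
}
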