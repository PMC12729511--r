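# Maximum-entropy presence-background model: Gibbs distribution over the
# background universe with linear/quadratic/hinge features, fitted by cyclic
# coordinate descent on the L1-penalized log likelihood, cloglog output.

#' Build the feature set for a design table
#'
#' Variables are scaled to `[0, 1]` by their design min/max. Feature classes:
#' linear `v'`, quadratic `v'^2`, forward hinges `max(0, (v'-k)/(1-k))` and
#' reverse hinges `max(0, (k-v')/k)` at `hinge_knots` evenly spaced sample
#' quantiles per direction. Constant variables contribute no quadratic or
#' hinge features (with a warning).
#'
#' @param design a design table (or any data.frame holding the variables).
#' @param vars variable names (default: all non-label columns).
#' @param classes feature classes, subset of `c("L", "Q", "H")`.
#' @param hinge_knots knots per hinge direction (default 10).
#' @return object of class `feature_set`.
#' @export
build_features <- function(design, vars = NULL, classes = c("L", "Q", "H"),
                           hinge_knots = 10) {
  if (is.null(vars)) vars <- design_vars(design)
  stopifnot(length(vars) >= 1, all(classes %in% c("L", "Q", "H")))
  bounds <- lapply(design[vars], range)
  defs <- list()
  for (v in vars) {
    lo <- bounds[[v]][1]; hi <- bounds[[v]][2]
    if (hi <= lo) {
      warning("variable '", v, "' is constant; linear feature only")
      if ("L" %in% classes)
        defs[[length(defs) + 1L]] <- list(var = v, type = "L", knot = NA)
      next
    }
    vp <- (design[[v]] - lo) / (hi - lo)
    if ("L" %in% classes)
      defs[[length(defs) + 1L]] <- list(var = v, type = "L", knot = NA)
    if ("Q" %in% classes)
      defs[[length(defs) + 1L]] <- list(var = v, type = "Q", knot = NA)
    if ("H" %in% classes && hinge_knots > 0) {
      ks <- unique(as.numeric(quantile(vp, probs = seq_len(hinge_knots) /
                                         (hinge_knots + 1), names = FALSE)))
      for (k in ks[ks > 0 & ks < 1]) {
        defs[[length(defs) + 1L]] <- list(var = v, type = "HF", knot = k)
        defs[[length(defs) + 1L]] <- list(var = v, type = "HR", knot = k)
      }
    }
  }
  structure(list(vars = vars, bounds = bounds, defs = defs,
                 classes = classes, hinge_knots = hinge_knots),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  tp <- vapply(x$defs, `[[`, character(1), "type")
  cat(sprintf("feature_set: %d variables, %d features (L=%d Q=%d hinge=%d)\n",
              length(x$vars), length(x$defs), sum(tp == "L"), sum(tp == "Q"),
              sum(tp %in% c("HF", "HR"))))
  invisible(x)
}

# evaluate the feature matrix on raw variable rows; values clamped to the
# training bounds so every feature stays in [0, 1]
feature_matrix <- function(fs, data) {
  n <- nrow(data)
  out <- matrix(0, n, length(fs$defs))
  scaled <- list()
  for (v in fs$vars) {
    lo <- fs$bounds[[v]][1]; hi <- fs$bounds[[v]][2]
    scaled[[v]] <- if (hi > lo) pmin(pmax((data[[v]] - lo) / (hi - lo), 0), 1)
                   else rep(0, n)
  }
  for (j in seq_along(fs$defs)) {
    d <- fs$defs[[j]]
    vp <- scaled[[d$var]]
    out[, j] <- switch(d$type,
      L = vp,
      Q = vp^2,
      HF = pmax(0, (vp - d$knot) / (1 - d$knot)),
      HR = pmax(0, (d$knot - vp) / d$knot))
  }
  colnames(out) <- vapply(seq_along(fs$defs), function(j) {
    d <- fs$defs[[j]]
    if (d$type %in% c("L", "Q")) paste0(d$var, ":", d$type)
    else sprintf("%s:%s@%.4f", d$var, d$type, d$knot)
  }, character(1))
  out
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Fit a maximum-entropy presence-background model
#'
#' Maximizes
#' `mean_presence(eta) - log sum_background(exp(eta)) - sum_j beta_j |lambda_j|`
#' with `eta = sum_j lambda_j f_j(x)`, by cyclic coordinate descent with
#' soft-thresholding and step halving (the objective never decreases). The
#' per-feature penalty is `beta_j = rm * c_class * sd_j(presences) / sqrt(m)`
#' with class constants 1.0 for linear/quadratic and 0.5 for hinge features.
#' The fitted raw distribution `q(x) = exp(eta) / Z` sums to one over the
#' background universe; its entropy `H` drives the cloglog output
#' `p = 1 - exp(-e^H q)`.
#'
#' @param design a design table from [assemble_design()] (label column: 1
#'   presence, 0 background).
#' @param vars variables to use (default: all).
#' @param features a [build_features()] result; built from `design` if `NULL`.
#' @param classes,hinge_knots forwarded to [build_features()].
#' @param rm regularization multiplier (default 1).
#' @param tol convergence threshold on the objective gain per full cycle
#'   (default 1e-5).
#' @param max_cycles cap on coordinate-descent cycles (default 500).
#' @return object of class `maxent` with coefficients, penalties, `logZ`,
#'   entropy `H`, percent `contributions`, and a convergence record.
#' @export
maxent <- function(design, vars = NULL, features = NULL,
                   classes = c("L", "Q", "H"), hinge_knots = 10,
                   rm = 1, tol = 1e-5, max_cycles = 500) {
  stopifnot(sum(design$label == 1) >= 2, sum(design$label == 0) >= 2)
  if (is.null(vars)) vars <- design_vars(design)
  if (is.null(features))
    features <- build_features(design, vars, classes, hinge_knots)
  Xp <- feature_matrix(features, design[design$label == 1, , drop = FALSE])
  Xb <- feature_matrix(features, design[design$label == 0, , drop = FALSE])
  m <- nrow(Xp); B <- nrow(Xb); p <- ncol(Xb)
  fvar <- vapply(features$defs, `[[`, character(1), "var")
  ftyp <- vapply(features$defs, `[[`, character(1), "type")
  cclass <- ifelse(ftyp %in% c("L", "Q"), 1.0, 0.5)
  sdp <- apply(Xp, 2, sd)
  beta <- rm * cclass * pmax(sdp, 0.001) / sqrt(m)

  fbar <- colMeans(Xp)
  lambda <- numeric(p)
  eta <- numeric(B)
  logZ <- log(B)
  q <- rep(1 / B, B)
  mean_eta_p <- 0
  obj <- mean_eta_p - logZ
  credit <- setNames(numeric(length(features$vars)), features$vars)
  converged <- FALSE; cycles <- 0L

  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    obj_cycle <- obj
    # cheap screen with the current q (stale within the cycle is fine: a
    # skipped feature is revisited next cycle)
    Ef_all <- as.vector(crossprod(Xb, q))
    active <- which(lambda != 0 | abs(fbar - Ef_all) > beta)
    for (j in active) {
      f <- Xb[, j]
      Ef <- sum(q * f)
      d1 <- fbar[j] - Ef
      if (lambda[j] == 0 && abs(d1) <= beta[j]) next
      V <- max(sum(q * f * f) - Ef^2, 1e-12)
      u <- lambda[j] + d1 / V
      lam_new <- sign(u) * max(0, abs(u) - beta[j] / V)
      delta <- lam_new - lambda[j]
      if (delta == 0) next
      if (abs(delta) > 5) delta <- sign(delta) * 5
      repeat {
        lam_try <- lambda[j] + delta
        eta_try <- eta + delta * f
        logZ_try <- logsumexp(eta_try)
        obj_try <- (mean_eta_p + delta * fbar[j]) - logZ_try -
          sum(beta * abs(replace(lambda, j, lam_try)))
        if (obj_try >= obj - 1e-12 || abs(delta) < 1e-12) break
        delta <- delta / 2
      }
      if (abs(delta) < 1e-12 || obj_try < obj) next
      credit[fvar[j]] <- credit[fvar[j]] + (obj_try - obj)
      lambda[j] <- lambda[j] + delta
      eta <- eta_try; logZ <- logZ_try
      mean_eta_p <- mean_eta_p + delta * fbar[j]
      q <- exp(eta - logZ)
      obj <- obj_try
    }
    if (obj - obj_cycle < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("maxent fit reached the cycle cap (", max_cycles,
            ") before converging")

  H <- -sum(ifelse(q > 0, q * log(q), 0))
  contrib <- if (sum(credit) > 0) 100 * credit / sum(credit)
             else setNames(rep(100 / length(credit), length(credit)),
                           names(credit))
  # penalty term at the solution, for gain bookkeeping
  penalty <- sum(beta * abs(lambda))
  bg_means <- colMeans(design[design$label == 0, features$vars, drop = FALSE])
  structure(list(features = features, lambda = setNames(lambda, colnames(Xb)),
                 beta = beta, rm = rm, logZ = logZ, entropy = H,
                 objective = unname(obj), penalty = penalty,
                 n_presence = m, n_background = B,
                 gain = unname(obj) + log(B),
                 contributions = contrib, bg_means = bg_means,
                 converged = converged, cycles = cycles, tol = tol),
            class = "maxent")
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf(paste0("maxent model: %d presences vs %d background cells, ",
                     "%d features (%d active)\n"),
              x$n_presence, x$n_background, length(x$lambda),
              sum(x$lambda != 0)))
  cat(sprintf("  regularized training gain %.4f, entropy %.4f, %s in %d cycles\n",
              x$gain, x$entropy,
              if (x$converged) "converged" else "NOT converged", x$cycles))
  invisible(x)
}

#' @export
summary.maxent <- function(object, ...) {
  out <- list(model = object,
              contributions = sort(object$contributions, decreasing = TRUE))
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  cat("percent contribution:\n")
  for (nm in names(x$contributions))
    cat(sprintf("  %-10s %6.1f\n", nm, x$contributions[[nm]]))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$lambda

#' Predict from a fitted maxent model
#'
#' `raw` is the Gibbs density relative to the training background universe
#' (summing to one over it); `cloglog` is `1 - exp(-e^H q)` with the entropy
#' `H` and partition value frozen from training; `link` is the linear
#' predictor.
#'
#' @param object a fitted [maxent()] model.
#' @param newdata data.frame carrying all model variables.
#' @param type `"cloglog"` (default), `"raw"`, or `"link"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("cloglog", "raw", "link"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features$vars, names(newdata))
  if (length(miss))
    stop("newdata is missing model variable(s): ", paste(miss, collapse = ", "))
  ok <- complete.cases(newdata[object$features$vars])
  eta <- rep(NA_real_, nrow(newdata))
  if (any(ok)) {
    X <- feature_matrix(object$features, newdata[ok, , drop = FALSE])
    eta[ok] <- as.vector(X %*% object$lambda)
  }
  if (type == "link") return(eta)
  q <- exp(eta - object$logZ)
  if (type == "raw") return(q)
  1 - exp(-exp(object$entropy) * q)
}

# rank AUC: P(presence score > background score), ties counted half
rank_auc <- function(scores_pos, scores_neg) {
  m <- length(scores_pos); n <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Cross-validated AUC of the presence-background model
#'
#' Presences are partitioned into `k` seeded folds; for each fold the model is
#' refit on the remaining presences (against the full background) and the test
#' AUC is the rank statistic of held-out presence predictions against
#' background predictions. `mode = "split"` instead performs a single seeded
#' 75/25 train/test split.
#'
#' @param design a design table.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param mode `"kfold"` (default) or `"split"`.
#' @param train_prop training fraction for `mode = "split"` (default 0.75).
#' @param ... settings forwarded to [maxent()].
#' @return object of class `cv_report`: per-fold AUCs and their mean.
#' @export
evaluate_cv <- function(design, k = 10, seed = 1L, mode = c("kfold", "split"),
                        train_prop = 0.75, ...) {
  mode <- match.arg(mode)
  ip <- which(design$label == 1)
  bg <- design[design$label == 0, , drop = FALSE]
  if (mode == "kfold" && k > length(ip))
    stop("k exceeds the number of presence rows")
  set.seed(seed)
  folds <- if (mode == "kfold") {
    sample(rep_len(seq_len(k), length(ip)))
  } else {
    ifelse(seq_along(ip) %in% sample(seq_along(ip),
                                     round((1 - train_prop) * length(ip))),
           1L, 0L)
  }
  test_sets <- if (mode == "kfold") seq_len(k) else 1L
  aucs <- vapply(test_sets, function(fold) {
    test <- ip[folds == fold]
    train <- setdiff(ip, test)
    d_train <- rbind(design[train, , drop = FALSE], bg)
    fit <- maxent(d_train, ...)
    sp <- predict(fit, design[test, , drop = FALSE], type = "link")
    sb <- predict(fit, bg, type = "link")
    rank_auc(sp, sb)
  }, numeric(1))
  structure(list(k = if (mode == "kfold") k else 1L, mode = mode,
                 fold_auc = aucs, mean_auc = mean(aucs), seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s cross-validation: mean test AUC %.4f over %d fold(s)\n",
              x$mode, x$mean_auc, length(x$fold_auc)))
  invisible(x)
}

#' Percent contribution and jackknife variable importance
#'
#' Percent contribution accumulates the positive objective improvements
#' credited to each coefficient's parent variable during training. The
#' jackknife refits the model with each variable alone and with it omitted;
#' gains are regularized training gains (objective minus the uniform-model
#' objective `-log B`).
#'
#' @param design a design table.
#' @param vars variables (default all).
#' @param ... settings forwarded to [maxent()].
#' @return object of class `variable_importance`.
#' @export
variable_importance <- function(design, vars = NULL, ...) {
  if (is.null(vars)) vars <- design_vars(design)
  full <- maxent(design, vars = vars, ...)
  jk <- data.frame(var = vars, gain_only = NA_real_, gain_without = NA_real_)
  for (i in seq_along(vars)) {
    jk$gain_only[i] <- maxent(design, vars = vars[i], ...)$gain
    if (length(vars) > 1)
      jk$gain_without[i] <- maxent(design, vars = setdiff(vars, vars[i]),
                                   ...)$gain
  }
  structure(list(percent_contribution = full$contributions[vars],
                 jackknife = jk, full_gain = full$gain, model = full),
            class = "variable_importance")
}

#' @export
print.variable_importance <- function(x, ...) {
  cat(sprintf("variable importance (full-model gain %.4f)\n", x$full_gain))
  ord <- order(-x$percent_contribution)
  for (i in ord)
    cat(sprintf("  %-10s contrib %5.1f%%  gain only %7.4f  without %7.4f\n",
                x$jackknife$var[i], x$percent_contribution[i],
                x$jackknife$gain_only[i], x$jackknife$gain_without[i]))
  invisible(x)
}

#' Response curve of one variable with suitable-range extraction
#'
#' The variable sweeps its observed (training) range at `grid_n` points while
#' the other variables sit at their background means; cloglog output uses the
#' frozen training partition value and entropy. The suitable range is the set
#' of maximal intervals with `p >= threshold` (default 0.5); the adaptive
#' threshold is the value maximizing `p` (ties: smallest value).
#'
#' @param model a fitted [maxent()] model.
#' @param variable variable name.
#' @param grid_n number of evaluation points (default 100).
#' @param threshold suitability threshold (default 0.5).
#' @return object of class `response_summary` with `curve` (value, p),
#'   `suitable_range` (data.frame lo/hi), `adaptive_threshold`.
#' @export
response_curve <- function(model, variable, grid_n = 100, threshold = 0.5) {
  if (!variable %in% model$features$vars)
    stop("variable '", variable, "' is not in the model")
  b <- model$features$bounds[[variable]]
  vals <- seq(b[1], b[2], length.out = grid_n)
  nd <- as.data.frame(lapply(model$bg_means, rep, grid_n))
  nd[[variable]] <- vals
  p <- predict(model, nd, type = "cloglog")
  above <- p >= threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sr <- data.frame(lo = vals[starts[runs$values]],
                   hi = vals[ends[runs$values]])
  amax <- which(p == max(p))[1]
  structure(list(variable = variable,
                 curve = data.frame(value = vals, p = p),
                 suitable_range = sr, adaptive_threshold = vals[amax],
                 threshold = threshold),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("response of %s: adaptive threshold %.4g\n",
              x$variable, x$adaptive_threshold))
  if (nrow(x$suitable_range))
    for (i in seq_len(nrow(x$suitable_range)))
      cat(sprintf("  suitable (p >= %.2f): [%.4g, %.4g]\n", x$threshold,
                  x$suitable_range$lo[i], x$suitable_range$hi[i]))
  else cat(sprintf("  no values reach p >= %.2f\n", x$threshold))
  invisible(x)
}

#' @export
plot.maxent <- function(x, variables = NULL, grid_n = 100, ...) {
  if (is.null(variables)) variables <- head(x$features$vars, 4)
  old <- graphics::par(mfrow = c(ceiling(length(variables) / 2),
                                 min(2, length(variables))))
  on.exit(graphics::par(old))
  for (v in variables) {
    rc <- response_curve(x, v, grid_n = grid_n)
    plot(rc$curve$value, rc$curve$p, type = "l", xlab = v,
         ylab = "cloglog p", ylim = c(0, 1), ...)
    graphics::abline(h = 0.5, lty = 3)
  }
  invisible(x)
}

#' Project a fitted model over a raster stack
#'
#' Per-cell cloglog prediction; cells that are nodata in any model layer
#' propagate to nodata.
#'
#' @param model a fitted [maxent()] model.
#' @param stack a [raster_stack()] supplying every model variable.
#' @param type prediction type (default `"cloglog"`).
#' @return a [raster_grid()] of predictions.
#' @export
project_to_raster <- function(model, stack, type = "cloglog") {
  miss <- setdiff(model$features$vars, names(stack$layers))
  if (length(miss))
    stop("stack is missing model layer(s): ", paste(miss, collapse = ", "))
  spec <- stack$spec
  nd <- as.data.frame(lapply(stack$layers[model$features$vars],
                             function(g) as.vector(g$values)))
  p <- predict(model, nd, type = type)
  raster_grid(spec, matrix(p, spec$n_rows, spec$n_cols))
}
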