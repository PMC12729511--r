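# Two-step predictor optimization: drop zero-contribution variables from a
# preliminary maximum-entropy fit, prune |r| > 0.8 pairs keeping the
# higher-contribution member, then iterate until all VIF < 10.

#' Pearson correlation matrix of design variables
#'
#' Zero-variance variables are flagged, excluded with a warning, and reported
#' in the `"excluded"` attribute.
#'
#' @param table data.frame holding the variables.
#' @param vars variable names (default: all non-label columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table, vars = NULL) {
  if (is.null(vars)) vars <- design_vars(table)
  stopifnot(nrow(table) >= 3)
  sds <- vapply(table[vars], sd, numeric(1))
  bad <- vars[!is.finite(sds) | sds == 0]
  if (length(bad)) {
    warning("zero-variance variable(s) excluded: ", paste(bad, collapse = ", "))
    vars <- setdiff(vars, bad)
  }
  m <- cor(as.matrix(table[vars]))
  attr(m, "excluded") <- bad
  m
}

#' Percent contributions from a preliminary model fit
#'
#' Fits a maximum-entropy model with the given settings and returns its
#' percent contributions; variables with zero contribution are listed in the
#' `"zero"` attribute for removal.
#'
#' @param design a design table from [assemble_design()].
#' @param vars variables to use (default all).
#' @param ... settings forwarded to [maxent()].
#' @return named numeric vector of percent contributions (sums to 100).
#' @export
contribution_screen <- function(design, vars = NULL, ...) {
  if (is.null(vars)) vars <- design_vars(design)
  fit <- maxent(design, vars = vars, ...)
  contrib <- fit$contributions
  attr(contrib, "zero") <- names(contrib)[contrib <= 0]
  contrib
}

#' Prune highly correlated variable pairs
#'
#' Pairs are processed in descending `|r|`; for each pair above the threshold
#' where both members are still kept, the lower-contribution member is dropped
#' (ties: the lexicographically later code).
#'
#' @param corr correlation matrix over the candidate variables.
#' @param contributions named percent contributions covering the same
#'   variables.
#' @param threshold absolute-correlation threshold (default 0.8).
#' @return list with `kept` (character) and `dropped` (data.frame: dropped,
#'   kept, r).
#' @export
prune_pairwise <- function(corr, contributions, threshold = 0.8) {
  vars <- rownames(corr)
  stopifnot(all(vars %in% names(contributions)))
  pairs <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  ledger <- data.frame(dropped = character(0), kept = character(0),
                       r = numeric(0))
  if (nrow(pairs)) {
    ord <- order(-abs(corr[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    alive <- setNames(rep(TRUE, length(vars)), vars)
    for (k in seq_len(nrow(pairs))) {
      a <- vars[pairs[k, 1]]; b <- vars[pairs[k, 2]]
      if (!alive[a] || !alive[b]) next
      ca <- contributions[[a]]; cb <- contributions[[b]]
      drop <- if (ca > cb) b
              else if (cb > ca) a
              else sort(c(a, b))[2]           # tie: later code goes
      keep <- setdiff(c(a, b), drop)
      alive[drop] <- FALSE
      ledger <- rbind(ledger, data.frame(dropped = drop, kept = keep,
                                         r = corr[pairs[k, 1], pairs[k, 2]]))
    }
    vars <- vars[alive[vars]]
  }
  list(kept = vars, dropped = ledger)
}

# VIF of each variable: 1/(1 - R^2) of an OLS on the remaining variables
vif_values <- function(table, vars) {
  X <- as.matrix(table[vars])
  vapply(seq_along(vars), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(vars)
}

#' Iterative VIF pruning
#'
#' While the maximum VIF is at or above the threshold, drop the max-VIF
#' variable (ties broken toward the lower contribution) and recompute.
#' Perfectly collinear variables get VIF infinity and go first.
#'
#' @param table data.frame with the variable columns.
#' @param vars candidate variables (>= 2); a single variable is returned
#'   as-is with VIF 1.
#' @param threshold VIF threshold (default 10).
#' @param contributions optional named vector used only for tie-breaking.
#' @return list with `kept`, `final_vifs`, `dropped` (data.frame: var, vif).
#' @export
vif_prune <- function(table, vars, threshold = 10, contributions = NULL) {
  dropped <- data.frame(var = character(0), vif = numeric(0))
  while (length(vars) >= 2) {
    v <- vif_values(table, vars)
    if (max(v) < threshold) break
    worst <- names(v)[v == max(v)]
    if (length(worst) > 1 && !is.null(contributions))
      worst <- worst[order(contributions[worst])]
    worst <- worst[1]
    dropped <- rbind(dropped, data.frame(var = worst, vif = max(v)))
    vars <- setdiff(vars, worst)
  }
  final <- if (length(vars) >= 2) vif_values(table, vars)
           else setNames(rep(1, length(vars)), vars)
  list(kept = vars, final_vifs = final, dropped = dropped)
}

#' Run the full variable-optimization protocol
#'
#' Contribution screen (preliminary model fit; zero-contribution variables
#' removed), pairwise correlation pruning at `|r| > r_threshold` keeping the
#' higher-contribution member, then iterative VIF pruning to below
#' `vif_threshold`. Correlations are computed over the background rows (the
#' landscape sample) by default — collinearity is a property of the predictor
#' field, not of the presences; set `correlation_rows = "all"` to use every
#' row. Variables listed in `retain` are never dropped by the pairwise step
#' (expert override).
#'
#' @param design a design table from [assemble_design()].
#' @param r_threshold pairwise correlation threshold (default 0.8).
#' @param vif_threshold VIF threshold (default 10).
#' @param retain variables never dropped in the pairwise step.
#' @param correlation_rows `"background"` (default) or `"all"`.
#' @param ... settings forwarded to the preliminary [maxent()] fit.
#' @return object of class `selection_report`.
#' @export
select_variables <- function(design, r_threshold = 0.8, vif_threshold = 10,
                             retain = character(0),
                             correlation_rows = c("background", "all"), ...) {
  correlation_rows <- match.arg(correlation_rows)
  vars <- design_vars(design)
  contrib <- contribution_screen(design, vars = vars, ...)
  zero <- attr(contrib, "zero")
  vars1 <- setdiff(vars, zero)

  rows <- if (correlation_rows == "background") design$label == 0
          else rep(TRUE, nrow(design))
  corr <- pearson_matrix(design[rows, , drop = FALSE], vars1)
  vars1 <- rownames(corr)   # zero-variance exclusions applied

  # expert-retained variables are shielded by inflating their contribution
  c2 <- contrib[vars1]
  c2[names(c2) %in% retain] <- Inf
  pw <- prune_pairwise(corr[vars1, vars1, drop = FALSE], c2,
                       threshold = r_threshold)
  vp <- vif_prune(design[rows, , drop = FALSE], pw$kept,
                  threshold = vif_threshold, contributions = contrib)

  structure(list(initial_vars = vars, contributions = contrib,
                 correlation_matrix = corr,
                 dropped_zero_contribution = zero,
                 dropped_pairwise = pw$dropped, dropped_vif = vp$dropped,
                 final_vars = vp$kept, final_vifs = vp$final_vifs,
                 r_threshold = r_threshold, vif_threshold = vif_threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("variable selection report\n")
  cat(sprintf("  initial: %d variables\n", length(x$initial_vars)))
  if (length(x$dropped_zero_contribution))
    cat("  zero contribution:",
        paste(x$dropped_zero_contribution, collapse = ", "), "\n")
  if (nrow(x$dropped_pairwise))
    for (i in seq_len(nrow(x$dropped_pairwise)))
      cat(sprintf("  |r|=%.3f: dropped %s (kept %s)\n",
                  abs(x$dropped_pairwise$r[i]), x$dropped_pairwise$dropped[i],
                  x$dropped_pairwise$kept[i]))
  if (nrow(x$dropped_vif))
    for (i in seq_len(nrow(x$dropped_vif)))
      cat(sprintf("  VIF=%.1f: dropped %s\n", x$dropped_vif$vif[i],
                  x$dropped_vif$var[i]))
  cat(sprintf("  final: %s\n", paste(x$final_vars, collapse = ", ")))
  invisible(x)
}
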