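test_that("pearson matrix matches closed forms and flags degeneracy", {
  tb <- data.frame(x = c(1, 2, 3), y = c(1, 2, 4), z = -c(1, 2, 3),
                   k = c(5, 5, 5))
  expect_warning(m <- pearson_matrix(tb, c("x", "y", "z", "k")), "k")
  expect_equal(diag(m), c(x = 1, y = 1, z = 1))
  expect_equal(m["x", "z"], -1)
  expect_equal(m["x", "y"], 0.98198, tolerance = 1e-5)
  expect_equal(attr(m, "excluded"), "k")
})

test_that("pairwise pruning keeps the higher-contribution member", {
  corr <- diag(2); dimnames(corr) <- list(c("A", "B"), c("A", "B"))
  corr["A", "B"] <- corr["B", "A"] <- 0.95
  out <- prune_pairwise(corr, c(A = 5, B = 3))
  expect_equal(out$kept, "A")
  expect_equal(out$dropped$dropped, "B")

  # nothing above threshold: nothing dropped
  corr["A", "B"] <- corr["B", "A"] <- 0.5
  expect_equal(prune_pairwise(corr, c(A = 5, B = 3))$kept, c("A", "B"))

  # fully correlated triple: only the top contributor survives
  corr3 <- matrix(0.9, 3, 3); diag(corr3) <- 1
  dimnames(corr3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  out3 <- prune_pairwise(corr3, c(A = 5, B = 3, C = 1))
  expect_equal(out3$kept, "A")
  expect_equal(nrow(out3$dropped), 2)
})

test_that("VIF pruning removes collinear variables until all are below 10", {
  set.seed(31)
  n <- 200
  tb <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tb$x3 <- tb$x1 + tb$x2 + rnorm(n, sd = 0.05)
  out <- vif_prune(tb, c("x1", "x2", "x3"))
  expect_equal(out$dropped$var[1], "x3")
  expect_gte(out$dropped$vif[1], 10)
  expect_true(all(out$final_vifs < 10))

  # exact duplicate: infinite VIF, dropped first
  tb$x4 <- tb$x1
  out2 <- vif_prune(tb, c("x1", "x4"))
  expect_equal(out2$dropped$vif[1], Inf)
  expect_length(out2$kept, 1)

  # orthogonal variables: all VIF 1, nothing dropped
  tb2 <- data.frame(a = rep(c(1, -1), 8), b = rep(c(1, 1, -1, -1), 4))
  out3 <- vif_prune(tb2, c("a", "b"))
  expect_equal(unname(out3$final_vifs), c(1, 1), tolerance = 1e-12)
  expect_equal(nrow(out3$dropped), 0)
})

test_that("removing a variable never raises another variable's VIF", {
  set.seed(41)
  for (rep in 1:5) {
    tb <- as.data.frame(matrix(rnorm(40 * 4), 40, 4))
    names(tb) <- paste0("v", 1:4)
    tb$v4 <- tb$v1 * 0.7 + rnorm(40, sd = 0.4)
    v_all <- iqzone:::vif_values(tb, names(tb))
    v_less <- iqzone:::vif_values(tb, names(tb)[-4])
    # R^2 of a regression cannot increase when a regressor is removed
    expect_true(all(v_less <= v_all[names(v_less)] + 1e-9))
  }
})

test_that("contributions normalize to 100 and credit informative variables", {
  scen <- small_scenario(seed = 13L)
  b <- gen_truth_bundle(scen)
  d <- assemble_design(occurrence_set(b$presences), b$env, seed = 13L)
  contrib <- contribution_screen(d)
  expect_equal(sum(contrib), 100, tolerance = 0.01)
  # single-variable design: everything is credited to it
  d1 <- d[c("label", "lon", "lat", "bio12")]
  class(d1) <- class(d)
  c1 <- contribution_screen(d1)
  expect_equal(unname(c1["bio12"]), 100, tolerance = 1e-9)
  # a pure-noise variable earns (nearly) nothing
  set.seed(99)
  dn <- d
  dn$noise <- rnorm(nrow(d))
  cn <- contribution_screen(dn)
  expect_lt(unname(cn["noise"]), 5)
})

test_that("the full protocol removes the constructed nuisance duplicates", {
  scen <- small_scenario(seed = 17L)
  b <- gen_truth_bundle(scen)
  d <- assemble_design(occurrence_set(b$presences), b$env, seed = 17L)
  sel <- select_variables(d)
  expect_true(all(!c("nuis1", "nuis2", "nuis3") %in% sel$final_vars))
  expect_true(all(sel$final_vifs < 10))
  # survivors are below the pairwise threshold too
  cm <- sel$correlation_matrix[sel$final_vars, sel$final_vars]
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.8))
  # every initial variable lands in exactly one bin
  binned <- c(sel$final_vars, sel$dropped_zero_contribution,
              sel$dropped_pairwise$dropped, sel$dropped_vif$var)
  expect_setequal(binned, sel$initial_vars)
  # determinism
  sel2 <- select_variables(d)
  expect_identical(sel$final_vars, sel2$final_vars)
})
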