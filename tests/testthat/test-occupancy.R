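test_that("predict_raw matches the four-state equations and their limits", {
  # no repression: all constructs read identically
  p <- occupancy_params(x1 = 0.3, x2 = 0.3, x3 = 0.4, y1 = 1, y2 = 1)
  expect_equal(unname(predict_raw(p)), rep(1, 4))

  # full repression of bound fractions
  p <- occupancy_params(x1 = 0.4, x2 = 0.4, x3 = 0.2, y1 = 0, y2 = 0)
  out <- predict_raw(p)
  expect_equal(out[["FTL"]], 0.2)
  expect_equal(out[["DOUBLE"]], 1.0)

  # duplicate-implementation oracle: independently re-typed equations
  set.seed(11)
  for (i in 1:200) {
    q <- random_occupancy()
    oracle <- c(
      q$y1 * q$x1 + q$y2 * q$x2 + q$x3,
      q$y1 * (q$x1 + q$alpha) + q$x2 - q$alpha + q$x3,
      q$x1 - q$beta + q$y2 * (q$x2 + q$beta) + q$x3,
      q$x1 + q$x2 + q$x3
    )
    expect_equal(unname(predict_raw(q)), oracle, tolerance = 1e-12)
  }
})

test_that("constraint violations are rejected with the named constraint", {
  expect_error(occupancy_params(x1 = -0.1, x2 = 0.5, x3 = 0.6,
                                y1 = 0.5, y2 = 0.5), "x1 >= 0")
  expect_error(occupancy_params(x1 = 0.5, x2 = 0.5, x3 = 0,
                                y1 = 1.5, y2 = 0.5), "y1")
  expect_error(occupancy_params(x1 = 0.2, x2 = 0.2, x3 = 0.6,
                                y1 = 0.5, y2 = 0.5,
                                alpha = 0.7, beta = 0.7),
               "alpha \\+ beta")
  expect_error(occupancy_params(x1 = 0.5, x2 = 0.5, x3 = 0.5,
                                y1 = 0.5, y2 = 0.5), "x1 \\+ x2 \\+ x3")
})

test_that("predict_reduced agrees with predict_raw after eliminating x3", {
  # algebraic-identity oracle over >= 1000 random draws: substitute
  # x3 = 1 - y1 x1 - y2 x2 into the raw equations and renormalize
  set.seed(21)
  for (i in 1:1000) {
    q <- random_occupancy()
    x3_sub <- 1 - q$y1 * q$x1 - q$y2 * q$x2
    raw <- c(
      q$y1 * (q$x1 + q$alpha) + q$x2 - q$alpha + x3_sub,
      q$x1 - q$beta + q$y2 * (q$x2 + q$beta) + x3_sub,
      q$x1 + q$x2 + x3_sub
    )
    expect_equal(unname(predict_reduced(q)), raw, tolerance = 1e-12)
  }
  # y1 = y2 = 1 collapses every construct to the wild-type readout
  p <- occupancy_params(x1 = 0.2, x2 = 0.3, x3 = 0.5, y1 = 1, y2 = 1)
  expect_equal(unname(predict_reduced(p)), rep(1, 3))
  # direct arithmetic case
  p <- occupancy_params(x1 = 0.3, x2 = 0.3, x3 = 0.4, y1 = 0, y2 = 0)
  expect_equal(predict_reduced(p)[["DOUBLE"]], 1.6)
})

test_that("the exclusivity identity Double - Loop - D3RE = bracket holds", {
  set.seed(31)
  for (i in 1:1000) {
    q <- random_occupancy()
    pred <- predict_reduced(q)
    expect_equal(pred[["DOUBLE"]] - pred[["LOOP"]] - pred[["D3RE"]],
                 bracket_term(q$y1, q$y2, q$alpha, q$beta),
                 tolerance = 1e-12)
  }
})

test_that("bracket_term spans exactly [-1, 0] over the constraint box", {
  expect_equal(bracket_term(0.3, 0.9, 0, 0), -1)
  expect_equal(bracket_term(0, 0, 0.4, 0.6), 0)
  g <- seq(0, 1, length.out = 20)
  grid <- expand.grid(y1 = g, y2 = g, alpha = g, beta = g)
  grid <- grid[grid$alpha + grid$beta <= 1, ]
  vals <- with(grid, alpha + beta - y1 * alpha - y2 * beta - 1)
  expect_equal(min(vals), -1)
  expect_equal(max(vals), 0)
})

test_that("rhs_bounds reproduces the published feasibility bound", {
  b <- rhs_bounds(12.5, 4.4)
  expect_equal(b[["upper"]], 16.9)
  expect_equal(b[["lower"]], 15.9)
  expect_equal(unname(rhs_bounds(1, 1)), c(1, 2))
  expect_error(rhs_bounds(-1, 2), "positive")
})

test_that("test_exclusivity rejects the published readouts", {
  v <- test_exclusivity(published_readouts(), n_draws = 20000)
  expect_false(v$point_consistent)
  expect_lt(v$p_consistent, 0.001)
  expect_equal(v$z_score, (41.8 - 12.5 - 4.4) / sqrt(6.5^2 + 2.9^2 + 0.4^2))
})

test_that("readouts inside the feasible band are accepted", {
  ro <- construct_readouts(data.frame(
    construct = c("D3RE", "LOOP", "DOUBLE"),
    mean = c(4, 12, 15.5),      # Double = Loop + D3RE - 0.5
    sd = c(0.01, 0.01, 0.01), n = 3))
  v <- test_exclusivity(ro, n_draws = 5000)
  expect_true(v$point_consistent)
  expect_gt(v$p_consistent, 0.999)
})

test_that("test_exclusivity is seed-reproducible and monotone in Double", {
  ro <- published_readouts()
  v1 <- test_exclusivity(ro, n_draws = 5000, seed = 7)
  v2 <- test_exclusivity(ro, n_draws = 5000, seed = 7)
  expect_identical(v1$p_consistent, v2$p_consistent)

  doubles <- c(14, 17, 20, 25, 41.8)
  ps <- vapply(doubles, function(d) {
    ro$mean[ro$construct == "DOUBLE"] <- d
    test_exclusivity(ro, n_draws = 20000, seed = 3)$p_consistent
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("test_exclusivity errors and warnings are informative", {
  ro <- construct_readouts(data.frame(
    construct = c("D3RE", "LOOP"), mean = c(4.4, 12.5),
    sd = c(0.4, 2.9), n = 6))
  expect_error(test_exclusivity(ro), "DOUBLE")
  expect_warning(test_exclusivity(published_readouts(), n_draws = 500),
                 "n_draws")
})

test_that("fit_exclusive recovers noise-free synthetic outputs", {
  q <- occupancy_params(x1 = 0.35, x2 = 0.25, x3 = 0.4,
                        y1 = 0.15, y2 = 0.4, alpha = 0.2, beta = 0.3)
  raw <- predict_raw(q)
  norm <- raw / raw[["FTL"]]
  ro <- construct_readouts(data.frame(
    construct = c("D3RE", "LOOP", "DOUBLE"),
    mean = norm[c("D3RE", "LOOP", "DOUBLE")],
    sd = 0.05, n = 6))
  fit <- fit_exclusive(ro, seed = 2)
  expect_true(fit$feasible)
  expect_lt(fit$chisq, 1e-6)
  # the map is not injective: the contract is on recovered outputs
  expect_equal(unname(fit$fitted),
               unname(norm[c("D3RE", "LOOP", "DOUBLE")]),
               tolerance = 1e-4)
})

test_that("fit_exclusive declares the published readouts infeasible", {
  fit <- fit_exclusive(published_readouts(), seed = 2)
  expect_false(fit$feasible)
  expect_true(fit$converged)
  # the constrained minimum cannot beat the propagated z^2
  z2 <- ((41.8 - 12.5 - 4.4) / sqrt(6.5^2 + 2.9^2 + 0.4^2))^2
  expect_gt(fit$chisq, qchisq(0.95, 3))
  expect_equal(fit$chisq, z2, tolerance = 0.05)
})

test_that("fit_exclusive accepts flat unity readouts via y1 = y2 = 1", {
  ro <- construct_readouts(data.frame(
    construct = c("D3RE", "LOOP", "DOUBLE"),
    mean = c(1, 1, 1), sd = 0.01, n = 3))
  fit <- fit_exclusive(ro, seed = 4)
  expect_true(fit$feasible)
  expect_lt(fit$chisq, 1e-4)
})
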