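test_that("simulation without competitor approaches the quadratic equilibrium", {
  r <- binding_reaction(competitor_fold = 0, duration = 300)
  tc <- simulate_competition(r, seq(0, 300, by = 20))
  # closed-form two-component equilibrium (quadratic in the complex)
  rt <- r$labeled_rna; pt <- r$protein; kd <- r$koff / r$kon
  s <- rt + pt + kd
  rp_eq <- (s - sqrt(s^2 - 4 * rt * pt)) / 2
  expect_equal(tail(tc$bound_fraction, 1), rp_eq / rt, tolerance = 1e-6)
  # monotone approach from below, up to integrator tolerance
  # (atol 1e-9 nM on a 0.3 nM probe ~ 3e-9 in fraction units)
  expect_true(all(diff(tc$bound_fraction) >= -1e-7))
})

test_that("saturating fast binding drives the bound fraction to 1", {
  r <- binding_reaction(kon = 1e9, koff = 1e-4, duration = 60)
  tc <- simulate_competition(r, c(0, 60))
  expect_gt(tail(tc$bound_fraction, 1), 0.999)
})

test_that("an equal-affinity competitor partitions protein 1:fold", {
  r <- binding_reaction(competitor_fold = 1000, duration = 3000)
  tc <- simulate_competition(r, c(0, 3000))
  eq <- equilibrium_bound(r)
  # trajectory reaches the algebraic competitive equilibrium
  expect_equal(tail(tc$bound_fraction, 1), unname(eq["bound_fraction"]),
               tolerance = 1e-5)
  # identical rate constants: bound fractions are equal, so labeled
  # complexes are 1/1001 of all complexes
  labeled <- eq[["bound_fraction"]] * r$labeled_rna
  comp <- eq[["bound_comp"]] * r$competitor_fold * r$labeled_rna
  expect_equal(labeled / (labeled + comp), 1 / 1001, tolerance = 1e-9)
})

test_that("bound fractions stay physical along every trajectory", {
  for (fold in c(0, 1000, 75000)) {
    r <- binding_reaction(competitor_fold = fold, duration = 600)
    tc <- simulate_competition(r, seq(0, 600, length.out = 40))
    expect_true(all(tc$bound_fraction >= 0 & tc$bound_fraction <= 1))
  }
})

test_that("labeled bound fraction is non-increasing in competitor excess", {
  r <- binding_reaction(duration = 1110)
  folds <- 10^seq(3, 5, length.out = 6)
  dr <- gen_dose_response(r, folds, noise_sd = 0, seed = 1)
  expect_true(all(diff(dr$response) <= 1e-9))
  # and so is the algebraic equilibrium
  eqs <- vapply(folds, function(f) {
    r$competitor_fold <- f
    equilibrium_bound(r)[["bound_fraction"]]
  }, numeric(1))
  expect_true(all(diff(eqs) < 0))
})

test_that("sample times outside the incubation are rejected", {
  r <- binding_reaction(duration = 100)
  expect_error(simulate_competition(r, c(0, 200)), "duration")
})

test_that("fit_koff recovers the printed rate from a noiseless chase", {
  tc <- simulate_competition(chase_reaction(),
                             seq(0, 510, length.out = 60))
  fit <- fit_koff(tc, t_min = 30)
  expect_true(fit$converged)
  expect_equal(fit$koff, 0.006, tolerance = 0.01)
})

test_that("fit_koff flags flat curves and needs enough points", {
  flat <- data.frame(time_min = seq(0, 480, by = 60),
                     bound_fraction = 0.85)
  expect_false(fit_koff(flat)$converged)
  expect_error(fit_koff(data.frame(time_min = c(0, 10, 20),
                                   bound_fraction = c(1, .5, .2))),
               "5 time points")
})

test_that("fit_koff is consistent under replicated 2% noise", {
  # scaled-down version of the recovery study (full 50-replicate run
  # lives in the acceptance suite)
  tc <- gen_timecourse(chase_reaction(), noise_sd = 0.02, n_points = 40,
                       seed = 99, n_rep = 10)
  ests <- vapply(split(tc, tc$replicate), function(d) {
    fit_koff(d, t_min = 30)$koff
  }, numeric(1))
  expect_equal(mean(ests), 0.006, tolerance = 0.06)
})

test_that("equilibrium checkpoints mirror the 11 h / 18 h comparison", {
  tc <- simulate_competition(
    binding_reaction(competitor_fold = 1e5, duration = 1110),
    seq(0, 1110, by = 30))
  expect_true(equilibrium_reached(tc, 660, 1080, tol = 0.02))
  expect_false(equilibrium_reached(tc, 0, 30, tol = 0.02))
  flat <- data.frame(time_min = seq(0, 1110, by = 30),
                     bound_fraction = 0.15)
  expect_true(equilibrium_reached(flat, 100, 1000))
  expect_error(equilibrium_reached(tc, 500, 2000), "beyond")
  expect_error(equilibrium_reached(tc, 700, 600), "earlier")
})

test_that("fit_dose_response recovers exact four-parameter logistic data", {
  folds <- 10^seq(2, 5, length.out = 10)
  y <- 0.1 + (0.9 - 0.1) / (1 + 10^(1.2 * (log10(folds) - log10(5000))))
  fit <- fit_dose_response(data.frame(fold_excess = folds, response = y))
  expect_true(fit$determinable)
  expect_equal(fit$ic50, 5000, tolerance = 1e-6)
  expect_equal(fit$hill, 1.2, tolerance = 1e-6)
  expect_lte(fit$bottom, fit$top)
})

test_that("IC50 is invariant to uniform response rescaling", {
  folds <- 10^seq(2, 5, length.out = 10)
  y <- 0.05 + 0.85 / (1 + 10^(0.9 * (log10(folds) - log10(8000))))
  f1 <- fit_dose_response(data.frame(fold_excess = folds, response = y))
  f2 <- fit_dose_response(data.frame(fold_excess = folds, response = 7 * y))
  expect_equal(f1$ic50, f2$ic50, tolerance = 1e-6)
})

test_that("non-competing (Loop-like) curves are not determinable", {
  folds <- 10^seq(3, 5, length.out = 8)
  set.seed(5)
  flat <- data.frame(fold_excess = rep(folds, 3),
                     response = 0.8 + rnorm(24, 0, 0.01))
  fit <- fit_dose_response(flat)
  expect_false(fit$determinable)
  expect_match(fit$reason, "competition|converge")
  expect_error(fit_dose_response(data.frame(fold_excess = c(10, 100, 1000),
                                            response = c(1, .5, .2))),
               "4 distinct")
})
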