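test_that("fit_progress_curve recovers the generating model exactly", {
  cv <- make_curve(v0 = 0.001, kobs = 0.005, times = seq(0, 1200, by = 20))
  fit <- fit_progress_curve(cv)
  expect_true(fit$converged)
  expect_lt(abs(fit$v0 - 0.001) / 0.001, 1e-6)
  expect_lt(abs(fit$kobs - 0.005) / 0.005, 1e-6)

  # Eq limits of the fitted model: P(Inf) = v0/kobs, dP/dt|0 = v0
  expect_equal(fit$plateau, fit$v0 / fit$kobs)

  # a baseline offset is estimated and reported when t=0 signal is nonzero
  cvb <- make_curve(v0 = 0.001, kobs = 0.005, baseline = 0.3)
  fitb <- fit_progress_curve(cvb)
  expect_lt(abs(fitb$baseline - 0.3), 1e-6)
  expect_lt(abs(fitb$kobs - 0.005) / 0.005, 1e-5)
})

test_that("fit_progress_curve handles the kobs -> 0 straight-line limit", {
  cv <- make_curve(v0 = 2e-4, kobs = 0, times = seq(0, 600, by = 30))
  fit <- fit_progress_curve(cv)
  expect_lte(fit$kobs, 1e-6)
  expect_lt(abs(fit$v0 - 2e-4) / 2e-4, 1e-4)
})

test_that("fit_progress_curve matches an independent grid-search oracle", {
  plateau <- 0.001 / 0.004
  cv <- make_curve(v0 = 0.001, kobs = 0.004, noise_sd = 0.02 * plateau,
                   seed = 7)
  fit <- fit_progress_curve(cv, baseline = "none")
  gr <- oracle_grid_progress(cv$times, cv$signal,
                             v0_range = c(5e-4, 2e-3),
                             kobs_range = c(2e-3, 8e-3), n_grid = 241)
  expect_lt(abs(fit$v0 - gr$v0), 3 * gr$dv)
  expect_lt(abs(fit$kobs - gr$kobs), 3 * gr$dk)
  expect_lte(fit$rss, gr$rss + 1e-12)
})

test_that("fit_progress_curve rejects degenerate input", {
  expect_error(fit_progress_curve(
    progress_curve("x", c(0, 1, 2, 3), c(0, 1, 2, 3), 1, .2, 200)),
    ">= 5 points")
  expect_error(fit_progress_curve(
    progress_curve("x", 0:5, rep(1, 6), 1, .2, 200)), "constant")
})

test_that("fit_kobs_vs_inhibitor is exact on lines and matches OLS oracle", {
  I <- c(1, 2, 4, 6, 8) * 1e-6
  reg <- fit_kobs_vs_inhibitor(I, 2e4 * I)
  expect_equal(reg$slope, 2e4, tolerance = 1e-10)
  expect_equal(reg$intercept, 0, tolerance = 1e-10)
  expect_equal(reg$r_squared, 1)

  # affine invariance of the slope
  reg2 <- fit_kobs_vs_inhibitor(I, 2e4 * I + 1e-4)
  expect_equal(reg2$slope, 2e4, tolerance = 1e-8)
  expect_equal(reg2$intercept, 1e-4, tolerance = 1e-10)

  set.seed(19)
  y <- 3e4 * I + rnorm(5, 0, 1e-3)
  reg3 <- fit_kobs_vs_inhibitor(I, y)
  or <- oracle_ols(I, y)
  expect_equal(reg3$slope, or$slope, tolerance = 1e-10)
  expect_equal(reg3$intercept, or$intercept, tolerance = 1e-10)
  expect_equal(reg3$r_squared, or$r_squared, tolerance = 1e-10)

  expect_error(fit_kobs_vs_inhibitor(c(1, 1, 1) * 1e-6, c(1, 2, 3)),
               "distinct")
  expect_error(fit_kobs_vs_inhibitor(1e-6, 0.01), "distinct")
})

# vectorized over substrate for the monotonicity property
correct_association_constant_v <- function(k, S, km)
  vapply(S, function(s) correct_association_constant(k, s, km), 0)

test_that("correct_association_constant implements the competition factor", {
  # inverted from the reported ka = 8.4e4 at [S] = 200 uM, Km = 114 uM
  kapp <- 8.4e4 / (1 + 200 / 114)
  expect_equal(correct_association_constant(kapp, 200, 114), 8.4e4,
               tolerance = 1e-12)
  expect_equal(correct_association_constant(3.05e4, 0, 114), 3.05e4)
  expect_equal(correct_association_constant(3.05e4, 114, 114), 2 * 3.05e4)
  expect_error(correct_association_constant(1, 200, 0), "km")

  # strictly increasing in [S], decreasing in Km
  S <- seq(0, 500, by = 50)
  expect_true(all(diff(correct_association_constant_v(1e4, S, 114)) > 0))
  kms <- seq(50, 500, by = 50)
  vals <- vapply(kms, function(km)
    correct_association_constant(1e4, 200, km), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("association pipeline recovers ka exactly without noise across a log-grid", {
  for (ka in 10^seq(3, 7)) {
    sc <- kinetic_scenario(ka_true = ka, noise_sd_frac = 0)
    fit <- run_association_pipeline(simulate_progress_curves(sc), km = sc$km)
    expect_lt(abs(fit$ka - ka) / ka, 1e-4)
    expect_equal(fit$ka, fit$kapp_prime * (1 + fit$substrate_conc / fit$km))
  }
})

test_that("association pipeline tolerates 2% noise within 5%", {
  sc <- kinetic_scenario(ka_true = 1e5, noise_sd_frac = 0.02, seed = 11)
  fit <- run_association_pipeline(simulate_progress_curves(sc), km = sc$km)
  expect_lt(abs(fit$ka - 1e5) / 1e5, 0.05)
})

test_that("association pipeline validates its inputs", {
  sc <- kinetic_scenario(inhibitor_concs = 0.4, noise_sd_frac = 0)
  expect_error(run_association_pipeline(simulate_progress_curves(sc), 114),
               "distinct")
  sc2 <- kinetic_scenario(inhibitor_concs = c(0.05, 0.4, 0.8, 1.2),
                          noise_sd_frac = 0)
  expect_warning(run_association_pipeline(simulate_progress_curves(sc2), 114),
                 "pseudo-first-order")
  # mixed substrate concentrations are rejected
  cvs <- simulate_progress_curves(kinetic_scenario(noise_sd_frac = 0))
  cvs[[1]]$substrate_conc <- 100
  expect_error(run_association_pipeline(cvs, 114), "substrate")
})
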