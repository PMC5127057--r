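test_that("simulate_progress_curves inverts the analysis model exactly", {
  sc <- kinetic_scenario(ka_true = 1e5, inhibitor_concs = 1,
                         noise_sd_frac = 0)
  cv <- simulate_progress_curves(sc)[[1]]
  kobs_expected <- 1e5 * 1e-6 / (1 + 200 / 114)
  fit <- fit_progress_curve(cv)
  expect_lt(abs(fit$kobs - kobs_expected) / kobs_expected, 1e-6)
})

test_that("simulator output is seed-reproducible byte for byte", {
  sc <- kinetic_scenario(seed = 3)
  a <- simulate_progress_curves(sc)
  b <- simulate_progress_curves(sc)
  expect_identical(a, b)

  # golden-file style: the whole written table is identical too
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  serpintools:::write_progress_table(a, p1)
  serpintools:::write_progress_table(b, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_identical(simulate_titration(1.76, seed = 8),
                   simulate_titration(1.76, seed = 8))
  expect_identical(simulate_decay(21, seed = 8), simulate_decay(21, seed = 8))
  expect_identical(simulate_fecal_assay(seed = 8),
                   simulate_fecal_assay(seed = 8))
})

test_that("sub-seeding isolates noise: adding a curve shifts nothing", {
  # fixed read schedule: the shared time grid must not depend on which
  # curves are present for the isolation property to be meaningful
  s6 <- kinetic_scenario(seed = 5, duration = 1200, n_timepoints = 61)
  s4 <- kinetic_scenario(seed = 5, duration = 1200, n_timepoints = 61,
                         inhibitor_concs = kinetic_scenario()$inhibitor_concs[1:4])
  a <- simulate_progress_curves(s6)
  b <- simulate_progress_curves(s4)
  for (i in 1:4) expect_identical(a[[i]]$signal, b[[i]]$signal)
})

test_that("simulate_titration follows the clipped-linear partitioning model", {
  ts <- simulate_titration(2, ratios = 0:4, noise_sd = 0)
  expect_equal(ts$fractional_activity, c(1, 0.5, 0, 0, 0))
  expect_error(simulate_titration(0.5), "si_true")
})

test_that("simulate_decay follows the exponential with flooring", {
  d <- simulate_decay(10, times = c(0, 10, 20), noise_sd_pct = 0)
  expect_equal(d$residual_activity, c(100, 50, 25))
  dn <- simulate_decay(1, times = seq(0, 60, 5), noise_sd_pct = 5, seed = 2)
  expect_true(all(dn$residual_activity >= 0))
})

test_that("simulate_fecal_assay reproduces stated folds and inhibitions", {
  meas <- simulate_fecal_assay(control_mean = 1, fold_dss = 2.2,
                               inhibition_pct = c(s1 = 30), noise_cv = 0)
  g <- summarize_groups(meas)
  dss <- g[g$group_label == "DSS", ]
  pbs <- g[g$group_label == "PBS", ]
  expect_equal(fold_change(dss, pbs), 2.2)
  s1 <- g[g$group_label == "DSS+s1", ]
  expect_equal(percent_residual(s1$mean_activity,
                                dss$mean_activity)$residual_pct, 70)

  # noisy group means land within 3 SEM of the generating means
  meas <- simulate_fecal_assay(control_mean = 1, fold_dss = 2.2,
                               inhibition_pct = c(s1 = 30, s2 = 35),
                               n_per_group = 8, noise_cv = 0.25, seed = 21)
  g <- summarize_groups(meas)
  truth <- c(PBS = 1, DSS = 2.2, `DSS+s1` = 2.2 * 0.7, `DSS+s2` = 2.2 * 0.65)
  for (grp in names(truth)) {
    row <- g[g$group_label == grp, ]
    expect_lt(abs(row$mean_activity - truth[[grp]]), 3 * row$sem)
  }
})

test_that("end-to-end noiseless identifiability holds for every generator", {
  # ka
  sc <- kinetic_scenario(ka_true = 2.6e5, km = 270, noise_sd_frac = 0)
  fit <- run_association_pipeline(simulate_progress_curves(sc), km = 270)
  expect_lt(abs(fit$ka - 2.6e5) / 2.6e5, 1e-4)
  # SI
  si <- fit_si(simulate_titration(1.82, noise_sd = 0))$si
  expect_lt(abs(si - 1.82) / 1.82, 1e-4)
  # t_half
  th <- fit_half_life(simulate_decay(21, seq(0, 120, 10), 0))$t_half
  expect_lt(abs(th - 21) / 21, 1e-4)
  # folds
  g <- summarize_groups(simulate_fecal_assay(noise_cv = 0))
  expect_lt(abs(fold_change(g[g$group_label == "DSS", ],
                            g[g$group_label == "PBS", ]) - 2.2) / 2.2, 1e-4)
})

test_that("ODE stress mode approaches the closed form in the excess limit", {
  # with inhibitor barely depleted (SI * E0 << I0) the mass-action system
  # reduces to the pseudo-first-order closed form
  sc <- kinetic_scenario(ka_true = 1e5, enzyme_conc = 0.01,
                         inhibitor_concs = 2, si_true = 1,
                         noise_sd_frac = 0)
  closed <- simulate_progress_curves(sc, ode = FALSE)[[1]]
  ode <- simulate_progress_curves(sc, ode = TRUE)[[1]]
  expect_lt(max(abs(closed$signal - ode$signal)) / max(closed$signal), 0.01)

  # higher SI consumes inhibitor faster: less protease loss, more product
  sc_hi <- kinetic_scenario(ka_true = 1e5, enzyme_conc = 1,
                            inhibitor_concs = 2, si_true = 3,
                            noise_sd_frac = 0)
  sc_lo <- kinetic_scenario(ka_true = 1e5, enzyme_conc = 1,
                            inhibitor_concs = 2, si_true = 1,
                            noise_sd_frac = 0)
  p_hi <- simulate_progress_curves(sc_hi, ode = TRUE)[[1]]
  p_lo <- simulate_progress_curves(sc_lo, ode = TRUE)[[1]]
  expect_gt(max(p_hi$signal), max(p_lo$signal))
})
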