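test_that("noiseless model-generated data is recovered to optimizer tolerance", {
  times <- tcspc_grid(512L)
  irf <- std_irf(times)
  truth <- decay_model(tau_disc = 4, alpha_disc = 4000, tau_g = 3.3,
                       fwhm_g = 1, alpha_g = 6000, baseline = 2)
  y <- evaluate_model(truth, irf, times)
  trace <- decay_trace(times, y)
  start <- truth
  for (nm in c("tau_disc", "alpha_disc", "tau_g", "fwhm_g", "alpha_g"))
    start[[nm]] <- truth[[nm]] * 1.15  # within 20% of truth
  fit <- fit_decay(trace, irf, start, restarts = 0L)
  for (nm in c("tau_disc", "alpha_disc", "tau_g", "fwhm_g", "alpha_g"))
    expect_equal(fit$model[[nm]], truth[[nm]], tolerance = 1e-4)
  expect_lt(fit$reduced_chi_square, 1e-6)
  expect_true(fit$converged)
})

test_that("held parameters are returned exactly and fractions sum to one", {
  times <- tcspc_grid(512L)
  irf <- std_irf(times)
  truth <- bound_truth()
  truth$alpha_disc <- 4000; truth$alpha_g <- 6000
  trace <- simulate_decay(truth, irf, 1e6, seed = 7, times = times)
  start <- truth
  start$alpha_g <- 5000
  fit <- fit_decay(trace, irf, start,
                   fixed = c("tau_disc", "shift", "tau_nuis", "alpha_nuis"),
                   restarts = 0L)
  expect_identical(fit$model$tau_disc, truth$tau_disc)
  expect_identical(fit$model$shift, 0)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
  expect_true(all(fit$fractions >= 0 & fit$fractions <= 1))
})

test_that("an absent gaussian component is recovered as absent", {
  times <- tcspc_grid(512L)
  irf <- std_irf(times)
  truth <- decay_model(tau_disc = 4, alpha_disc = 1, alpha_g = 0)
  trace <- simulate_decay(truth, irf, 1e6, seed = 3, times = times)
  start <- decay_model(tau_disc = 4, alpha_disc = 2e4, tau_g = 3,
                       fwhm_g = 1, alpha_g = 1e4)
  null_start <- start
  null_start$alpha_g <- 1
  fit <- fit_decay(trace, irf, start, restarts = 1L,
                   extra_starts = list(null_start))
  expect_lt(fit$fractions[["gaussian"]], 0.02)
})

test_that("degenerate inputs are rejected and sparse data warns", {
  times <- tcspc_grid(128L)
  irf <- std_irf(times, center = 1)
  expect_error(fit_decay(decay_trace(times, rep(0, 128L)), irf,
                         donor_truth()), "all-zero")
  truth <- decay_model(tau_disc = 4, alpha_disc = 1)
  tr <- simulate_decay(truth, irf, 2e3, seed = 1, times = times)
  expect_warning(fit_decay(tr, irf, initial <- decay_model(4, 50),
                           restarts = 0L), "1e4 photons")
})

test_that("two-step protocol recovers the donor lifetime and the bound-state centre", {
  times <- tcspc_grid()
  irf <- std_irf(times)
  ctrl <- simulate_decay(donor_truth(), irf, 2e6, seed = 21, times = times)
  samp <- simulate_decay(bound_truth(), irf, 2e6, seed = 22, times = times)
  fit <- two_step_fit(ctrl, samp, irf, seed = 1)
  # step 1: donor lifetime within 1% of the 4 ns simulator truth
  expect_equal(fit$tau_donor, 4, tolerance = 0.01)
  # step 2: held donor, free gaussian recovered near truth
  expect_identical(fit$sample$model$tau_disc, fit$tau_donor)
  expect_true("tau_disc" %in% fit$sample$fixed)
  expect_equal(fit$sample$model$tau_g, 3.3, tolerance = 0.15 / 3.3)
  expect_equal(unname(fit$sample$fractions[["gaussian"]]), 0.6,
               tolerance = 0.05 / 0.6)
  expect_equal(unname(fit$sample$fractions[["discrete"]]), 0.4,
               tolerance = 0.05 / 0.4)
})

test_that("a sample identical to the control shows no FRET population", {
  times <- tcspc_grid()
  irf <- std_irf(times)
  ctrl <- simulate_decay(donor_truth(), irf, 2e6, seed = 31, times = times)
  samp <- simulate_decay(donor_truth(), irf, 2e6, seed = 32, times = times)
  fit <- two_step_fit(ctrl, samp, irf, seed = 1)
  expect_lt(fit$sample$fractions[["gaussian"]], 0.02)
})

test_that("short-lifetime contamination lands in the nuisance component", {
  times <- tcspc_grid()
  irf <- std_irf(times)
  # 8% of photons in a 0.3 ns component: amplitudes scale as share / tau
  contaminated <- decay_model(tau_disc = 4, alpha_disc = 0.92 / 4,
                              alpha_g = 0, tau_nuis = 0.3,
                              alpha_nuis = 0.08 / 0.3)
  ctrl <- simulate_decay(contaminated, irf, 2e6, seed = 41, times = times)
  samp <- simulate_decay(bound_truth(), irf, 2e6, seed = 42, times = times)
  fit <- two_step_fit(ctrl, samp, irf, seed = 1)
  shares <- intensity_fractions(fit$control$model)
  expect_lt(shares[["nuisance"]], 0.10)
  expect_equal(fit$tau_donor, 4, tolerance = 0.02)
})

test_that("a control dominated by short lifetimes raises a control-quality error", {
  times <- tcspc_grid()
  irf <- std_irf(times)
  # 70% of photons at 0.4 ns
  junk <- decay_model(tau_disc = 4, alpha_disc = 0.3 / 4, alpha_g = 0,
                      tau_nuis = 0.4, alpha_nuis = 0.7 / 0.4)
  ctrl <- simulate_decay(junk, irf, 2e6, seed = 51, times = times)
  samp <- simulate_decay(bound_truth(), irf, 2e6, seed = 52, times = times)
  expect_error(two_step_fit(ctrl, samp, irf, seed = 1), "control-quality")
})

test_that("gaussian-centre estimator is nearly unbiased with small dispersion", {
  # >= 20 Poisson replicates at 2e6 photons: bias < 2%, SD < 5% of truth
  times <- tcspc_grid()
  irf <- std_irf(times)
  centers <- vapply(1:20, function(i) {
    ctrl <- simulate_decay(donor_truth(), irf, 2e6, seed = 1000 + i,
                           times = times)
    samp <- simulate_decay(bound_truth(), irf, 2e6, seed = 2000 + i,
                           times = times)
    fit <- two_step_fit(ctrl, samp, irf, seed = i, restarts = 0L)
    fit$sample$model$tau_g
  }, numeric(1))
  expect_lt(abs(mean(centers) - 3.3) / 3.3, 0.02)
  expect_lt(sd(centers) / 3.3, 0.05)
})

test_that("reduced chi-square is calibrated on well-populated windows", {
  # windows whose channels carry enough photons keep the Neyman statistic
  # near 1; 95% of replicates within [0.8, 1.2]
  times <- tcspc_grid(512L)
  irf <- std_irf(times)
  truth <- bound_truth()
  chis <- vapply(1:20, function(i) {
    tr <- simulate_decay(truth, irf, 2e6, seed = 3000 + i, times = times)
    start <- truth
    start$alpha_disc <- 0.3 * max(tr$counts)
    start$alpha_g <- 0.45 * max(tr$counts)
    fit_decay(tr, irf, start, restarts = 0L)$reduced_chi_square
  }, numeric(1))
  expect_gte(mean(chis >= 0.8 & chis <= 1.2), 0.95)
})
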