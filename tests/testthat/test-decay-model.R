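test_that("decay trace and IRF containers enforce their grid contracts", {
  t64 <- seq(0, by = 0.05, length.out = 64)
  expect_s3_class(decay_trace(t64, rep(1, 64)), "decay_trace")
  expect_error(decay_trace(t64[1:32], rep(1, 32)), "at least 64")
  expect_error(decay_trace(t64, rep(-1, 64)), "non-negative")
  bad <- t64; bad[10] <- bad[10] + 0.01
  expect_error(decay_trace(bad, rep(1, 64)), "uniform")
  expect_error(decay_trace(rev(t64), rep(1, 64)), "increasing")
  expect_error(instrument_response(t64, rep(0, 64)), "zero total")
})

test_that("gaussian discretisation has unit weights, correct sigma, and a degenerate limit", {
  # sigma = fwhm / (2 sqrt(2 ln 2)); frozen from independent arithmetic
  g <- discretize_gaussian(center = 3.3, fwhm = 1.0, n_nodes = 61)
  sigma <- diff(range(g$lifetimes)) / 6  # 61 nodes span +/- 3 sigma
  expect_equal(sigma, 0.42466, tolerance = 1e-4)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_true(all(g$weights >= 0))
  # nodes symmetric about the centre
  expect_equal(g$lifetimes + rev(g$lifetimes), rep(6.6, 61), tolerance = 1e-12)

  # width below the resolution floor collapses to a single node
  g0 <- discretize_gaussian(center = 3.3, fwhm = 1e-6)
  expect_equal(g0$lifetimes, 3.3)
  expect_equal(g0$weights, 1)

  # unit weights across assorted shapes
  for (p in list(c(1, 0.3), c(0.5, 2), c(10, 5))) {
    gi <- discretize_gaussian(p[1], p[2])
    expect_equal(sum(gi$weights), 1, tolerance = 1e-12)
    expect_true(all(gi$lifetimes >= 0.01))
  }
  expect_error(discretize_gaussian(-1, 1), "positive")
  expect_error(discretize_gaussian(3, 1, n_nodes = 10), "odd")
})

test_that("delta-IRF convolution reduces to the analytic exponential mixture", {
  times <- tcspc_grid(256L)
  m <- decay_model(tau_disc = 3.3, alpha_disc = 5, baseline = 0)
  y <- evaluate_model(m, delta_irf(times), times)
  expect_equal(y, 5 * exp(-times / 3.3), tolerance = 1e-9)

  # with a Gaussian component the delta-IRF output is the node mixture
  m2 <- decay_model(tau_disc = 4, alpha_disc = 1, tau_g = 3.3, fwhm_g = 1,
                    alpha_g = 2)
  g <- discretize_gaussian(3.3, 1)
  manual <- exp(-times / 4) +
    2 * colSums(g$weights * exp(outer(-1 / g$lifetimes, times)))
  expect_equal(evaluate_model(m2, delta_irf(times), times), manual,
               tolerance = 1e-9)
})

test_that("the forward model is linear in the amplitudes", {
  times <- tcspc_grid(256L)
  irf <- std_irf(times)
  m <- decay_model(tau_disc = 4, alpha_disc = 0.4, tau_g = 3.3, fwhm_g = 1,
                   alpha_g = 0.6, baseline = 0)
  m3 <- m
  m3$alpha_disc <- 3 * m$alpha_disc
  m3$alpha_g <- 3 * m$alpha_g
  expect_equal(evaluate_model(m3, irf, times),
               3 * evaluate_model(m, irf, times), tolerance = 1e-9)
})

test_that("zero-amplitude gaussian leaves the output independent of its shape", {
  times <- tcspc_grid(256L)
  irf <- std_irf(times)
  m1 <- decay_model(tau_disc = 4, alpha_disc = 1, tau_g = 1, fwhm_g = 0.5,
                    alpha_g = 0)
  m2 <- decay_model(tau_disc = 4, alpha_disc = 1, tau_g = 6, fwhm_g = 3,
                    alpha_g = 0)
  expect_identical(evaluate_model(m1, irf, times),
                   evaluate_model(m2, irf, times))
})

test_that("gaussian-IRF convolution matches a 10x-oversampled brute-force oracle", {
  dt <- 0.05
  times <- seq(0, by = dt, length.out = 400L)
  center <- 2; fwhm <- 0.25
  irf <- make_irf(times, center = center, fwhm = fwhm)
  m <- decay_model(tau_disc = 3.3, alpha_disc = 1, baseline = 0)
  y <- evaluate_model(m, irf, times)

  # brute force: sample the same Gaussian profile on a 10x finer grid,
  # normalise to unit sum, and accumulate the causal sum directly
  fine <- seq(0, by = dt / 10, length.out = 4000L)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  p <- exp(-0.5 * ((fine - center) / sigma)^2)
  p <- p / sum(p)
  oracle <- vapply(times, function(tk) {
    s <- fine[fine <= tk]
    sum(p[seq_along(s)] * exp(-(tk - s) / 3.3))
  }, numeric(1))

  # compare where the IRF rise is complete (causal-cutoff effects gone)
  sel <- times > center + 0.6
  expect_lt(max(abs(y[sel] - oracle[sel]) / oracle[sel]), 1e-3)
})

test_that("evaluate_model rejects mismatched grids and never dips below baseline", {
  times <- tcspc_grid(256L)
  irf <- std_irf(times)
  m <- decay_model(tau_disc = 4, alpha_disc = 1, baseline = 7)
  expect_error(evaluate_model(m, irf, seq(0, by = 0.1, length.out = 256)),
               "spacing")
  expect_true(all(evaluate_model(m, irf, times) >= 7))
})

test_that("amplitude fractions report molar shares and reject the degenerate model", {
  m <- decay_model(tau_disc = 4, alpha_disc = 2, tau_g = 3, fwhm_g = 1,
                   alpha_g = 3)
  expect_equal(amplitude_fractions(m),
               c(discrete = 0.4, gaussian = 0.6))
  expect_equal(sum(amplitude_fractions(m)), 1, tolerance = 1e-12)
  m1 <- decay_model(tau_disc = 4, alpha_disc = 1, alpha_g = 0)
  expect_equal(amplitude_fractions(m1), c(discrete = 1, gaussian = 0))
  m0 <- m; m0$alpha_disc <- 0; m0$alpha_g <- 0
  expect_error(amplitude_fractions(m0), "zero")
})

test_that("intensity fractions weight amplitudes by lifetime", {
  # equal amplitudes, lifetimes 4 and ~3.3: photon shares follow alpha*tau
  m <- decay_model(tau_disc = 4, alpha_disc = 1, tau_g = 3.3, fwhm_g = 1e-6,
                   alpha_g = 1)
  f <- intensity_fractions(m)
  expect_equal(unname(f["discrete"] / f["gaussian"]), 4 / 3.3,
               tolerance = 1e-6)
  expect_equal(sum(f), 1, tolerance = 1e-12)
})
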