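# Shared fixtures, built in code.

# 0.05 ns channel grid; 1024 channels (51.2 ns) resolves the full donor
# decay, 512 channels is enough when only fit calibration matters.
tcspc_grid <- function(n = 1024L, dt = 0.05) seq(0, by = dt, length.out = n)

std_irf <- function(times = tcspc_grid(), center = 2, fwhm = 0.25) {
  make_irf(times, center = center, fwhm = fwhm)
}

# IRF with all mass in the first channel: convolution identity
delta_irf <- function(times = tcspc_grid()) {
  y <- numeric(length(times))
  y[1L] <- 1
  instrument_response(times, y)
}

# Bound-state truth used across the TCSPC recovery tests: unquenched donor
# 4 ns (molar fraction 0.4) + bent population centred at 3.3 ns, fwhm 1 ns
# (fraction 0.6).
bound_truth <- function() {
  decay_model(tau_disc = 4, alpha_disc = 0.4, tau_g = 3.3, fwhm_g = 1,
              alpha_g = 0.6, baseline = 0)
}

donor_truth <- function() {
  decay_model(tau_disc = 4, alpha_disc = 1, alpha_g = 0, baseline = 0)
}

# Independent closed-form oracle for the n = 1 depletion binding curve:
# theta = ((C + L + K) - sqrt((C + L + K)^2 - 4 C L)) / (2 L)
depletion_quadratic <- function(c_total, l_total, kd) {
  s <- c_total + l_total + kd
  (s - sqrt(s^2 - 4 * c_total * l_total)) / (2 * l_total)
}
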