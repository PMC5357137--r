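#' Mixture decay model: one discrete lifetime plus a Gaussian distribution
#'
#' The forward model for a donor fluorescence decay: a discrete-lifetime
#' component (the unquenched donor), a component whose lifetime is spread as
#' a Gaussian distribution (the FRET-shortened, bent-DNA population), an
#' optional short-lifetime nuisance component (scattered light and anomalous
#' fluorophore behaviour), a constant baseline, and a sub-channel IRF shift.
#' Amplitudes are pre-exponential factors in count units; amplitude
#' fractions report molar populations.
#'
#' @param tau_disc discrete lifetime, ns (> 0).
#' @param alpha_disc pre-exponential amplitude of the discrete component
#'   (>= 0).
#' @param tau_g centre of the Gaussian lifetime distribution, ns (> 0).
#' @param fwhm_g full width at half maximum of the distribution, ns (> 0).
#' @param alpha_g pre-exponential amplitude of the Gaussian component
#'   (>= 0); `alpha_disc + alpha_g` must be positive.
#' @param baseline constant counts per channel (>= 0).
#' @param shift IRF shift in channels (real; 0 = none).
#' @param tau_nuis nuisance short lifetime, ns; only used when
#'   `alpha_nuis > 0`.
#' @param alpha_nuis nuisance amplitude (>= 0, default 0 = absent).
#' @return An object of class `"decay_model"`.
#' @export
decay_model <- function(tau_disc, alpha_disc, tau_g = 3.3, fwhm_g = 1,
                        alpha_g = 0, baseline = 0, shift = 0,
                        tau_nuis = 0.3, alpha_nuis = 0) {
  m <- structure(list(tau_disc = tau_disc, alpha_disc = alpha_disc,
                      tau_g = tau_g, fwhm_g = fwhm_g, alpha_g = alpha_g,
                      baseline = baseline, shift = shift,
                      tau_nuis = tau_nuis, alpha_nuis = alpha_nuis),
                 class = "decay_model")
  validate_decay_model(m)
  m
}

validate_decay_model <- function(m, allow_zero_amplitude = FALSE) {
  stopifnot(is.list(m))
  if (!(m$tau_disc > 0) || !(m$tau_g > 0) || !(m$fwhm_g > 0) ||
      !(m$tau_nuis > 0))
    stop("lifetimes and fwhm must be positive", call. = FALSE)
  if (m$alpha_disc < 0 || m$alpha_g < 0 || m$alpha_nuis < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  if (!allow_zero_amplitude && m$alpha_disc + m$alpha_g <= 0)
    stop("at least one of the discrete and Gaussian amplitudes must be positive",
         call. = FALSE)
  if (m$baseline < 0)
    stop("baseline must be non-negative", call. = FALSE)
  invisible(m)
}

#' @export
print.decay_model <- function(x, ...) {
  cat("Decay model (discrete + Gaussian lifetime distribution)\n")
  cat(sprintf("  discrete : tau = %.4g ns, alpha = %.4g\n",
              x$tau_disc, x$alpha_disc))
  cat(sprintf("  gaussian : centre = %.4g ns, fwhm = %.4g ns, alpha = %.4g\n",
              x$tau_g, x$fwhm_g, x$alpha_g))
  if (x$alpha_nuis > 0)
    cat(sprintf("  nuisance : tau = %.4g ns, alpha = %.4g\n",
                x$tau_nuis, x$alpha_nuis))
  cat(sprintf("  baseline = %.4g counts/channel, shift = %.4g channels\n",
              x$baseline, x$shift))
  invisible(x)
}

# fwhm -> Gaussian sigma
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Discretise a Gaussian lifetime distribution into quadrature nodes
#'
#' Realises a Gaussian distribution of lifetimes as a finite set of
#' (lifetime, weight) nodes for use inside the forward convolution. Nodes
#' are placed symmetrically about the centre over `span_sigmas` standard
#' deviations with trapezoid weights; lifetimes falling below `floor` are
#' dropped and the remaining weights renormalised to unit sum. A width below
#' the numerical resolution floor (1e-3 ns) collapses to a single node at
#' the centre.
#'
#' @param center distribution centre, ns (> 0).
#' @param fwhm full width at half maximum, ns (> 0);
#'   `sigma = fwhm / (2 sqrt(2 ln 2))`.
#' @param n_nodes odd node count >= 3 (default 61).
#' @param span_sigmas half-range in standard deviations (default 3).
#' @param floor smallest admissible lifetime, ns (default 0.01).
#' @return A list with numeric vectors `lifetimes` and `weights`
#'   (`sum(weights) == 1`).
#' @export
discretize_gaussian <- function(center, fwhm, n_nodes = 61L,
                                span_sigmas = 3, floor = 0.01) {
  if (!(center > 0) || !(fwhm > 0))
    stop("`center` and `fwhm` must be positive", call. = FALSE)
  if (n_nodes < 3L || n_nodes %% 2L == 0L)
    stop("`n_nodes` must be an odd integer >= 3", call. = FALSE)
  if (fwhm < 1e-3)
    return(list(lifetimes = center, weights = 1))
  sigma <- fwhm * FWHM_TO_SIGMA
  tau <- seq(center - span_sigmas * sigma, center + span_sigmas * sigma,
             length.out = n_nodes)
  w <- exp(-0.5 * ((tau - center) / sigma)^2)
  # trapezoid rule end-point halving
  w[c(1L, n_nodes)] <- w[c(1L, n_nodes)] / 2
  keep <- tau >= floor
  if (!any(keep))
    stop("entire lifetime distribution lies below the floor", call. = FALSE)
  tau <- tau[keep]
  w <- w[keep]
  list(lifetimes = tau, weights = w / sum(w))
}

#' Expected TCSPC counts by forward convolution
#'
#' Evaluates the reconvolution forward model: the multi-exponential impulse
#' response implied by `model` is convolved (discrete, causal) with the
#' unit-sum, shift-interpolated instrument response, scaled by the
#' pre-exponential amplitudes, and offset by the baseline.
#'
#' @param model a [decay_model()].
#' @param irf an [instrument_response()].
#' @param times evaluation grid, ns; defaults to the IRF grid. Must share
#'   the IRF channel width.
#' @param n_nodes,span_sigmas,floor Gaussian discretisation controls passed
#'   to [discretize_gaussian()].
#' @return Numeric vector of expected counts per channel (all
#'   `>= model$baseline`).
#' @export
evaluate_model <- function(model, irf, times = irf$times, n_nodes = 61L,
                           span_sigmas = 3, floor = 0.01) {
  # amplitude boundaries are legitimately visited during optimisation
  validate_decay_model(model, allow_zero_amplitude = TRUE)
  if (!inherits(irf, "instrument_response"))
    stop("`irf` must be an instrument_response", call. = FALSE)
  dt <- check_uniform_grid(times)
  if (abs(dt - irf$channel_width) > 1e-9 * irf$channel_width)
    stop("evaluation grid and IRF grid spacings differ", call. = FALSE)
  n <- length(times)

  # impulse response sampled on relative time from the first channel
  trel <- times - times[1L]
  h <- model$alpha_disc * exp(-trel / model$tau_disc)
  if (model$alpha_g > 0) {
    g <- discretize_gaussian(model$tau_g, model$fwhm_g, n_nodes = n_nodes,
                             span_sigmas = span_sigmas, floor = floor)
    h <- h + model$alpha_g *
      colSums(g$weights * exp(outer(-1 / g$lifetimes, trel)))
  }
  if (model$alpha_nuis > 0)
    h <- h + model$alpha_nuis * exp(-trel / model$tau_nuis)

  p <- shift_profile(irf$counts, model$shift)
  p <- p / sum(irf$counts)
  y <- causal_convolve(p, h)
  # FFT roundoff can leave tiny negative values before the IRF rise
  model$baseline + pmax(y, 0)
}

# Linear-interpolation sub-channel shift; positive shift moves the profile
# to later channels. Out-of-range samples are zero.
shift_profile <- function(counts, shift) {
  if (shift == 0) return(counts)
  n <- length(counts)
  idx <- seq_len(n) - shift
  lo <- floor(idx)
  frac <- idx - lo
  at <- function(i) ifelse(i >= 1 & i <= n, counts[pmin(pmax(i, 1L), n)], 0)
  (1 - frac) * at(lo) + frac * at(lo + 1)
}

# First n terms of the discrete (causal) convolution of p and h.
causal_convolve <- function(p, h) {
  n <- length(h)
  full <- stats::convolve(p, rev(h), type = "open")
  full[seq_len(n)]
}

#' Amplitude (molar) fractions of the discrete and Gaussian components
#'
#' The share of each principal component in the pre-exponential amplitudes,
#' reporting molar populations: `fraction_i = alpha_i / (alpha_disc +
#' alpha_g)`. The nuisance component is excluded.
#'
#' @param model a [decay_model()] with `alpha_disc + alpha_g > 0`.
#' @return Named numeric vector `c(discrete, gaussian)` summing to 1.
#' @export
amplitude_fractions <- function(model) {
  tot <- model$alpha_disc + model$alpha_g
  if (tot <= 0)
    stop("both principal amplitudes are zero", call. = FALSE)
  c(discrete = model$alpha_disc / tot, gaussian = model$alpha_g / tot)
}

#' Intensity (photon) fractions of the decay components
#'
#' Converts pre-exponential amplitudes to steady-state photon shares by
#' weighting each amplitude with its lifetime (the Gaussian component by its
#' node-weighted mean lifetime). Includes the nuisance component when
#' present, so the result describes shares of total detected photons.
#'
#' @inheritParams amplitude_fractions
#' @return Named numeric vector (`discrete`, `gaussian`, and `nuisance` when
#'   present) summing to 1.
#' @export
intensity_fractions <- function(model) {
  g <- discretize_gaussian(model$tau_g, model$fwhm_g)
  parts <- c(discrete = model$alpha_disc * model$tau_disc,
             gaussian = model$alpha_g * sum(g$weights * g$lifetimes))
  if (model$alpha_nuis > 0)
    parts <- c(parts, nuisance = model$alpha_nuis * model$tau_nuis)
  if (sum(parts) <= 0)
    stop("all component intensities are zero", call. = FALSE)
  parts / sum(parts)
}
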