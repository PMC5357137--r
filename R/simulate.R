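#' Synthetic Gaussian instrument response
#'
#' A Gaussian excitation/detection profile sampled on the channel grid and
#' normalised to unit sum, emulating an IRF measured in a scattering
#' solution. A width at or below the channel spacing collapses to a
#' single-channel spike.
#'
#' @param times uniform channel grid, ns.
#' @param center profile centre, ns; must lie inside the grid.
#' @param fwhm full width at half maximum, ns (> 0, default 0.25).
#' @return An [instrument_response()].
#' @export
make_irf <- function(times, center, fwhm = 0.25) {
  dt <- check_uniform_grid(times)
  if (center < times[1L] || center > times[length(times)])
    stop("IRF centre lies outside the time grid", call. = FALSE)
  if (fwhm <= 0) stop("`fwhm` must be positive", call. = FALSE)
  sigma <- fwhm * FWHM_TO_SIGMA
  y <- exp(-0.5 * ((times - center) / sigma)^2)
  if (sum(y) == 0 || fwhm <= dt) {
    y <- numeric(length(times))
    y[which.min(abs(times - center))] <- 1
  }
  instrument_response(times, y / sum(y))
}

#' Simulate a TCSPC decay with Poisson photon statistics
#'
#' Draws per-channel counts independently from Poisson laws whose means are
#' the [evaluate_model()] expectation scaled so the expected total equals
#' `total_counts`, emulating shot-noise-limited photon counting.
#'
#' @param model generating [decay_model()].
#' @param irf [instrument_response()] to convolve with.
#' @param total_counts expected total photons (>= 1e3).
#' @param seed integer seed; the same seed reproduces the trace exactly.
#' @param times channel grid, defaults to the IRF grid.
#' @return A [decay_trace()].
#' @export
simulate_decay <- function(model, irf, total_counts = 2e6, seed = NULL,
                           times = irf$times) {
  if (total_counts < 1e3)
    stop("`total_counts` must be at least 1e3", call. = FALSE)
  lambda <- evaluate_model(model, irf, times)
  lambda <- lambda * (total_counts / sum(lambda))
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  decay_trace(times, counts)
}

#' Default 12-point twofold serial dilution from 1 uM
#'
#' @param top top concentration, nM (default 1000).
#' @param n_points number of dilutions (default 12).
#' @param factor dilution factor between steps (default 2).
#' @return Concentrations in nM, descending.
#' @export
serial_dilution <- function(top = 1000, n_points = 12L, factor = 2) {
  top / factor^(seq_len(n_points) - 1L)
}

#' Simulate an anisotropy titration
#'
#' Draws replicate anisotropy reads around the depletion + Hill binding
#' curve with additive Gaussian noise, emulating the plate-reader design of
#' several independent dilution series each read multiple times (default
#' 3 series x 5 reads = 15 measurements per concentration). Each series
#' gets a deterministic sub-seed split from `seed`.
#'
#' @param kd,n,r_free,r_bound generating binding parameters (see
#'   [fit_titration()]).
#' @param l_total labeled DNA, nM (default 6).
#' @param conc_nM concentration series; default [serial_dilution()].
#' @param noise_sd additive anisotropy noise SD (default 0.005); used by
#'   the default `"anisotropy"` noise mode.
#' @param n_series,n_reads independent dilution series and reads per series.
#' @param seed integer seed.
#' @param mode `"anisotropy"` (additive Gaussian noise on the anisotropy,
#'   default) or `"counts"` (Poisson shot noise on the polarised
#'   intensities, for stress testing).
#' @param total_counts expected total photon counts per read in `"counts"`
#'   mode.
#' @return Data frame with `conc_nM`, `anisotropy`, `replicate`
#'   (series.read id), `series`; `"counts"` mode adds `i_par` and `i_perp`.
#' @export
simulate_titration <- function(kd, n = 1, r_free = 0.10, r_bound = 0.26,
                               l_total = 6, conc_nM = serial_dilution(),
                               noise_sd = 0.005, n_series = 3L,
                               n_reads = 5L, seed = NULL,
                               mode = c("anisotropy", "counts"),
                               total_counts = 1e5) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  mode <- match.arg(mode)
  theta <- bound_fraction(conc_nM, l_total, kd = kd, n = n)
  mu <- predict_anisotropy(theta, r_free, r_bound)
  seeds <- if (is.null(seed)) rep(list(NULL), n_series)
           else as.list(split_seeds(seed, n_series))
  out <- lapply(seq_len(n_series), function(s) {
    base <- data.frame(conc_nM = rep(conc_nM, each = n_reads),
                       replicate = paste0(s, ".",
                                          rep(seq_len(n_reads),
                                              times = length(conc_nM))),
                       series = s)
    mus <- rep(mu, each = n_reads)
    if (mode == "anisotropy") {
      base$anisotropy <- with_seed(seeds[[s]],
        mus + stats::rnorm(length(mus), 0, noise_sd))
    } else {
      # r = (Ipar - Iperp) / (Ipar + 2 Iperp) inverted at G = 1
      lam_par <- total_counts * (1 + 2 * mus) / 3
      lam_perp <- total_counts * (1 - mus) / 3
      cts <- with_seed(seeds[[s]], list(
        i_par = stats::rpois(length(mus), lam_par),
        i_perp = stats::rpois(length(mus), lam_perp)))
      base$i_par <- cts$i_par
      base$i_perp <- cts$i_perp
      base$anisotropy <- anisotropy(base$i_par, base$i_perp)
    }
    base
  })
  do.call(rbind, out)
}

#' Simulate replicate strand-transfer progress curves
#'
#' Fractions follow the equal-concentration second-order progress curve
#' ([second_order_fraction()]) plus Gaussian noise, clipped to `[0, 1]`,
#' emulating gel-quantified kinetics replicates from independent
#' transpososome preparations.
#'
#' @param k rate constant, per uM per min.
#' @param c0 initial concentration of each reactant, uM.
#' @param timepoints sampling times, minutes.
#' @param noise_sd fraction noise SD (default 0).
#' @param n_reps replicates (default 4).
#' @param seed integer seed.
#' @return Long data frame with `replicate`, `time_min`, `fraction`.
#' @export
simulate_kinetics <- function(k, c0, timepoints, noise_sd = 0,
                              n_reps = 4L, seed = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  mu <- second_order_fraction(k, c0, timepoints)
  seeds <- if (is.null(seed)) rep(list(NULL), n_reps)
           else as.list(split_seeds(seed, n_reps))
  out <- lapply(seq_len(n_reps), function(r) {
    f <- with_seed(seeds[[r]],
                   mu + stats::rnorm(length(mu), 0, noise_sd))
    data.frame(replicate = r, time_min = timepoints,
               fraction = pmin(pmax(f, 0), 1))
  })
  do.call(rbind, out)
}

#' Simulate a disintegration lane pair
#'
#' Builds baseline (immediately after STC purification) and post-treatment
#' lanes whose [disintegration_fraction()] equals `reversal_fraction`
#' exactly in the noise-free case: the baseline lane splits unit signal
#' into residual intact target (`1 - product_share_t0`) and strand-transfer
#' product (`product_share_t0`); treatment re-ligates `reversal_fraction`
#' of the product back into intact target.
#'
#' @param product_share_t0 product share of the baseline lane, in `[0, 1]`.
#' @param reversal_fraction fraction of product reverted, in `[0, 1]`.
#' @param total total lane signal (arbitrary units, default 1).
#' @return A list with named band vectors `t0` and `t`.
#' @export
simulate_disintegration <- function(product_share_t0, reversal_fraction,
                                    total = 1) {
  if (product_share_t0 < 0 || product_share_t0 > 1 ||
      reversal_fraction < 0 || reversal_fraction > 1)
    stop("shares must lie in [0, 1]", call. = FALSE)
  t0 <- c(target = (1 - product_share_t0) * total,
          product = product_share_t0 * total)
  reverted <- product_share_t0 * reversal_fraction
  t1 <- c(target = (1 - product_share_t0 + reverted) * total,
          product = (product_share_t0 - reverted) * total)
  list(t0 = t0, t = t1)
}
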