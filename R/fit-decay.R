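DECAY_PAR_NAMES <- c("tau_disc", "alpha_disc", "tau_g", "fwhm_g", "alpha_g",
                     "baseline", "shift", "tau_nuis", "alpha_nuis")

# physical box bounds for these dyes / this instrument class
DECAY_LOWER <- c(tau_disc = 0.05, alpha_disc = 0, tau_g = 0.05,
                 fwhm_g = 0.05, alpha_g = 0, baseline = 0, shift = -5,
                 tau_nuis = 0.05, alpha_nuis = 0)
DECAY_UPPER <- c(tau_disc = 20, alpha_disc = Inf, tau_g = 20, fwhm_g = 10,
                 alpha_g = Inf, baseline = Inf, shift = 5, tau_nuis = 0.8,
                 alpha_nuis = Inf)

model_to_par <- function(model) {
  unlist(model[DECAY_PAR_NAMES])
}

par_to_model <- function(par) {
  structure(as.list(par[DECAY_PAR_NAMES]), class = "decay_model")
}

#' Default fit window for a reconvolution fit
#'
#' Channels from the point where the IRF rises through 1% of its peak to the
#' last channel holding at least `min_counts` photons: excludes pre-pulse
#' noise and the empty tail.
#'
#' @param trace a [decay_trace()].
#' @param irf the paired [instrument_response()].
#' @param min_counts tail cutoff in counts (default 5).
#' @return Integer vector of channel indices.
#' @export
fit_window <- function(trace, irf, min_counts = 5) {
  first <- which(irf$counts >= 0.01 * max(irf$counts))[1L]
  last <- max(which(trace$counts >= min_counts))
  if (last <= first)
    stop("empty fit window: trace has no populated channels past the IRF rise",
         call. = FALSE)
  seq.int(first, last)
}

#' Fit a TCSPC decay by forward reconvolution
#'
#' Minimises the Neyman chi-square (per-channel weights `1/max(counts, 1)`)
#' between the measured decay and the convolution forward model
#' ([evaluate_model()]) over the free parameters, holding any parameter
#' named in `fixed` at its starting value. Levenberg-Marquardt with box
#' bounds does the minimisation, restarted from jittered starting points;
#' the best chi-square wins, with ties (relative chi-square within 0.1%)
#' broken toward the smaller Gaussian amplitude so a component the data do
#' not need is not invented.
#'
#' @param trace a [decay_trace()]; total photons of 1e4 or more are needed
#'   for a meaningful fit (less raises a warning).
#' @param irf the paired [instrument_response()], same grid as `trace`.
#' @param start a [decay_model()] of starting values.
#' @param fixed character vector of parameter names to hold at their
#'   starting values. Defaults to holding the IRF shift and the nuisance
#'   component (off).
#' @param window integer channel indices to fit, default [fit_window()].
#' @param restarts number of additional jittered starting points
#'   (default 3); deterministic given `seed`.
#' @param seed integer seed for the restart jitter.
#' @param extra_starts optional list of additional `decay_model` starting
#'   points to try as-is.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return An object of class `"decay_fit"`: fitted `model`, `fixed` names,
#'   `reduced_chi_square`, amplitude `fractions`, standard errors `se`,
#'   `converged` flag, the fit `window`, full-grid `fitted` values, and the
#'   input data.
#' @export
fit_decay <- function(trace, irf, start, fixed = c("shift", "tau_nuis",
                                                   "alpha_nuis"),
                      window = NULL, restarts = 3L, seed = 1L,
                      extra_starts = NULL, maxiter = 200L) {
  stopifnot(inherits(trace, "decay_trace"),
            inherits(irf, "instrument_response"))
  validate_decay_model(start)
  if (sum(trace$counts) == 0)
    stop("all-zero decay trace", call. = FALSE)
  if (sum(trace$counts) < 1e4)
    warning("fewer than 1e4 photons: fit may be unreliable", call. = FALSE)
  if (length(trace$times) != length(irf$times))
    stop("trace and IRF must share one channel grid", call. = FALSE)
  fixed <- match.arg(fixed, DECAY_PAR_NAMES, several.ok = TRUE)
  if (is.null(window)) window <- fit_window(trace, irf)

  free <- setdiff(DECAY_PAR_NAMES, fixed)
  if (length(free) == 0L) stop("no free parameters", call. = FALSE)
  par0 <- model_to_par(start)
  w <- sqrt(1 / pmax(trace$counts[window], 1))
  obs <- trace$counts[window]

  resid_fn <- function(p_free) {
    par <- par0
    par[free] <- p_free
    y <- evaluate_model(par_to_model(par), irf, trace$times)
    (obs - y[window]) * w
  }

  starts <- list(par0[free])
  if (!is.null(extra_starts))
    for (s in extra_starts) starts <- c(starts, list(model_to_par(s)[free]))
  if (restarts > 0L) {
    jit <- with_seed(seed, lapply(seq_len(restarts), function(i) {
      p <- par0[free]
      pos <- p > 0 & is.finite(p)
      p[pos] <- p[pos] * exp(stats::rnorm(sum(pos), 0, 0.1))
      if ("shift" %in% free)
        p["shift"] <- p["shift"] + stats::runif(1, -0.5, 0.5)
      p
    }))
    starts <- c(starts, jit)
  }

  best <- NULL
  for (p_start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p_start, fn = resid_fn,
                         lower = DECAY_LOWER[free], upper = DECAY_UPPER[free],
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, maxfev = 100000,
                           ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chisq <- sum(fit$fvec^2)
    take <- is.null(best) || chisq < best$chisq * (1 - 1e-3)
    if (!take && !is.null(best) && chisq < best$chisq * (1 + 1e-3)) {
      # near-tied chi-square: prefer the more parsimonious solution
      gf_new <- gauss_share(par0, free, fit$par)
      gf_old <- gauss_share(par0, free, best$fit$par)
      take <- gf_new < gf_old
    }
    if (take) best <- list(fit = fit, chisq = chisq)
  }
  if (is.null(best))
    stop("reconvolution fit failed from every starting point", call. = FALSE)

  fit <- best$fit
  par <- par0
  par[free] <- fit$par
  model <- par_to_model(par)
  dof <- length(window) - length(free)
  redchi2 <- best$chisq / max(dof, 1L)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("reconvolution fit did not converge: ", fit$message,
            call. = FALSE)

  se <- rep(NA_real_, length(free))
  names(se) <- free
  cv <- tryCatch(solve(fit$hessian) * redchi2, error = function(e) NULL)
  if (!is.null(cv)) {
    d <- diag(cv)
    se[d >= 0] <- sqrt(d[d >= 0])
  }

  structure(list(model = model, fixed = fixed,
                 reduced_chi_square = redchi2,
                 fractions = amplitude_fractions(model),
                 se = se, converged = converged, info = fit$info,
                 message = fit$message, niter = fit$niter,
                 window = window,
                 fitted = evaluate_model(model, irf, trace$times),
                 trace = trace, irf = irf, dof = dof),
            class = "decay_fit")
}

gauss_share <- function(par0, free, p_free) {
  par <- par0
  par[free] <- p_free
  tot <- par["alpha_disc"] + par["alpha_g"]
  if (tot <= 0) return(0)
  unname(par["alpha_g"] / tot)
}

#' Two-step constrained reconvolution protocol
#'
#' Step 1 fits a transpososome-free (DNA-only, unquenched donor) control
#' with a free discrete lifetime plus a short-lifetime nuisance component
#' (lifetime bounded at 0.8 ns) absorbing the minor population of very short
#' lifetimes from instrumentation imperfections and anomalous fluorophore
#' behaviour. Step 2 fits the transpososome sample with the discrete
#' lifetime held at the step-1 value and the Gaussian lifetime distribution
#' free, so the distribution captures only the FRET-shortened (bent)
#' population.
#'
#' @param control DNA-only [decay_trace()].
#' @param sample transpososome-containing [decay_trace()].
#' @param irf shared [instrument_response()].
#' @param nuisance include the short-lifetime nuisance component in the
#'   control fit (default TRUE).
#' @param start_control,start_sample optional [decay_model()] starting
#'   values; sensible data-driven defaults otherwise.
#' @param restarts,seed,maxiter passed to [fit_decay()].
#' @return An object of class `"two_step_fit"`: a list with `control` and
#'   `sample` decay fits and the control-derived `tau_donor`.
#' @export
two_step_fit <- function(control, sample, irf, nuisance = TRUE,
                         start_control = NULL, start_sample = NULL,
                         restarts = 2L, seed = 1L, maxiter = 200L) {
  if (is.null(start_control)) start_control <- initial_decay_model(control)
  if (nuisance) {
    start_control$alpha_nuis <- 0.05 * start_control$alpha_disc
    start_control$tau_nuis <- 0.3
  } else {
    start_control$alpha_nuis <- 0
  }
  fixed_control <- c("tau_g", "fwhm_g", "alpha_g", "shift",
                     if (!nuisance) c("tau_nuis", "alpha_nuis"))
  ctrl_fit <- fit_decay(control, irf, start_control, fixed = fixed_control,
                        restarts = restarts, seed = seed, maxiter = maxiter)

  if (nuisance && ctrl_fit$model$alpha_nuis > 0) {
    shares <- intensity_fractions(ctrl_fit$model)
    if (shares[["nuisance"]] > 0.5)
      stop("control-quality error: more than half the control photons fit ",
           "to the short-lifetime nuisance component", call. = FALSE)
  }

  tau_donor <- ctrl_fit$model$tau_disc
  if (is.null(start_sample)) {
    start_sample <- initial_decay_model(sample)
    a <- start_sample$alpha_disc
    start_sample$alpha_disc <- 0.5 * a
    start_sample$alpha_g <- 0.5 * a
  }
  start_sample$tau_disc <- tau_donor
  start_sample$tau_g <- max(0.75 * tau_donor, 0.1)
  start_sample$fwhm_g <- 1
  start_sample$alpha_nuis <- 0
  # a near-null start lets the fit keep the Gaussian absent when the sample
  # carries no FRET population
  null_start <- start_sample
  null_start$alpha_g <- 1e-3 * start_sample$alpha_disc
  samp_fit <- fit_decay(sample, irf, start_sample,
                        fixed = c("tau_disc", "shift", "tau_nuis",
                                  "alpha_nuis"),
                        restarts = restarts, seed = seed + 1L,
                        extra_starts = list(null_start), maxiter = maxiter)

  structure(list(control = ctrl_fit, sample = samp_fit,
                 tau_donor = tau_donor),
            class = "two_step_fit")
}

# Crude data-driven starting model: tail-weighted mean arrival time past the
# peak approximates the dominant lifetime; baseline from the last channels.
initial_decay_model <- function(trace) {
  pk <- which.max(trace$counts)
  n <- length(trace$counts)
  tail_idx <- seq.int(max(pk, n - max(16L, n %/% 50L)), n)
  b0 <- stats::median(trace$counts[tail_idx])
  post <- seq.int(pk, n)
  cts <- pmax(trace$counts[post] - b0, 0)
  tau0 <- sum(cts * (trace$times[post] - trace$times[pk])) / max(sum(cts), 1)
  tau0 <- min(max(tau0, 0.5), 15)
  decay_model(tau_disc = tau0, alpha_disc = max(trace$counts),
              alpha_g = 0, baseline = max(b0, 0))
}

#' @export
print.decay_fit <- function(x, ...) {
  m <- x$model
  cat("Reconvolution decay fit",
      if (!x$converged) "(NOT converged)", "\n")
  held <- function(nm) if (nm %in% x$fixed) " (held)" else ""
  cat(sprintf("  discrete : tau = %.4g ns%s, fraction %.3f\n",
              m$tau_disc, held("tau_disc"), x$fractions[["discrete"]]))
  if (m$alpha_g > 0)
    cat(sprintf("  gaussian : centre %.4g ns, fwhm %.4g ns, fraction %.3f\n",
                m$tau_g, m$fwhm_g, x$fractions[["gaussian"]]))
  if (m$alpha_nuis > 0)
    cat(sprintf("  nuisance : tau = %.4g ns (photon share %.3f)\n",
                m$tau_nuis, intensity_fractions(m)[["nuisance"]]))
  cat(sprintf("  baseline %.4g, reduced chi-square %.3f (%d channels)\n",
              m$baseline, x$reduced_chi_square, length(x$window)))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  free <- setdiff(DECAY_PAR_NAMES, object$fixed)
  est <- model_to_par(object$model)
  tab <- data.frame(estimate = est,
                    se = NA_real_,
                    held = DECAY_PAR_NAMES %in% object$fixed,
                    row.names = DECAY_PAR_NAMES)
  tab[free, "se"] <- object$se[free]
  out <- list(parameters = tab,
              fractions = object$fractions,
              reduced_chi_square = object$reduced_chi_square,
              dof = object$dof, converged = object$converged)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat("Reconvolution decay fit summary\n")
  print(round(x$parameters[, c("estimate", "se")], 5))
  cat(sprintf("fractions: discrete %.3f / gaussian %.3f\n",
              x$fractions[["discrete"]], x$fractions[["gaussian"]]))
  cat(sprintf("reduced chi-square %.4f on %d dof; converged: %s\n",
              x$reduced_chi_square, x$dof, x$converged))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) model_to_par(object$model)

#' @export
fitted.decay_fit <- function(object, ...) object$fitted

#' @export
residuals.decay_fit <- function(object, type = c("pearson", "response"),
                                ...) {
  type <- match.arg(type)
  r <- object$trace$counts - object$fitted
  if (type == "pearson")
    r <- r / sqrt(pmax(object$trace$counts, 1))
  r[object$window]
}

#' @export
predict.decay_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  evaluate_model(object$model, object$irf, times)
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  total <- sum(object$trace$counts)
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_decay(object$model, object$irf, total_counts = total,
                   times = object$trace$times)))
}

#' @export
plot.decay_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  t <- x$trace$times
  graphics::plot(t, pmax(x$trace$counts, 0.5), log = "y", pch = ".",
                 xlab = "", ylab = "counts", ...)
  graphics::lines(t, pmax(x$fitted, 0.5), col = 2, lwd = 1.5)
  graphics::abline(v = t[range(x$window)], lty = 3)
  graphics::par(mar = c(4, 4, 0, 1))
  graphics::plot(t[x$window], residuals(x), type = "l",
                 xlab = "time (ns)", ylab = "weighted resid.")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
print.two_step_fit <- function(x, ...) {
  cat("Two-step constrained reconvolution fit\n")
  cat(sprintf("step 1 (control): donor lifetime %.4g ns\n", x$tau_donor))
  print(x$control)
  cat("step 2 (sample, donor lifetime held):\n")
  print(x$sample)
  invisible(x)
}
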