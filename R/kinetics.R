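#' Fraction of total lane signal in the product band(s)
#'
#' @param bands named numeric vector of band signals (densitometry units,
#'   >= 0) for one gel lane; total must be positive.
#' @param product_labels character vector naming the bands designated as
#'   strand-transfer product; must be a subset of `names(bands)`.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_product <- function(bands, product_labels) {
  check_lane(bands)
  if (!all(product_labels %in% names(bands)))
    stop("product labels missing from the lane: ",
         paste(setdiff(product_labels, names(bands)), collapse = ", "),
         call. = FALSE)
  sum(bands[product_labels]) / sum(bands)
}

check_lane <- function(bands) {
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("lane bands must be a named vector", call. = FALSE)
  if (any(bands < 0)) stop("band signals must be non-negative", call. = FALSE)
  if (sum(bands) <= 0) stop("empty lane: zero total signal", call. = FALSE)
  invisible(bands)
}

#' Per-timepoint mean and SEM across replicate time series
#'
#' @param series long-format data frame with columns `replicate`,
#'   `time_min`, `fraction`; every replicate must share the same timepoint
#'   schedule.
#' @return Data frame with `time_min`, `mean`, `sem` (SD / sqrt(n)), `n`.
#' @export
aggregate_series <- function(series) {
  series <- as.data.frame(series)
  stopifnot(all(c("replicate", "time_min", "fraction") %in% names(series)))
  reps <- split(series, series$replicate)
  if (length(reps) < 2L)
    stop("need at least 2 replicates", call. = FALSE)
  tp <- sort(reps[[1L]]$time_min)
  for (r in reps)
    if (!isTRUE(all.equal(sort(r$time_min), tp)))
      stop("replicates do not share one timepoint schedule", call. = FALSE)
  mat <- vapply(reps, function(r) r$fraction[order(r$time_min)],
                numeric(length(tp)))
  n <- length(reps)
  data.frame(time_min = tp,
             mean = rowMeans(mat),
             sem = apply(mat, 1, stats::sd) / sqrt(n),
             n = n)
}

#' Initial-rate estimate from the steepest pairwise slope
#'
#' Scans all ordered timepoint pairs of a fraction-converted series for the
#' steepest slope `(f_j - f_i) / (t_j - t_i)` and converts it to a
#' second-order rate constant `k = slope / c0` for equal reactant
#' concentrations `c0`. Ties go to the earliest pair (initial-rate
#' semantics). A series that never increases yields `k = 0` with a warning
#' flag.
#'
#' @param time_min timepoints, minutes, strictly increasing, >= 0.
#' @param fraction fraction converted at each timepoint, in `[0, 1]`.
#' @param c0_um initial concentration of each reactant, micromolar (> 0).
#' @return An object of class `"rate_estimate"`: `k` (per uM per min),
#'   `slope` (per min), `pair` (the two timepoints), `c0_um`, and
#'   `flat` (TRUE when no positive slope exists).
#' @export
steepest_slope_rate <- function(time_min, fraction, c0_um) {
  if (length(time_min) < 2L)
    stop("need at least 2 timepoints", call. = FALSE)
  if (any(diff(time_min) <= 0) || any(time_min < 0))
    stop("timepoints must be non-negative and strictly increasing",
         call. = FALSE)
  if (any(fraction < -1e-12) || any(fraction > 1 + 1e-12))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (c0_um <= 0) stop("`c0_um` must be positive", call. = FALSE)
  best <- list(slope = -Inf, pair = c(NA_real_, NA_real_))
  n <- length(time_min)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- (fraction[j] - fraction[i]) / (time_min[j] - time_min[i])
      if (s > best$slope) best <- list(slope = s,
                                       pair = c(time_min[i], time_min[j]))
    }
  }
  flat <- best$slope <= 0
  if (flat) {
    warning("series never increases; rate set to 0", call. = FALSE)
    best$slope <- 0
  }
  structure(list(k = best$slope / c0_um, slope = best$slope,
                 pair = best$pair, c0_um = c0_um, flat = flat),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Steepest-slope initial rate: k = %.4g / uM / min\n", x$k))
  if (x$flat) {
    cat("  (series never increases)\n")
  } else {
    cat(sprintf("  slope %.4g / min between t = %.4g and %.4g min at c0 = %.3g uM\n",
                x$slope, x$pair[1L], x$pair[2L], x$c0_um))
  }
  invisible(x)
}

#' Second-order progress curve (equal reactant concentrations)
#'
#' Fraction converted for irreversible A + B -> P with `[A]0 = [B]0 = c0`:
#' `f(t) = k c0 t / (1 + k c0 t)`, monotone in `t` with limit 1.
#'
#' @param k rate constant, per uM per min (>= 0).
#' @param c0 initial concentration of each reactant, uM (>= 0).
#' @param t time(s), minutes (>= 0).
#' @return Fraction(s) converted in `[0, 1)`.
#' @export
second_order_fraction <- function(k, c0, t) {
  if (k < 0 || c0 < 0 || any(t < 0))
    stop("`k`, `c0` and `t` must be non-negative", call. = FALSE)
  x <- k * c0 * t
  x / (1 + x)
}

#' Time to reach a given conversion under second-order kinetics
#'
#' Inverse of [second_order_fraction()]: `t = f / (k c0 (1 - f))`.
#'
#' @param k rate constant, per uM per min (> 0).
#' @param c0 initial concentration of each reactant, uM (> 0).
#' @param f target fraction converted, in `[0, 1)`.
#' @return Time in minutes.
#' @export
second_order_time <- function(k, c0, f) {
  if (k <= 0 || c0 <= 0)
    stop("`k` and `c0` must be positive", call. = FALSE)
  if (any(f < 0) || any(f >= 1))
    stop("`f` must lie in [0, 1)", call. = FALSE)
  f / (k * c0 * (1 - f))
}

#' Fraction of strand-transfer product reverted by disintegration
#'
#' Compares a lane sampled immediately after STC purification (`bands_t0`,
#' the baseline of residual unreacted target) with a lane after treatment
#' (`bands_t`). Both lanes are normalised to their totals; the growth of the
#' intact-target share relative to the initial product share is the fraction
#' of strand-transfer product that became re-ligated:
#' `(target_share(t) - target_share(t0)) / product_share(t0)`,
#' clipped to `[0, 1]`.
#'
#' @param bands_t0,bands_t named numeric band-signal vectors for the
#'   baseline and treated lanes.
#' @param target_label name of the intact (re-ligated) target band.
#' @param product_labels names of the strand-transfer product band(s).
#' @return Fraction reverted, in `[0, 1]`.
#' @export
disintegration_fraction <- function(bands_t0, bands_t,
                                    target_label = "target",
                                    product_labels = "product") {
  check_lane(bands_t0)
  check_lane(bands_t)
  for (b in list(bands_t0, bands_t))
    if (!all(c(target_label, product_labels) %in% names(b)))
      stop("both lanes must contain the target and product bands",
           call. = FALSE)
  share0 <- bands_t0 / sum(bands_t0)
  share1 <- bands_t / sum(bands_t)
  prod0 <- sum(share0[product_labels])
  if (prod0 <= 0)
    stop("no strand-transfer product in the baseline lane", call. = FALSE)
  min(max((share1[[target_label]] - share0[[target_label]]) / prod0, 0), 1)
}

#' Percent of total lane signal in the single-ended product band
#'
#' Single-ended strand-transfer events produce a diagnostic short product
#' (the 58 nt band on the hairpin target); its share of the total lane
#' radioactivity, in percent, reports how concerted the reaction is.
#'
#' @param bands named numeric band-signal vector for one lane.
#' @param single_ended_label name of the single-ended product band; must be
#'   present in the lane.
#' @return Percent of total signal, in `[0, 100]`.
#' @export
single_ended_fraction <- function(bands, single_ended_label = "58nt") {
  check_lane(bands)
  if (!single_ended_label %in% names(bands))
    stop("band `", single_ended_label, "` not found in lane", call. = FALSE)
  100 * bands[[single_ended_label]] / sum(bands)
}
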