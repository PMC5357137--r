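#' FRET efficiency from donor lifetimes
#'
#' Energy transfer quenches the donor: `E = 1 - tau_DA / tau_D`, where
#' `tau_DA` is the donor lifetime in the presence of the acceptor and
#' `tau_D` the unquenched donor lifetime.
#'
#' @param tau_da donor lifetime with acceptor, ns; `0 < tau_da <= tau_d`.
#' @param tau_d unquenched donor lifetime, ns.
#' @return Efficiency in `[0, 1)`.
#' @export
efficiency_from_lifetimes <- function(tau_da, tau_d) {
  if (any(tau_da <= 0) || any(tau_d <= 0))
    stop("lifetimes must be positive", call. = FALSE)
  if (any(tau_da > tau_d))
    stop("negative efficiency: tau_DA exceeds tau_D; check that the ",
         "control (donor-only) lifetime is assigned to tau_d", call. = FALSE)
  1 - tau_da / tau_d
}

#' Donor-acceptor distance from FRET efficiency
#'
#' Inverts the Forster relation: `r = R0 * (1/E - 1)^(1/6)`, with 50%
#' efficiency at the Forster radius. The default radius of 69 Angstrom is
#' appropriate for the Atto565/Atto647N pair.
#'
#' @param e efficiency, strictly inside (0, 1).
#' @param r0 Forster radius, Angstrom (default 69).
#' @return Distance in Angstrom, strictly decreasing in `e`.
#' @export
distance_from_efficiency <- function(e, r0 = 69) {
  if (any(e <= 0) || any(e >= 1))
    stop("efficiency must lie strictly in (0, 1)", call. = FALSE)
  if (r0 <= 0) stop("`r0` must be positive", call. = FALSE)
  r0 * (1 / e - 1)^(1 / 6)
}

#' FRET efficiency at a given donor-acceptor distance
#'
#' `E = 1 / (1 + (r/R0)^6)`; inverse of [distance_from_efficiency()].
#'
#' @param r distance, Angstrom (> 0).
#' @param r0 Forster radius, Angstrom (default 69).
#' @return Efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(r, r0 = 69) {
  if (any(r <= 0) || r0 <= 0)
    stop("distances must be positive", call. = FALSE)
  1 / (1 + (r / r0)^6)
}

#' End-to-end extension of straight B-form DNA
#'
#' `n_bp * rise`: the contour length of an unbent duplex, used as the
#' fluorophore separation expected in the absence of bending. The
#' `n_bp * rise` convention (rather than `(n_bp - 1) * rise`) treats the
#' labels as sitting one helical rise beyond the terminal base pairs.
#'
#' @param n_bp number of base pairs (>= 2).
#' @param rise helical rise per base pair, Angstrom (default 3.4).
#' @return Length in Angstrom.
#' @export
bdna_extension <- function(n_bp, rise = 3.4) {
  if (any(n_bp < 2)) stop("`n_bp` must be at least 2", call. = FALSE)
  if (rise <= 0) stop("`rise` must be positive", call. = FALSE)
  n_bp * rise
}

#' Bent-DNA population fraction from a decay fit
#'
#' The Gaussian (FRET-active, lifetime-shortened) amplitude fraction of a
#' fitted decay is the molar fraction of target DNA held in the bent
#' conformation.
#'
#' @param fit a `"decay_fit"` (or the `sample` fit of a `"two_step_fit"`).
#' @return Fraction in `[0, 1]`.
#' @export
bent_fraction <- function(fit) {
  if (inherits(fit, "two_step_fit")) fit <- fit$sample
  if (!inherits(fit, "decay_fit"))
    stop("`fit` must be a decay_fit or two_step_fit", call. = FALSE)
  unname(fit$fractions[["gaussian"]])
}

#' FRET summary for a fitted sample/control pair
#'
#' Combines a two-step fit into efficiency, distance and bent fraction:
#' the Gaussian centre is the quenched donor lifetime, the held discrete
#' lifetime the unquenched one.
#'
#' @param fit a `"two_step_fit"`.
#' @param r0 Forster radius, Angstrom (default 69).
#' @return A list with `efficiency`, `distance` (Angstrom), `bent_fraction`,
#'   `tau_da`, and `tau_d`.
#' @export
fret_result <- function(fit, r0 = 69) {
  stopifnot(inherits(fit, "two_step_fit"))
  tau_da <- fit$sample$model$tau_g
  tau_d <- fit$tau_donor
  e <- efficiency_from_lifetimes(min(tau_da, tau_d), tau_d)
  list(efficiency = e,
       distance = if (e > 0) distance_from_efficiency(e, r0) else Inf,
       bent_fraction = bent_fraction(fit),
       tau_da = tau_da, tau_d = tau_d)
}
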