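---
title: "Models and methods: quantifying target-DNA bending, binding, and strand transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying target-DNA bending, binding, and strand transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpofit)
```

`transpofit` implements the quantitative analyses used to study how DNA
transpososomes (the tetrameric transposase-DNA machines of phage Mu and its
relatives) capture, bend, and react with target DNA. Three experimental
observables drive the package: time-correlated single photon counting
(TCSPC) fluorescence decays that report DNA bending through FRET,
fluorescence anisotropy titrations that report binding affinity, and gel
band intensities that report strand-transfer chemistry over time. Each has
a fitting or estimation stage, and each stage has a seeded simulator that
generates data with the statistical structure the estimator assumes, so
every estimator in the package is validated by parameter recovery.

## TCSPC reconvolution with a Gaussian lifetime distribution

A TCSPC measurement histograms photon arrival delays into uniform channels
(time in ns against counts). The measured histogram is the true
fluorescence impulse response convolved with the instrument response
function (IRF), so lifetimes are fit by *forward reconvolution*: a model
impulse response is convolved with the measured IRF and compared with the
data, rather than deconvolving the data.

The impulse response is a mixture of

* one **discrete lifetime** $\tau_{disc}$ with pre-exponential amplitude
  $\alpha_{disc}$ — the unquenched donor on unbound or unbent DNA;
* one **Gaussian distribution of lifetimes** with centre $\tau_c$, full
  width at half maximum $w$, and amplitude $\alpha_{g}$ — the
  FRET-quenched donor population on bent DNA, whose spread of
  donor-acceptor distances maps to a spread of lifetimes;
* optionally a **short-lifetime nuisance** component (lifetime bounded at
  0.8 ns) absorbing the minor population of very short lifetimes that
  instrumentation artifacts and anomalous fluorophore behaviour produce in
  control samples;
* a constant baseline and an optional sub-channel IRF shift.

The Gaussian distribution is discretised by `discretize_gaussian()` into 61
nodes spanning $\pm 3\sigma$ (with $\sigma = w / 2\sqrt{2\ln 2}$) with
trapezoid weights, truncated at a 0.01 ns lifetime floor and renormalised.
61 nodes over $\pm 3\sigma$ resolve widths down to about 0.1 ns without
dominating the cost of a model evaluation; a width below $10^{-3}$ ns
collapses to a single node. `evaluate_model()` performs the discrete causal
convolution of the unit-sum IRF with the node mixture via FFT.

### Fitting choices

* **Weighting.** Neyman $\chi^2$ with per-channel weights
  $1/\max(c_i, 1)$ — standard TCSPC practice that avoids dividing by zero
  in empty channels. A caveat follows from the same choice: in channels
  expecting fewer than roughly 50 photons the statistic is biased upward
  (observed counts underestimate the variance when they fluctuate low), so
  the reduced $\chi^2$ of a correct model is calibrated near 1 only when
  the fit window is well populated. The calibration test in the suite
  therefore uses a window whose channels carry ample counts; on long
  sparse tails a correct fit can legitimately show reduced $\chi^2$ of
  1.1-1.2.
* **Fit window.** From the channel where the IRF rises through 1% of its
  peak to the last channel with at least 5 counts (both configurable):
  excludes pre-pulse noise and the empty tail.
* **Optimiser.** Levenberg-Marquardt (`minpack.lm::nls.lm`) with box
  bounds: lifetimes in [0.05, 20] ns, width in [0.05, 10] ns, amplitudes
  and baseline non-negative, nuisance lifetime at most 0.8 ns — the
  physical range for these dyes on this instrument class. Fits restart
  from jittered starting points (deterministic given the seed) and keep
  the best $\chi^2$.
* **Parsimony tie-break.** When two starting points end within 0.1%
  relative $\chi^2$ of each other, the solution with the smaller Gaussian
  amplitude share wins. This matters in the degenerate case where the
  Gaussian centre drifts onto the discrete lifetime: a sample containing
  no FRET population can then be fit equally well by any amplitude split,
  and the tie-break keeps the spurious component at zero rather than
  reporting an arbitrary split.
* **IRF shift.** Implemented by linear interpolation and held at 0 by
  default; it can be freed, but none of the shipped protocols require it.

### The two-step protocol

Bound-state samples contain both unbound/unbent DNA (donor at its full
lifetime) and bent DNA (shortened lifetimes). Fitting both populations
freely from one decay is poorly conditioned, so `two_step_fit()` mirrors
the constrained protocol used with paired control samples:

1. fit the DNA-only control with the discrete lifetime free (plus the
   nuisance component); the control must not be dominated by the nuisance
   — if more than half its photons fit to the short-lifetime component the
   function raises a control-quality error;
2. fit the transpososome sample with the discrete lifetime *held* at the
   step-1 value and the Gaussian component free.

The Gaussian amplitude fraction of the step-2 fit is the **bent fraction**
(`bent_fraction()`): component fractions are computed on the
pre-exponential amplitudes, which report molar populations. Photon
(intensity) shares, which weight each amplitude by its lifetime, are
available through `intensity_fractions()`; the nuisance quality gate uses
photon shares because the population it guards against is defined by its
share of detected photons.

Parameter recovery at the simulated study scale ($2 \times 10^6$ photons,
0.05 ns channels, 0.25 ns fwhm IRF; donor 4.0 ns at molar fraction 0.4,
Gaussian centre 3.3 ns, fwhm 1.0 ns, fraction 0.6) returns the centre with
bias under 2% and dispersion under 5%. The donor lifetime used as
simulation truth, 4.0 ns, is a plausible unquenched lifetime for this
donor dye; recovery results are insensitive to the exact choice.

## FRET conversions

With the unquenched donor lifetime $\tau_D$ from step 1 and the quenched
centre $\tau_{DA}$ from step 2,

$$E = 1 - \tau_{DA}/\tau_D, \qquad r = R_0 (1/E - 1)^{1/6},$$

with $R_0 = 69$ Å for this Atto565/Atto647N dye pair. The conversions are
exact inverses of each other, and `bdna_extension()` provides the straight
B-DNA sanity bound: an unbent 35 bp target at the canonical 3.4 Å/bp rise
spans $35 \times 3.4 = 119$ Å, far outside the Forster-sensitive range, so
any detected transfer implies bending. The $n_{bp} \times rise$ convention
(not $(n_{bp}-1) \times rise$) is a deliberate, documented choice — it
treats the terminal labels as sitting one rise beyond the final base
pairs; linker length is not modelled.

## Anisotropy titrations: depletion + Hill binding

Anisotropy reports binding because the bound complex tumbles slowly.
`anisotropy()` applies the standard polarisation algebra with a scalar
G factor ($r = (I_\parallel - G I_\perp)/(I_\parallel + 2 G I_\perp)$);
per-well plate corrections are out of scope. The observable is modelled as
the linear mixture $r = r_{free} + \theta (r_{bound} - r_{free})$.

At a labeled-DNA concentration (6 nM) comparable to the dissociation
constants being measured, free and total protein differ materially, so the
occupancy $\theta$ must account for **receptor depletion**. The titrations
also show **cooperativity**, described phenomenologically by a Hill
coefficient (the mechanistic source — transient complex disassembly at low
concentration — is not modelled). The two features are combined in one
place, `bound_fraction()`, as Hill-shaped occupancy with mass conservation
on a 1:1 complex:

$$\theta = \frac{C_{free}^n}{K_D^n + C_{free}^n}, \qquad
  C_{free} = C_T - \theta L_T,$$

solved by bracketed root search (tolerance $10^{-12}$; the bracket
$[0, \min(1, C_T/L_T)]$ always contains exactly one root). For $n = 1$
this reproduces the closed-form depletion quadratic to $10^{-9}$, which the
test suite checks against an independently coded quadratic. Protein is
quantified as tetramer (the complex is the binding species), in nM.

`fit_titration()` fits $(K_D, n, r_{free}, r_{bound})$ by unweighted least
squares on the replicate-mean anisotropy per concentration (no weighting
scheme is imposed on the raw reads), with both anisotropy endpoints
floated — holding either would presume knowledge the data can supply.
`hill = 1` holds the Hill coefficient for non-cooperative fits. Confidence
intervals come from a parametric bootstrap (default 200 seeded resamples of
the mean curve at the residual SD) rather than curvature-based standard
errors, because $K_D$ and $n$ are strongly correlated on steep curves.

The simulator's defaults are the study design: 12-point twofold serial
dilution from 1 µM, 3 independent series each read 5 times (15 measurements
per concentration), additive Gaussian anisotropy noise with SD 0.005. The
noise level is a documented estimate of plate-reader repeatability (the
source experiments report confidence intervals, not raw SDs); a
counts-level mode with Poisson noise on $I_\parallel, I_\perp$ is available
for stress testing. Under these conditions the $K_D$ estimator's median
absolute relative error is below 10%, and recovery of every fitted
condition (15 nM with Hill 3.3, 15 nM with Hill 2.6, 29 nM, 38 nM) stays
within 15% ($K_D$) and 20% (Hill).

## Strand-transfer kinetics and band bookkeeping

Gel lanes are consumed as band-label/signal tables; image densitometry is
upstream of the package. `fraction_product()` is the share of total lane
signal in caller-designated product bands — the package imposes no band
taxonomy, so minor products are included exactly when the caller lists
them.

Progress curves are modelled as irreversible second-order kinetics with
equal reactant concentrations ($c_0$ = 0.1 µM of transpososome and of
target DNA in the reference design):

$$f(t) = \frac{k c_0 t}{1 + k c_0 t},$$

with closed-form time inverse $t = f / (k c_0 (1 - f))$. The initial-rate
estimator `steepest_slope_rate()` follows the steepest-slope rule: the
maximum of $\Delta f / \Delta t$ over **all ordered timepoint pairs** (not
only consecutive ones), ties broken toward the earlier pair — initial-rate
semantics. The slope is divided by $c_0$ of the limiting species to give
$k$ in µM⁻¹ min⁻¹; with both reactants at the same concentration the
choice of species is immaterial. Because the estimator reads a finite
difference on a convex-decreasing rate, it underestimates $k$ slightly at
finite sampling intervals (by 2.9% with a first interval of 0.1 min at
$k c_0 = 0.3$ min⁻¹) and converges to the true rate as the earliest
interval shrinks. A series that never increases returns $k = 0$ with a
warning flag rather than an error. Timepoint schedules are arguments
throughout, since sampling design varies by condition.

`disintegration_fraction()` quantifies reversal of strand transfer: both
lanes are normalised to their totals, the baseline lane (sampled
immediately after complex purification) supplies the residual
unreacted-target share to subtract, and the growth of the intact-target
share relative to the initial product share — clipped to $[0, 1]$ — is the
fraction of product re-ligated. `single_ended_fraction()` reports one
diagnostic band's percent of total lane signal.

## Synthetic data: what it does and does not emulate

Each simulator is a bit-reproducible function of its parameters and seed;
replicate-level sub-seeds are split deterministically from one parent
stream so individual replicates can be reproduced in isolation.

* `simulate_decay()` draws independent per-channel Poisson counts around
  the convolved model — genuine shot-noise statistics, but no detector
  dead time, pile-up, after-pulsing, or dye photophysics beyond
  single-exponential donors.
* `simulate_titration()` adds Gaussian noise on the anisotropy (or Poisson
  noise on polarised counts); it does not model quantum-yield changes on
  binding, well-position artifacts, or drift between series.
* `simulate_kinetics()` adds truncated Gaussian noise to the progress
  curve; it does not model gel loading variation as a correlated error.
* `simulate_disintegration()` builds exact lane pairs for the reversal
  bookkeeping; no densitometry noise.

Passing recovery tests on these simulations therefore demonstrates that
the estimators are correct and well calibrated *under the stated noise
models at the stated designs* — not that real instruments lack systematic
errors the models omit.

## Numerical notes and limitations

* The FFT convolution can leave values of order $-10^{-12}$ before the IRF
  rise; they are clamped at zero so Poisson simulation and baselines stay
  valid.
* Decay files follow the deposited two-column tab-delimited dialect (time
  in ns, counts), optional `#` comments; grids are taken from the file and
  must be uniform. When building grids in code, 0.05 ns channels over
  50 ns are used throughout the examples and tests; any uniform grid
  (e.g. 4096 channels of 0.0122 ns) works.
* The reconvolution model is limited to one discrete + one Gaussian
  component (plus the nuisance term): multi-Gaussian mixtures,
  stretched exponentials, maximum-entropy inversion, and time-resolved
  anisotropy decays are out of scope.
* Binding fits assume equilibrium and a single labeled species;
  competitive or kinetic binding schemes are not modelled.
* Degenerate inputs fail loudly: all-zero traces, empty lanes, flat
  titrations, and zero-amplitude models raise classified errors rather
  than returning numbers.
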