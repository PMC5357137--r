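# transpofit

Quantitative analysis of how DNA transpososomes — the tetrameric
transposase-DNA complexes of phage Mu and related mobile elements —
capture, bend, and react with target DNA. Transposition chemistry requires
the target duplex to be sharply bent, which makes bending an energetic
gatekeeper of target choice and of the irreversibility of strand transfer.
`transpofit` implements the three analyses that quantify this picture from
fluorescence and gel data:

1. **TCSPC-FRET lifetime deconvolution.** Donor fluorescence decays are
   fit by forward reconvolution of the measured instrument response with a
   mixture of one discrete lifetime (unbent/unbound DNA, unquenched donor)
   and one Gaussian *distribution* of lifetimes (the FRET-quenched, bent
   population). A two-step protocol first fixes the donor lifetime on a
   DNA-only control, then frees only the Gaussian component on
   transpososome samples; the Gaussian amplitude fraction is the molar
   bent-DNA fraction. Lifetimes convert to FRET efficiency
   `E = 1 - tau_DA/tau_D` and distance `r = R0 (1/E - 1)^(1/6)`
   (R0 = 69 Å for Atto565/Atto647N).
2. **Anisotropy binding titrations.** Occupancy of the labeled target
   follows a Hill curve in *free* protein with mass conservation on a 1:1
   complex (receptor depletion at 6 nM labeled DNA):
   `theta = C_free^n / (K_D^n + C_free^n)`, `C_free = C_T - theta L_T`,
   solved by bracketed root search and fit to replicate-mean anisotropies
   with bootstrap confidence intervals.
3. **Strand-transfer kinetics from gel band tables.** Fraction-product
   time courses follow equal-concentration second-order kinetics
   `f(t) = k c0 t / (1 + k c0 t)`; the initial rate is the steepest slope
   over all ordered timepoint pairs divided by `c0` (µM⁻¹ min⁻¹).
   Disintegration (reversal of strand transfer) and single-ended-event
   fractions are computed from normalised lane shares.

Seeded simulators (`simulate_decay`, `simulate_titration`,
`simulate_kinetics`, `simulate_disintegration`) generate every input the
fitting stages consume, so the whole pipeline is testable by parameter
recovery without any instrument data. Readers/writers cover the deposited
two-column decay format and headered titration, lane, and series tables.

The package is aimed at biophysicists analysing TCSPC lifetime-distribution
FRET, plate-reader anisotropy titrations in the depletion regime, or
gel-quantified reaction kinetics — inside or outside the transposition
field.

## Worked example

Simulate a bound-state measurement at study scale (2×10⁶ photons, 0.05 ns
channels, 0.25 ns fwhm IRF), run the two-step fit, and convert to FRET:

```r
library(transpofit)

times <- seq(0, by = 0.05, length.out = 1024)
irf   <- make_irf(times, center = 2, fwhm = 0.25)
donor <- decay_model(tau_disc = 4, alpha_disc = 1, alpha_g = 0)
bound <- decay_model(tau_disc = 4, alpha_disc = 0.4,
                     tau_g = 3.3, fwhm_g = 1, alpha_g = 0.6)
ctrl <- simulate_decay(donor, irf, 2e6, seed = 101)
samp <- simulate_decay(bound, irf, 2e6, seed = 102)
fit  <- two_step_fit(ctrl, samp, irf, seed = 1)
fit
#> Two-step constrained reconvolution fit
#> step 1 (control): donor lifetime 3.994 ns
#> ...
#> step 2 (sample, donor lifetime held):
#> Reconvolution decay fit
#>   discrete : tau = 3.994 ns (held), fraction 0.430
#>   gaussian : centre 3.254 ns, fwhm 0.996 ns, fraction 0.570
#>   baseline 0, reduced chi-square 1.102 (730 channels)
```

The generating truth (centre 3.3 ns, bent fraction 0.6) is recovered to
1.4% and 5%. `fret_result(fit)` converts the fit: efficiency 0.185,
distance 88.3 Å, bent fraction 0.57 — a strongly bent population, far
below the 119 Å of straight 35 bp B-DNA (`bdna_extension(35)`).

A cooperative titration at the plate-reader design (12-point dilution,
3 series × 5 reads, noise SD 0.005) and its fit:

```r
titr <- simulate_titration(kd = 15, n = 3.3, noise_sd = 0.005, seed = 42)
fit_titration(titr, boot = 200, seed = 1)
#> Equilibrium binding fit (receptor depletion + Hill)
#>   K_D     = 15.42 nM  [95%: 14.94, 15.82]
#>   Hill n  = 3.5  [95%: 3.225, 3.811]
#>   r_free  = 0.1007  [95%: 0.09924, 0.1021]
#>   r_bound = 0.2603  [95%: 0.2589, 0.2618]
#>   labeled DNA 6 nM; residual sum 1.95e-05 over 12 concentrations
```

And the initial-rate estimator on a noiseless second-order curve
(k = 3 µM⁻¹ min⁻¹, 0.1 µM each reactant):

```r
tp <- c(0, 0.1, 0.5, 1, 2, 5)
steepest_slope_rate(tp, second_order_fraction(3.0, 0.1, tp), c0_um = 0.1)
#> Steepest-slope initial rate: k = 2.913 / uM / min
#>   slope 0.2913 / min between t = 0 and 0.1 min at c0 = 0.1 uM
```

The 2.9% underestimate is the finite-difference cost of a 0.1 min first
sampling interval; it vanishes as the interval shrinks.

## Layout

- `R/` — containers and forward models (`decay-trace.R`, `decay-model.R`),
  fitting (`fit-decay.R`, `binding.R`), FRET conversions (`fret.R`),
  kinetics and lane bookkeeping (`kinetics.R`), simulators
  (`simulate.R`), file formats and reports (`io.R`).
- `vignettes/transpososome-analysis.Rmd` — models, assumptions, numerical
  choices, and limitations.
- `tests/testthat/` — unit, property, and end-to-end recovery tests.
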