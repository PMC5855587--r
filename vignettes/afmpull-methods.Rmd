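---
title: "Methods: force-curve analysis of single-molecule unbinding from mineral surfaces"
author: "afmpull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-curve analysis of single-molecule unbinding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmpull)
```

## The measurement and the model

In AFM force spectroscopy a ligand (an amino acid or short oligopeptide)
is tethered to the cantilever tip through a flexible PEG crosslinker and
pressed against a surface (in the motivating application, natural
pyrite).  During retraction, a bound ligand loads the tether: the
deflection trace shows a nonlinear ramp that terminates in an abrupt
step back to the free-cantilever baseline when the bond breaks.  The
force at that step is the *unbinding force*; the mode of its histogram
over many curves is the *most probable force* (MPF), and the fraction of
curves showing such an event is the *binding frequency*.

Force is the product of cantilever deflection and spring constant,
`F = k·d`, carried internally as pN with `k` in nN/nm and `d` in nm.
Deflection is negative under adhesive load, and unbinding forces are
reported as magnitudes.  The tether extension axis is
`x = (z − z_contact) − |d|`: piezo travel from the contact point minus
the deflection of the cantilever toward the surface.

The tether is modelled as a worm-like chain in the Marko–Siggia
interpolation,

$$F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4(1-x/L_c)^2} - \frac14 +
\frac{x}{L_c}\right],$$

with persistence length `Lp = 0.1 nm` by default (the value
conventionally used to describe PEG spacer elasticity in this kind of
experiment, although it is below a monomer length — it is a fitting
convention, not a structural claim) and contour length `Lc` free,
because the crosslinker's molecular weight, hence `Lc`, is
heterogeneous.  The numerical inverse is vectorised bisection on
`[0, Lc)`; round-trips hold to better than 1e−9 relative.

## Event detection and curve taxonomy

Curves are classified as *no adhesion*, *non-specific adhesion*
(rupture at near-zero tether extension), *specific* (accepted
tether-mediated rupture), or *plateau* (constant-force peeling).  The
acceptance rules follow the force-spectroscopy conventions for this
system:

* **Detection floor** `min_force_pN = 10` pN: shallower ruptures are
  below the instrument's resolution.
* **Extension window** `window_nm = c(15, 60)`: a rupture is specific
  only if it occurs between 15 and 60 nm of tether extension.  Below
  15 nm it is indistinguishable from tip–surface adhesion artefacts;
  above 60 nm the PEG tether (maximally ~30–40 nm, allowing for MW
  heterogeneity) cannot reach.

The detector's internal steps are declared, configurable choices (the
instrument-software procedures they replace are typically proprietary
and unpublished):

1. **Baseline**: least squares on the final 20% of the retract trace,
   then a refit over every "quiet" sample of the whole trace (within 4
   noise SDs of the first line and with no smoothed signal beyond 3
   smoothed-noise SDs).  The refit matters: a tail-only slope estimate
   extrapolates poorly hundreds of nm away, and the low-force foot of a
   tether ramp would otherwise bias the offset.  Both cuts are
   symmetric, so pure noise leaves the baseline unbiased.
2. **Contact point**: a straight line fitted to the raw repulsive-wall
   samples, intersected with the baseline.  A smoothed zero crossing
   (the fallback when the wall is too short) is biased late by ~0.5 nm
   because smoothing rounds the contact kink.
3. **Smoothing**: a second-order Savitzky–Golay filter, window 11
   samples, used *only* to localise candidate events; forces are always
   read from the unsmoothed trace at the located index, so filtering
   never attenuates rupture heights.
4. **Candidates**: contiguous stretches with smoothed adhesion at or
   above the floor, ending in a drop to within 2 noise SDs of baseline.
   The stretch peak must additionally clear
   `max(min_force, 5.5 × smoothed-noise SD)`: per-curve maxima of
   smoothed Gaussian noise reach ~4.5–5 SD, so without this false-peak
   control a few percent of noise-only curves would sprout spurious
   events.  The rupture index is refined as the largest single-sample
   drop of the raw trace near the stretch end.
5. **Headline force**: when several events are accepted, the curve's
   unbinding force is the final rupture (largest extension; ties to the
   larger force), matching the single-tether reading of such curves.
   Sub-window adhesion marks a curve non-specific only if no accepted
   event coexists.
6. **WLC validation** (optional): the ramp preceding each accepted event
   can be fitted with `fit_wlc()`; the residual RMS is stored as a
   plausibility score but never used to reject, since real PEG stretches
   deviate systematically from the ideal WLC shape.
7. **Plateaus**: the longest stretch of at least 20 nm whose smoothed
   force stays within ±2 noise SDs of its own mean (edges trimmed by the
   filter width) and ends in a step to baseline.  A detected plateau
   takes precedence over an accepted rupture: a flat segment ending in
   detachment is a peeling curve even when the detachment falls inside
   the window.  A WLC ramp cannot pass the flatness test, so specific
   curves are never demoted.

## Force statistics

Histograms use left-closed, right-open 10 pN bins anchored at 0 (the
bin width of published unbinding histograms is rarely stated; 10 pN is
the package default and configurable).  Unbinding-force histograms are
typically right-skewed; the MPF is therefore estimated exactly as
practitioners do: a Gaussian is least-squares fitted to the bins within
±3 bins of the tallest bin — a local fit around the peak, not a global
or skew-normal fit — and its centre is the MPF.  Simulation (200
replicates at n = 36, σ = 10) shows the estimator is approximately
unbiased (|bias| ≤ 1 pN) despite the local window.  Multi-modal
histograms are decomposed by least-squares Gaussian mixtures,
initialised at the tallest well-separated local maxima; degenerate
components are merged with a warning.

Two fitted modes are compared with a two-sided normal interval on the
difference, `±z · sqrt(σ₁²/n₁ + σ₂²/n₂)` with `z = 1.960` at 95% and
`1.282` at 80%, where σ is the fitted Gaussian SD and n the accepted
event count.  At these sample sizes (n ≈ 32–38) a t quantile would round
to the same printed pN values; z is the declared contract.  Binding
frequencies carry Wilson score intervals.

## Peeling work

Polymer-coated tips (e.g. poly-L-lysine) produce constant-force peeling
plateaus instead of tether ruptures.  The mechanical work of peeling is
the trapezoidal integral of the baseline-corrected force over an
extension segment, by default `[20, 80]` nm to avoid the convoluted
initial region; the endpoints are placed exactly by linear
interpolation, so a constant-force plateau integrates to `F·Δx` at
machine precision.  Unit chain: work (J) → work per nm → ×Avogadro →
J nm⁻¹ mol⁻¹ → ÷ residue line density (default 3 residues per nm) →
per-residue adsorption energy in kJ/mol.  For a 55 pN plateau this gives
3300×10⁻²¹ J over 60 nm and 11.0 kJ/mol per residue — the package
reports the arithmetically exact value rather than a rounded "about
10 kJ/mol".

## Multivalent binding statistics

An n-site ligand with identical, independent sites has `W = 2ⁿ − 1`
bound configurations (every non-empty subset of sites) against one
unbound state, and a configurational entropy gain `ΔS = k_B ln W`.
`enumerate_bound_states()` is the brute-force oracle for the closed
form (n ≤ 20).  The optional frequency predictor `1 − (1−p)ⁿ` for a
per-site binding probability p is an explicit extrapolation — the
configurational argument itself does not fix how W maps to an observed
frequency — and is flagged as such in the result.  It reproduces the
qualitative monomer < dimer < trimer < pentamer frequency ordering and
drives the synthetic length-series experiment in
`run_length_series()`.

## Spring-constant calibration

`equipartition_k()` implements the simple equipartition form of the
thermal-noise method: `k = k_B T / var(d)` from baseline deflection
fluctuations.  Spectral (Lorentzian) fitting and cantilever-shape
correction factors, which rescale k by a known constant, are out of
scope and noted here.  The reported `relative_uncertainty` is the
sampling error of a variance estimate, `sqrt(2/(n−1))`; records under
1000 samples are flagged.  In practice the method carries ~10%
instrumental uncertainty, the tolerance used in the recovery tests.

## What the synthetic generator emulates — and what it does not

`simulate_ensemble()` produces ground-truth-labelled retract curves:

* a linear repulsive contact wall (0.8 nm deflection per nm of
  penetration) with the retract segment starting 20 nm into contact;
* WLC tether ramps solved self-consistently with cantilever compliance
  (`F = WLC(z − F/k)`, vectorised bisection), terminated by an
  instantaneous single-sample step to baseline at the drawn rupture
  force — one sample is snapped onto the exact rupture point so the
  drawn force *is* the maximum tether force;
* near-contact triangular adhesion artefacts (detachment 2–10 nm);
* constant-force peeling plateaus;
* Gaussian baseline noise (default 5 pN) and optional linear drift.

Default study conditions: specific ruptures drawn from a Gaussian with
mean 76 pN and σ 10 pN at per-curve probability 0.125 — the best
characterised species in the motivating experiments (pentaglycine first
peak; other species are emulated by overriding the model) — tether
contour length 35 ± 5 nm, persistence length 0.1 nm, spring constant
0.02 nN/nm, 0.75 µm retract travel, 2000 samples per curve, 298 K.
Ensembles of 500–1000 curves mirror a realistic session.  One master
seed fixes the whole stream; each curve gets a derived sub-seed so any
single curve is reproducible in isolation.

Deliberately **not** simulated: loading-rate (Bell–Evans) dependence of
the rupture force — the analysis assumes all species are measured under
similar loading rates, so forces are drawn directly from the stated
distribution; finite detachment kinetics; hydrodynamic drag and
cantilever ringing; PEG conformational transitions; and the
unexplained excess force real PEG stretches show in the mid-extension
region relative to the WLC curve.  Passing recovery tests therefore
demonstrate that the estimators are correct for data obeying the stated
model, not that the model captures every feature of experimental
curves.

A note on the detection benchmarks: with this generator's physics
(Lp = 0.1 nm, Lc = 35 ± 5 nm) about 4% of true ruptures fall below
15 nm extension.  The window filter excludes them *by design* — that is
its purpose — so the sensitivity benchmark counts only specific curves
whose true event satisfies the acceptance criteria (force ≥ 30 pN and
true extension inside the window); the filter's exactness is asserted
separately.  On 1000-curve ensembles at default noise the detector
achieves sensitivity ≥ 0.95, false-positive rate ≤ 0.02, and
|mean force bias| ≤ 1 pN.

## Numerical choices and degenerate inputs

* Bisection everywhere a monotone inversion is needed (WLC inverse,
  force balance): 100 iterations, interval width ≪ any tolerance; no
  convergence failures possible on the open interval.
* Nonlinear least squares via Levenberg–Marquardt; non-convergent
  histogram fits fall back to the single-peak fit with a warning, and
  non-convergent WLC fits return a flagged result instead of an error
  so the curve keeps its events unvalidated.
* Histograms need ≥ 3 occupied bins near the peak; otherwise the error
  advises a smaller bin width.
* Empty retract segments, non-monotone piezo records, non-positive
  spring constants and temperatures are rejected at construction with
  the offending curve named.
* Rounding of mode differences to whole pN happens only in `print`
  methods; all stored values are exact.

## Problem sizes

The test suite simulates one 1000-curve ensemble at default settings
(the realistic size of a measurement session) for the detection
benchmarks and 120–600-curve ensembles elsewhere; MPF recovery uses the
historical sample sizes n = 36 and n = 32 with 20 replicate seeds, the
estimator-bias check uses 200 replicates, and calibration checks use
10³–10⁵ deflection samples.

## Known limitations

* The equipartition calibration omits mode-shape and spectral
  corrections (constant factors in practice).
* The MPF local Gaussian fit is a convention, not a maximum-likelihood
  estimator for skewed rupture-force distributions; no skew model is
  provided.
* Multi-tether deconvolution and per-event loading-rate estimation are
  out of scope.
* Vendor binary AFM formats are not read; curves enter as delimited
  text with a metadata header.
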