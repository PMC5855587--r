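# afmpull

Single-molecule AFM force-spectroscopy analysis of tethered-ligand
unbinding and polymer peeling.

## The problem

In AFM force mode, a ligand — an amino acid, a short oligopeptide, or a
polymer — is tethered to the cantilever tip through a flexible PEG
crosslinker and repeatedly pressed against and retracted from a solid
surface (the motivating system is peptide adhesion to natural pyrite).
Each retraction yields a force-distance curve; a bound ligand loads the
tether in a nonlinear worm-like-chain (WLC) ramp that terminates in an
abrupt rupture back to baseline. From thousands of such curves one
estimates:

* the **most probable unbinding force (MPF)**: the mode of a Gaussian
  fitted locally around the tallest peak of the unbinding-force
  histogram (multi-peak decomposition where cooperative unbinding
  produces extra peaks);
* the **binding frequency**: the fraction of curves with an accepted
  specific event — a rupture above the ~10 pN detection floor occurring
  at 15–60 nm of tether extension, the window reachable by the PEG
  spacer and clear of near-contact adhesion artefacts;
* **mode differences** between molecular species with confidence
  intervals `±z·sqrt(σ₁²/n₁ + σ₂²/n₂)`;
* **peeling work** for polymer curves with constant-force plateaus:
  `W = ∫F dx`, converted to molar and per-residue adsorption energies;
* **multivalency statistics**: an n-site ligand has `W = 2ⁿ − 1` bound
  configurations and configurational entropy `ΔS = k_B ln W`;
* the cantilever **spring constant** by the thermal-noise
  (equipartition) method, `k = k_B T / var(deflection)`.

Because raw experimental curves for such studies are rarely deposited,
the package includes a first-class synthetic-data generator producing
ground-truth-labelled ensembles (WLC ramps with instantaneous rupture,
non-specific adhesion artefacts, peeling plateaus, Gaussian noise and
drift), so every stage of the pipeline is testable end to end. It is
intended for force-spectroscopy practitioners and for anyone needing a
transparent, scriptable reimplementation of this analysis chain.

## Worked example

```r
library(afmpull)

res <- run_pipeline(pipeline_config(
  simulation = simulation_config(n_curves = 500),
  seed = 42
))
#> simulate: 500 curves (seed 42): no_adhesion=337, nonspecific=90, specific=73
#> detect: 68 accepted events on 68 specific curves; 96 candidates rejected by the 15-60 nm window
#> stats: MPF 77.5 pN from 68 events

print(res$summary, row.names = FALSE)
#>  sample_label n_total n_specific MPF_pN relative_frequency_pct frequency_ci_pct
#>     synthetic     500         68     78                   13.6        10.9-16.9
```

The default simulation emulates a pentaglycine-like tip chemistry:
specific ruptures drawn from a Gaussian with mean 76 pN and σ 10 pN on
12.5% of curves. The run recovers an MPF of 77.5 pN (σ 13.5 pN, n = 68)
and a binding frequency of 13.6% (Wilson 95% CI 10.9–16.9%) — both
consistent with the generating parameters; 96 sub-window adhesion
artefacts were rejected by the extension filter.

Mode comparison between two species summaries:

```r
compare_modes(mpf_result(76, 10, 36), mpf_result(55, 11, 38), 0.95)
#> Mode difference: 21 +/- 5 pN at 95% confidence (exact 21.00 +/- 4.79)
```

Peeling energetics of a constant 55 pN plateau:

```r
x <- seq(0, 100, by = 0.5)
peeling_result(x, rep(55, length(x)), c(20, 80))
#> Peeling over [20, 80] nm: mean force 55.0 pN, work 3.3e-18 J
#> (5.5e-20 J/nm; 3.31e+04 J/nm/mol; 11.0 kJ/mol per residue at 3 residues/nm)
```

Multivalency and calibration:

```r
multivalency_result(5, per_site_probability = 0.03)
#> n = 5 sites: W = 31 bound states, delta S = 4.741e-23 J/K
#> predicted binding probability (extrapolated, p = 0.03): 0.1413

equipartition_k(simulate_thermal_deflections(1e5, 0.09, 298, seed = 1), 298)
#> Equipartition calibration: k = 0.08937 nN/nm (n = 100000, T = 298 K, +/- 0.4% sampling)
```

A thin command-line wrapper over the same pipeline lives at
`inst/scripts/afmpull-pipeline.R`; the methods vignette
(`vignettes/afmpull-methods.Rmd`) documents the model, detection rules,
defaults and limitations.

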