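# synucalc

Analysis pipeline for studies of calcium binding to the C terminus of
alpha-synuclein and its consequences for synaptic vesicle interaction.
Alpha-synuclein (140 residues: N terminus aa 1–60, NAC region aa 61–95,
C terminus aa 96–140) binds synaptic vesicles via its N terminus; calcium
binding at the negatively charged C terminus extends that interaction and
shifts vesicle pool behavior. synucalc implements the quantitative methods
such a study needs, end to end, with seeded synthetic-data generators so
every stage is testable against known ground truth:

* **NMR CSP titration** — weighted perturbations
  Δδ = √(½(δ_H² + 0.15 δ_N²)), bound fractions χ_B = Δδ_obs/Δδ_sat, and a
  global multi-ligand fit
  χ_B = (P + C/L + K_D − √((P + C/L + K_D)² − 4PC/L)) / 2P
  returning the dissociation constant K_D and ligand number L, plus residue
  ranking and NAC broadening detection.
* **CEST profiles** — normalization against a −100 kHz reference, a scalar
  saturation-transfer score per residue, and per-region condition contrasts
  with a seeded bootstrap.
* **dSTORM cluster radii** — ROI segmentation, pair-distance histograms
  normalized by a Monte-Carlo CSR reference, Ripley-style cluster-radius
  estimates, Welch t-test comparisons.
* **STED vesicle fields** — 250 nm linkage classification into singles /
  pairs / clusters, ANOVA + Tukey across conditions.
* **ThT kinetics** — Finke–Watzky two-step fits
  (B_t = A₀ − (k₁/k₂ + A₀)/(1 + (k₁/(k₂A₀))e^((k₁+k₂A₀)t))), tangent-method
  lag times, fold changes, SEC calibration to residual monomer.
* **ESI stoichiometry** — theoretical m/z for protein–calcium complexes
  (each Ca²⁺ displacing two protons), grid-search charge deconvolution over
  9+–19+, and maximum-stoichiometry counting on the 38.06 Da adduct ladder.

## Worked example

Simulate a titration at the study conditions (200 µM protein, calcium
0–3.6 mM, ground truth K_D = 21 µM, L = 7.8, 1% shift noise) and recover the
binding parameters:

```r
library(synucalc)
series <- generate_titration(seed = 101)
fit <- fit_binding(series)
print(fit)
#> Global multi-ligand binding fit
#>   K_D = 21.8 uM (SE 0.88)
#>   L   = 7.78 Ca2+ per protein (SE 0.04)
#>   12 residue(s) in fit, RSS = 8.72e-05
sort(rank_perturbed_residues(series, top_k = 13))
#>  [1] 104 107 112 119 123 124 126 127 129 130 135 136 137
detect_broadening(series)
#> [1] 65 70 71 74 80 85
```

The fitted K_D (µM) and L come back within a few percent of the generating
truth; the most perturbed residues are exactly the 13 C-terminal sites the
generator perturbed, and broadening is confined to the NAC region.

The `analysis/` directory holds one driver per data kind
(`01_titration_binding.R` … `06_ms_stoichiometry.R`); each simulates its
inputs under the documented presets, runs the analysis, prints what it
found, and writes tables under `results/`. `run_pipeline()` executes the
same stages programmatically and writes a combined JSON report.

## Layout

```
R/                  package code (one file per pipeline stage + generators)
analysis/           numbered narrative drivers, write to results/
scripts/acceptance.R  headline-number reproduction
tests/testthat/     unit, property, and acceptance tests
vignettes/methods.Rmd  models, parameters, design decisions, limitations
```
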