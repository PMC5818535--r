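---
title: "Models and methods behind synucalc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synucalc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synucalc)
```

synucalc reimplements, as one tested pipeline, the analyses used to study
calcium binding at the C terminus of alpha-synuclein and its consequences for
synaptic vesicle interaction: an NMR chemical-shift-perturbation (CSP)
titration with a global multi-ligand binding fit, CEST saturation-transfer
profiling by protein region, cluster-radius estimation from single-molecule
localization tables, 250 nm linkage classification of vesicle fields,
Finke–Watzky aggregation kinetics from ThT curves, and charge deconvolution
of ESI spectra for calcium-adduct stoichiometry. No raw datasets are
distributed with the underlying study, so every stage is exercised on
synthetic data whose generators are first-class, seeded, and carry their
ground truth; this vignette explains each model, the tunable parameters, and
the design decisions that were genuinely open.

## The multi-ligand binding model (NMR CSP)

Amide-resonance movement between the calcium-free and calcium-bound states is
summarized per residue by the weighted CSP

$$\Delta\delta = \sqrt{\tfrac12\left(\delta_H^2 + 0.15\,\delta_N^2\right)},$$

with the 0.15 weight compensating the wider ¹⁵N ppm scale. The bound fraction
at a given calcium concentration is $\chi_B = \Delta\delta_{obs} /
\Delta\delta_{sat}$. Treating the $L$ calcium ions bound per protein as a
single composite ligand with dissociation constant $K_D$, mass action over
total protein $P$ and total calcium $C$ gives the closed form

$$\chi_B = \frac{P + C/L + K_D - \sqrt{(P + C/L + K_D)^2 - 4PC/L}}{2P},$$

implemented in `binding_model_chiB()` and verified in the tests against an
independent mass-action root-finding oracle to 1e-6.

`fit_binding()` fits $(K_D, L)$ and one saturation shift per selected residue
jointly, by bounded Levenberg–Marquardt least squares on the $\Delta\delta$
scale (so no pre-fit $\chi_B$ clipping is ever needed; the standalone
`chi_B()` helper still clips noisy ratios into $[0,1]$ and reports the count).
Residue selection defaults to "weighted CSP at the top concentration above
mean + 2 SD of all residues", a concrete reading of "the peaks associated
with the major perturbations".

Two numerical choices matter:

* **Starting values.** With $K_D \ll P$ the titration is quasi-stoichiometric
  and the least-squares surface has a local minimum at the $K_D \to 0$
  boundary, where $L$ absorbs the knee position. A fixed start can fall into
  it. Because the saturation shifts enter linearly, they are profiled out in
  closed form and a coarse log-grid search over $(K_D, L)$ picks the start;
  the subsequent LM polish then converges to the global optimum. An explicit
  `init` overrides this.
* **$\Delta\delta_{sat}$ free, not fixed.** The last titration point (3.6 mM)
  sits near but not at saturation; fixing the saturation shifts to it would
  bias $K_D$ upward. They are fitted, initialized at the top-concentration
  CSP.

Standard errors come from the Gauss–Newton covariance at the optimum.
Exchange broadening is detected separately (`detect_broadening()`) as
intensity loss below a ratio threshold (default 0.7), excluding residues that
shifted more than 0.05 ppm, so shift and broadening are not conflated.

## CEST profiles and the region score

The CEST generator evolves a two-state Bloch–McConnell system — free protein
exchanging with a broad vesicle-bound state — under 400 Hz continuous-wave
saturation at offsets (−9 … 9 kHz, 13 values) plus a −100 kHz reference,
10 °C-scale relaxation constants ($R_1 = 1.5$, $R_{2,free} = 5$,
$R_{2,bound} = 700\ \mathrm{s^{-1}}$, $k_{ex} = 100\ \mathrm{s^{-1}}$,
0.5 s saturation). The bound-state linewidth makes saturation efficiency fall
off smoothly across the offset schedule, which is what gives the profiles
their diagnostic shape. Direct saturation of the visible state is included,
so even an unbound residue shows the on-resonance notch — as real profiles
do; a zero-bound-fraction profile is flat at 1 only beyond ±3 kHz.

Measured profiles are normalized by the per-residue reference
(`normalize_cest()`) and summarized by `cest_score()`:
$1 - \overline{I}_{|\Omega| \le 4\,\mathrm{kHz}} / \overline{I}_{|\Omega| \ge
7\,\mathrm{kHz}}$, a scalar in $[0,1]$. The 4/7 kHz bands are our choice from
the offset schedule; the score is pipeline plumbing for ordinal comparisons,
not an exchange parameter, and no rates or populations are extracted from
measured profiles. `compare_regions()` contrasts conditions per region
(N 1–60, NAC 61–95, C 96–140) with a seeded 1000-resample bootstrap over
residues (seed 42).

## Cluster radius from localization tables

ROIs are segmented by single-linkage connected components at 200 nm and
filtered at 50 localizations. Within an ROI the pair-distance histogram
(10 nm bins) is normalized by the mean histogram of `n_rand = 50` uniform
placements of the same number of points in the same region — a Monte-Carlo
complete-spatial-randomness reference that handles any ROI shape and its
boundary implicitly.

Reading a "cluster radius" off that histogram required an interpretation. The
per-bin ratio observed/CSR is analytically maximal as distance → 0 for any
compact cluster (both densities vanish linearly at 0 and the ratio decreases
in $r$), so its argmax sits in the first bin regardless of cluster size and
cannot serve as a size metric. The default rule is therefore the peak of the
**excess** over CSR, `count - expected`, which for a Gaussian cluster of SD
$\sigma$ peaks near $\sigma\sqrt2$ and scales with the cluster, in the spirit
of Ripley-K-derived cluster metrics whose $H(r)$ maximum estimates cluster
radius. The literal ratio argmax (`rule = "ratio"`) and the largest distance
with ratio > 1 (`rule = "crossing"`) are available for comparison. Estimates
from flat histograms (ratio max/median < 1.2, or peak excess below 5
Monte-Carlo SDs) are flagged unreliable. Bins whose CSR expectation is below
2% of the maximum are ignored — their ratios are Monte-Carlo noise.

The synthetic synaptosomes are 700 nm discs; the clustered preset draws
emitters from four σ = 30 nm sub-clusters, while the dispersed preset spreads
them as one broad central Gaussian (SD = half the disc radius). A uniform
disc would be exactly CSR inside its own ROI and carry no length scale at
all; spreading over the synaptosome interior instead makes the synaptosome
itself the cluster scale, which reproduces the reported direction (larger
apparent cluster size upon calcium depletion). Localization noise is 10 nm
SD. Condition comparison is a two-tailed Welch t-test.

## Vesicle-field classification

`classify_clusters()` links vesicles within 250 nm (center-to-center) and
takes connected components, so a chain A–B–C is one cluster of three even if
A–C exceeds 250 nm — linkage is transitive, which we record as a choice the
source leaves open. Percentages are reported over vesicles (a pair
contributes two vesicles), matching the phrasing "88% of synaptic vesicles
were distributed as single vesicles"; per-component percentages are available
via `denominator = "components"`. Duplicate coordinates within 1 nm are
merged.

The generator targets per-condition fractions — EGTA 88% singles, calcium
84%, alpha-synuclein + calcium 81% — with the clustered remainder split
roughly 2:1 between pairs (40–200 nm apart) and triples-plus (tight rings);
the pair/multi split is not reported and is our choice. Component centers are
kept ≥ 750 nm apart by dart-throwing, which guarantees distinct components
are never linked at 250 nm, so a field realizes its target fractions exactly
up to rounding at the default density (300 vesicles per 20 × 20 µm field,
0.75 µm⁻²). Condition comparisons use one-way ANOVA per size category with
Tukey-adjusted pairwise tests.

## Finke–Watzky kinetics and the tangent lag

ThT curves follow the two-step nucleation/autocatalytic-growth solution

$$[B]_t = [A]_0 - \frac{k_1/k_2 + [A]_0}
{1 + \frac{k_1}{k_2 [A]_0}\,e^{(k_1 + k_2 [A]_0)t}},$$

with the printed exponent read as $(k_1 + k_2[A]_0)t$ — the standard
Finke–Watzky logistic; $B(0) = 0$ holds as an algebraic identity.
`fit_fw()` fits $(A_0, k_1, k_2)$ plus an additive baseline offset by
Levenberg–Marquardt, with the rate constants on the log scale because $k_1$
can sit ten or more decades below $k_2 A_0$ in nucleation-limited curves.
Fitting the baseline (rather than subtracting a pre-estimate) keeps the
noiseless round trip exact, because the model curve has no plateau to
estimate a baseline from when nucleation is fast.

`lag_time_tangent()` implements the classical tangent construction: baseline
= median of the earliest points (never past the 20%-of-range crossing);
elongation line = the local least-squares tangent at the steepest point of
the rise, found by sliding a short window (3–11 points, scaled to the
sampled transition length) over the 20–80% amplitude band; lag = where that
line meets the baseline. A single secant over the whole 20–80% band
systematically underestimates the slope of a logistic by ~13% and
overestimates the lag, which is why the tangent is localized. On noiseless
model curves in the nucleation-limited regime the result agrees with the
closed-form inflection-tangent lag to within 2%.

Preset conditions are specified by their target lag and transition sharpness
$\lambda = k_1 + k_2 A_0$ (per hour), with $k_1$ solved from the closed-form
lag: calcium-only 3.95 h, calcium + vesicles 5.55 h, EGTA + vesicles
44.72 h, EGTA-only 78.95 h. The reference report prints its rate constants
in units that cannot be reconciled with its 16-min sampling interval, so
those printed values are treated as shapes to reproduce ordinally (fold
changes, lag ordering), never as numbers to recover. The EGTA-only lag sits
at the edge of a standard 300-cycle (80 h) run; the analysis script simulates
the EGTA arms for 450 cycles to capture the full sigmoid and says so. Curves
are averaged across the 18 replicate wells per condition before lag
extraction. `sec_monomer()` maps SEC peak areas to concentrations through an
ordinary least-squares calibration line and flags extrapolation.

## ESI charge deconvolution

Species masses follow a charge-balanced adduct model: each bound Ca²⁺
displaces two protons, so one calcium adds $m_{Ca} - 2m_p = 38.063$ Da to
the neutral species, and the ion at charge $z$ appears at
$(M + z\,m_p)/z$. Whether the instrument software of the reference used this
or a protonation-only convention is unknown; ours is declared here and in
the output metadata.

`charge_deconvolve()` is a grid-search deconvolution (0.2 Da steps): the
evidence for mass $M$ is the summed intensity within 0.05 Th of its
theoretical m/z at every charge 9+–19+. Four guards keep it honest on noisy,
wide mass grids, each added against an observed artifact class: a
rolling-median baseline is subtracted without clamping (clamping biases the
summed evidence by half the noise amplitude per sample); the noise floor is
median + 3 MAD of the evidence trace with a 2% relative floor; a charge
supports a mass only if its window sum exceeds 3 MAD of that charge's own
window sums, and near-full envelope support (all but one charge) is
required — partial harmonics (e.g. a ~2M mass aligning with a true peak at
one charge) fail this; finally species within 2 Da are de-duplicated
greedily by abundance. `count_stoichiometry()` assigns each species the
nearest rung of the calcium ladder and rejects assignments beyond 2 Da.

## Synthetic data: what it does and does not emulate

All generators take an explicit seed, use one private RNG stream (the global
RNG state is saved and restored), and attach a `truth` attribute that the
writers serialize as `truth.json`. Identical seeds give byte-identical
outputs. Default noise levels — 1% multiplicative on shift perturbations, 2%
on CEST and ThT intensities, 10 nm localization SD, 3% MS baseline — are our
choices; none are stated by the source.

The generators reproduce the *statistical structure* the analyses assume,
not instrument physics: no spectral folding or detector saturation, no
isotope patterns, no dSTORM blinking/drift artifacts, no STED depletion
effects. Titration noise is multiplicative on the perturbation, so
unperturbed residues have exactly zero CSP — convenient for ground-truth
ranking, optimistic relative to real spectra. Vesicle fields enforce
component separation, so classification error on them is rounding only; real
fields have accidental proximities. Passing tests therefore demonstrate that
the estimators recover known truth under the stated noise model at the study
conditions, not that they are robust to every failure mode of real data.

## Problem sizes

The shipped configuration uses 140 residues × 10 titration points, 13 CEST
offsets × 140 residues × 2 conditions, ~6 synaptosomes × 300 localizations
per field, 300 vesicles per field, 18 wells × 300–450 cycles, and ~90,000
m/z samples; the recovery experiments use 20 seeded replicates. These sizes
keep every analysis script and the full test suite in the seconds-to-minutes
range on a single core while leaving all estimators well inside their
asymptotic regimes.
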