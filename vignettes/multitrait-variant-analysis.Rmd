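---
title: "Multi-trait biophysical analysis and scoring of missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait biophysical analysis and scoring of missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varitrait)
library(dplyr)
```

## The problem this package addresses

NQO1 (NAD(P)H quinone oxidoreductase 1) is a dimeric, FAD-dependent,
multifunctional enzyme in which naturally occurring missense variants can
perturb several molecular traits at once: soluble expression, dimer thermal
stability, local stability of the thermolysin cleavage site, FAD cofactor
binding, and binding of the inhibitor dicoumarol. `varitrait` implements the
full quantitative chain from raw assay measurements to a semiquantitative
pathogenicity score for such variants, together with a synthetic-data module
that generates assay datasets from a known per-variant truth table so every
stage of the chain can be validated end to end without instrument data.

## Assay models

### Fluorescence cofactor titration

At 0.25 µM protein the dissociation constants of interest (tens of nM to a
few µM) are comparable to the protein concentration, so free ligand cannot
be approximated by total ligand. The fluorescence signal follows the
quadratic tight-binding isotherm

$$I = I_{apo} + (I_{holo}-I_{apo})\,
\frac{[P]+[L]+K_d-\sqrt{([P]+[L]+K_d)^2-4[P][L]}}{2[P]},$$

fitted by Levenberg–Marquardt least squares over $(K_d, I_{apo},
I_{holo})$ with a non-negativity bound on $K_d$
(`fit_titration()`). Initialization uses the first and last intensities
for the plateaus and the midpoint ligand concentration for $K_d$; the
isotherm is monotone and sigmoid-free, so this start is reliably inside
the convergence basin. Binding free energies use $\Delta G = RT\ln K_d$
with $K_d$ in molar. This is the convention used by the assay family we
reproduce — it omits the conventional minus sign — and we keep it as
printed because only *differences*, $\Delta\Delta G = RT\ln(K_d^{mut} /
K_d^{WT})$, are consumed downstream; those are convention-independent up
to sign and are tested for antisymmetry.

### Limited proteolysis

At fixed thermolysin concentration the intact fraction decays as a single
exponential, $f(t)=A e^{-k_{obs}t}$. The amplitude is a free parameter
rather than pinned at 1: in densitometry the zero-time control defines
band intensity only up to normalization error, and absorbing that error
into $A$ keeps $k_{obs}$ unbiased. $k_{prot}$ is then the ordinary
least-squares slope of $k_{obs}$ against protease concentration; the
intercept is reported as a diagnostic, since a substantial intercept
signals departure from the linear (EX2-like) regime in which $k_{prot}$
tracks the local folding equilibrium of the cleavage region. Local
stability changes are $\Delta\Delta G_{prot}=RT\ln(k_{prot}^{mut}/
k_{prot}^{WT})$, positive for destabilization, with errors propagated
linearly from the two slope standard errors.

### Thermal denaturation

Scans are normalized with linear pre- and post-transition baselines,
$f(T)=(S-pre)/(post-pre)$, and the apparent midpoint $T_m$ is the
temperature at $f=0.5$. Because denaturation of this dimer is
irreversible and scan-rate dependent, no two-state thermodynamic
parameters are claimed: $T_m$ is extracted by local linear interpolation
of the 0.5 crossing (points with $f$ between 0.25 and 0.75), not by
fitting a thermodynamic sigmoid. Baseline windows default to the first
and last 15% of the scanned range and are overridable; windows that
overlap or that leave the baselines crossing inside the transition raise
errors rather than silently producing a fraction outside [0, 1]. A curve
whose 0.5 crossing is not unique (multi-phasic or oscillating) is
rejected — an apparent midpoint cannot summarize it.

### Isothermal titration calorimetry

Integrated injection heats are fitted with the one-set-of-sites model:
after injection $i$ the bound-ligand concentration $B_i$ is the physical
root of the mass-balance quadratic with site concentration $N[P]$, and

$$q_i = \Delta H\, V_{cell} (B_i - B_{i-1}) + q_{dil} v_i.$$

Four parameters are free: $N$, $K_d$, $\Delta H$ and the dilution heat
per injected microlitre (a fitting parameter, not a measured blank). The
initial 0.5 µL pre-injection is excluded from the residuals by default —
standard practice, since its effective volume is unreliable — but its
ligand contribution to the cell is still tracked. The cell volume is
fixed at 200 µL and syringe-displacement (perfusion) corrections are
omitted; simulator and fitter share this convention, so round-trip
recovery is exact by construction and the omission cannot bias
mutant-versus-wild-type comparisons. Entropy follows from
$\Delta G=-RT\ln K_a$ and $\Delta S=(\Delta H-\Delta G)/T$; every fit is
checked for $|\Delta G - (\Delta H - T\Delta S)| < 10^{-6}$ kcal·mol⁻¹.
When $c = N[P]/K_d$ exceeds ~1000 the heats approach a step function and
$K_d$ is no longer resolvable; the fit warns rather than failing.

The heat-capacity change is the OLS slope of $\Delta H$ on temperature
over runs at 10, 15, 17.5, 20 and 25 °C. The binding enthalpy and
$\Delta C_p$ are then decomposed into an intrinsic rigid-body term
(−5.8 kcal·mol⁻¹ at 25 °C and −0.14 kcal·mol⁻¹·K⁻¹, imported
buried-surface-area estimates for the inhibitor complex) and a
conformational term converted to a residue count with the per-residue
folding coefficients 0.215 kcal·mol⁻¹ and 0.0138 kcal·mol⁻¹·K⁻¹:

$$N_{conf}^{(H)} = \Delta H_{conf}/0.215, \qquad
  N_{conf}^{(Cp)} = \Delta C_{p,conf}/0.0138.$$

The coefficients are positive while experimental conformational
contributions can carry either sign, so `conformational_change()` exposes
both the signed estimators and their magnitudes; the headline residue
count is the mean of the two magnitudes, matching the convention of
reporting a positive number of residues folding upon binding.

Cavity-creating mutations are handled separately:
`cavity_destabilization()` multiplies the cavity-volume increase by the
empirical 24–36 cal·mol⁻¹·Å⁻³ range from model-protein parametrizations,
returning a destabilization interval rather than a point estimate.

## The scoring rubric

Each measurable trait is encoded 3 (neutral), 2 (mild) or 1 (severe):

| trait | 3 (+++) | 2 (++) | 1 (+) |
|---|---|---|---|
| expression (% of WT) | ≥ 50 | 20–50 | < 20 |
| thermal stability (ΔTm) | within 2 °C | 2–5 °C lower | > 5 °C lower |
| proteolysis (k_prot fold) | ≤ 3 | 3–30 | > 30 |
| FAD / inhibitor binding (K_d fold) | ≤ 3 | 3–10 | > 10 |

Boundary conventions, fixed once and used everywhere: upper bounds on the
neutral side are inclusive (a 3-fold change codes 3, verified against the
published panel where 6-fold codes 2 and 12-fold codes 1); fold changes
below 1 and stabilizing ΔTm code 3, because the rubric penalizes only the
deleterious direction; and the published rubric's proteolysis row lists
"++" twice — the second occurrence (for > 30-fold) is treated as the
evident typo for "+", since otherwise code 1 would be unreachable while
the panel itself contains proteolysis "+" entries. One genuine ambiguity
remains: the published panel codes a 3-fold FAD change as "++" for one
variant while the caption's "within three-fold" wording implies "+++";
the package follows the caption (inclusive ≤ 3), and the built-in truth
table places that variant's fold-change at 3.5 so that its measured code
matches the published row.

The experimental score (ES) is the arithmetic mean of available trait
codes; insoluble variants are scored from expression alone. Bioinformatic
scores (BS) average predictor codes mapped from categorical calls
(PolyPhen-2, SIFT, MutationTaster, PROVEAN, PON-P2), skipping
undetermined entries. Recomputing the packaged 22-variant panels
reproduces all 22 printed ES values and 21 of 22 printed BS values; the
P187S predictor codes average 2.4 against a printed 2, and
`score_published_panels()` flags the row instead of silently adopting
either number. ES is regressed on BS by OLS with Pearson correlation,
pooled and within each mutation set (Nt, P187, K240); plain OLS is used
because the original presentation does not state any weighting.

## The synthetic-data module

`build_fixture_panel()` is the package's reference truth table: the wild
type plus six purifiable N-terminal variants whose fold-changes encode
the reported phenotypes (12-fold weaker FAD binding and a 4–5 °C lower
midpoint for T16M, 6-fold FAD for A29T, −1.5 °C for V9I, near-neutral
G3S/G3D). Each `simulate_*` function adds zero-mean Gaussian noise scaled
to the assay's signal amplitude; 2% is the default replicate-level
scatter, a calibration choice (typical of fluorescence and calorimetric
replicates) rather than a reported value. Identical (truth, design, seed)
inputs give bit-identical datasets, and seeding is local so simulation
never perturbs the caller's RNG stream.

Design defaults mirror the bench protocols: 0.25 µM protein titrated with
0–5 µM ligand in 16 steps; 0.2–1.2 µM thermolysin; 20–70 °C scans at
0.5 °C; a 0.5 µL pre-injection plus 21 × 1.75 µL injections of 120 µM
ligand into a 200 µL cell of 10 µM protein. Two defaults adapt to the
variant the way an experimenter would: proteolysis sampling times scale
with the expected half-life so fast-digesting variants are still resolved,
and the titration extends to about six times the expected $K_d$ so weak
binders reach their saturation plateau. The pipeline replicates assays as
the protocols do (three titrations, three thermal scans, duplicate
calorimetric runs at 25 °C).

The thermal transition is generated as a two-parameter logistic (midpoint
and width) because only the apparent midpoint is consumed downstream; the
default width of 1.2 °C reflects the steepness of cooperative dimer
unfolding and keeps the logistic tails negligible inside the default
baseline windows. The generator deliberately omits instrument-level
artifacts — baseline drift, photobleaching, calorimeter feedback
dynamics, scan-rate dependence of the irreversible transition — so
passing tests demonstrate that the analysis chain is correct and
well-calibrated for the statistical structure it assumes, not that it is
robust to every instrument pathology of real data.

## Numerical choices and degenerate inputs

* Concentrations are µM throughout; conversion to molar happens only
  inside $RT\ln$ terms, and µcal/kcal conversion is centralized in the
  ITC heat equation.
* $R$ = 1.987×10⁻³ kcal·mol⁻¹·K⁻¹ and $T$ = 298.15 K for all free-energy
  derivations.
* Flat titrations and blank enthalpograms raise "no binding signal"
  errors; non-decaying proteolysis courses return $k_{obs}=0$ with a
  warning; zero-amplitude thermal transitions and crossing baselines are
  errors.
* Fitted optima are cross-checked in the test suite against independent
  brute-force oracles: exhaustive grid searches with Nelder–Mead polish
  for the titration and ITC models, closed-form normal equations for
  every OLS slope, bisection on the raw mass-balance equations for bound
  ligand, and a dense-grid sign-change scan for the thermal midpoint.

## Problem sizes used in validation

The packaged checks use 200-seed recovery sweeps for titration, thermal
and calorimetric fits, 100-seed sweeps per rate ratio for the proteolysis
chain, and a single full-pipeline run (7 variants × 4 assays with
replication, about 90 nonlinear fits) — sizes chosen to give stable
coverage estimates while keeping the whole suite interactive. Parameter
recovery at these settings: Kd coverage at three standard errors ≥ 95%,
thermal midpoint bias < 0.1 °C with SD < 0.3 °C at 1% noise.

## Known limitations

* The trait rubric is a step function of continuous measurements, so a
  variant whose true fold-change sits near a boundary (e.g. 3-fold) can
  legitimately code differently between noisy replicate campaigns — at
  the bench as much as in simulation.
* Apparent $T_m$ values are operational (irreversible denaturation); they
  support variant ranking and ΔTm, not equilibrium thermodynamics.
* The intrinsic enthalpy/heat-capacity terms and per-residue coefficients
  are imported literature parametrizations; $N_{conf}$ inherits their
  (unstated) systematic uncertainty.
* Multi-site or cooperative binding, spectral deconvolution, fragment
  ladders in proteolysis, and mechanistic (Lumry–Eyring) modeling of the
  irreversible thermal transition are out of scope.
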