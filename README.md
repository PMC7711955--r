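# varitrait

Multi-trait biophysical characterization and semiquantitative scoring of
missense variants of NQO1, a dimeric FAD-dependent multifunctional enzyme.

Missense variants rarely break a protein through a single mechanism: a
substitution can simultaneously shift soluble expression, dimer thermal
stability, the local stability of a protease-sensitive region, cofactor
binding and inhibitor binding. `varitrait` is for biophysicists and
variant-effect researchers who want to go from per-assay measurement tables
to a per-variant pathogenicity score through one tested, reproducible chain:

* **Fluorescence FAD titrations** fitted with the quadratic tight-binding
  isotherm
  `I = I_apo + (I_holo − I_apo) · {[P]+[L]+K_d − √(([P]+[L]+K_d)² − 4[P][L])} / (2[P])`,
  with `ΔΔG_FAD = RT·ln(K_d^mut / K_d^WT)`.
* **Limited proteolysis**: single-exponential decays give `k_obs`, the OLS
  slope of `k_obs` vs thermolysin concentration gives `k_prot`, and
  `ΔΔG_prot = RT·ln(k_prot^mut / k_prot^WT)` (positive = locally
  destabilized).
* **Thermal denaturation**: linear pre/post-transition baseline
  normalization and apparent `Tm` at the half-denaturation crossing.
* **Isothermal titration calorimetry**: one-set-of-sites fits (N, K_d, ΔH,
  dilution heat), `ΔCp` from the temperature dependence of ΔH, and
  decomposition of (ΔH, ΔCp) into intrinsic plus conformational terms to
  estimate `N_conf`, the number of residues folding upon inhibitor binding
  (`ΔH_conf = 0.215·N_conf`, `ΔCp,conf = 0.0138·N_conf`). Cavity-creating
  mutations get destabilization bounds at 24–36 cal·mol⁻¹·Å⁻³.
* **Scoring**: each trait is coded +++/++/+ (3/2/1), the experimental score
  (ES) is the mean of available codes, bioinformatic scores (BS) average
  rubric-mapped calls from five pathogenicity predictors, and ES is
  regressed on BS overall and per mutation set.

A synthetic-data module simulates all four assay types from a per-variant
truth table with seeded, amplitude-scaled Gaussian noise, so the entire
pipeline is testable end to end without instrument data. The packaged
22-variant reference score panels ship as plain-text fixtures.

## Worked example

Fit one simulated titration of a weak-binding variant (truth K_d = 3 µM):

```r
library(varitrait)

curve <- simulate_titration(variant_truth("T16M", kd_fad = 3),
                            titration_design(kd_hint = 3),
                            noise_spec(0.02, seed = 42))
fit_titration(curve, protein_total = 0.25)
#> Tight-binding titration fit: Kd = 3.111 +/- 0.28 uM ([P] = 0.25 uM)
#>   I_apo = 100.5, I_holo = 30.06, RSS = 28.5
```

Run the whole chain — simulate, fit, derive fold-changes, encode the
rubric, score — on the built-in truth panel (wild type plus six purifiable
N-terminal variants):

```r
report <- run_pipeline(build_fixture_panel(), seed = 1)
report
#> Variant pipeline report (7 variants, seed 1)
#>
#> Trait codes and experimental scores:
#> # A tibble: 6 × 7
#>   variant_id expression thermal proteolysis fad_binding dic_binding    es
#>   <chr>           <int>   <int>       <int>       <int>       <int> <dbl>
#> 1 G3S                 3       3           3           3           3   3
#> 2 G3D                 3       3           3           3           3   3
#> 3 V9I                 3       3           3           3           3   3
#> 4 T16M                3       2           2           1           3   2.2
#> 5 Y20N                3       2           3           2           3   2.6
#> 6 A29T                3       3           3           2           3   2.8
#>
#> ES vs BS regression (published 22-variant panel):
#> # A tibble: 4 × 7
#>   set       n  slope slope_se intercept      r  p_value
#>   <chr> <int>  <dbl>    <dbl>     <dbl>  <dbl>    <dbl>
#> 1 all      22 0.804     0.206     0.749 0.658  0.000868
#> 2 Nt        8 0.995     0.173     0.309 0.920  0.00121
#> 3 P187      7 0.380     0.382     0.898 0.407  0.365
#> 4 K240      7 0.0718    0.509     2.40  0.0629 0.893
```

Reading this: T16M codes (3, 2, 2, 1, 3) — full expression, a 4–5 °C lower
melting midpoint, ~6-fold faster proteolysis, 12-fold weaker FAD binding,
unchanged inhibitor binding — averaging to ES 2.2 (mild). Pooled over the
22-variant reference panel, experimental and bioinformatic scores correlate
positively (slope 0.80, Pearson r = 0.66, p < 0.001), with the N-terminal
set much better predicted than the K240 set. The structure–energetics
decomposition for a variant with ΔH = −9.3 kcal·mol⁻¹ and
ΔCp = −0.35 kcal·mol⁻¹·K⁻¹:

```r
conformational_change(-9.3, -0.35)
#> Conformational change: dHconf = -3.50 kcal/mol, dCp,conf = -0.210 kcal/mol/K
#>   N_conf = 16.3 (from dH), 15.2 (from dCp), average 15.7 residues
```

`tidy()`, `glance()` and `autoplot()` methods are provided for every fit
object, and `plot_scores()` draws the ES-vs-BS scatter with pooled and
per-set regression lines.

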