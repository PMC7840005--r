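---
title: "Redox couples, NAD(P) indices and half-cell potentials in germinating seeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redox couples, NAD(P) indices and half-cell potentials in germinating seeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxgerm)
```

## The scientific problem

Seed germination is under redox control. The cell's main redox buffers —
the pyridine nucleotide couples NADH/NAD⁺ and NADPH/NADP⁺, the ascorbate
couple AsA/DHA and the glutathione couple GSH/GSSG — shift between their
reduced and oxidized forms as metabolism restarts, and desiccation-tolerant
(orthodox) and desiccation-sensitive (recalcitrant) seeds manage these
shifts very differently. The canonical contrast is between two *Acer*
species: Norway maple (orthodox; dried to ~10% water content) and sycamore
(recalcitrant; ~30% water content), sampled as dry seeds (D), after 24 h
imbibition (I), at intervals of weeks after imbibition (WAI; every 2 weeks
for sycamore, every 3 for Norway maple) and at radicle protrusion (G), in
embryonic axes and cotyledons with three biological replicates.

`redoxgerm` implements the complete computational path of such a study:

1. **`design_spec` / `make_default_truth` / `sample_concentrations`** — a
   synthetic-data generator emulating that factorial design;
2. **`render_assay_readouts` / `quantify_readouts`** — plate-reader assay
   calculations (calibration curves, kinetic slopes, subtraction logic);
3. **`couple_ratios`** and friends — the NAD(P)-originated physiological
   indices;
4. **`nernst_potential` / `sample_potentials`** — glutathione and
   ascorbate half-cell reduction potentials;
5. **`run_full_report`** — ANOVA + Tukey compact letter displays and
   masked Pearson correlation matrices.

## Assay quantification model

All four analytes are quantified through linear standard curves. For the
NAD(P) enzymatic cycling assay the plate reader records absorbance at
600 nm over time; the rate (absorbance s⁻¹), obtained by ordinary least
squares over all read points, is linear in the analyte amount:

\[ \text{rate} = \beta_1 \cdot \text{amount} + \beta_0 . \]

`fit_calibration()` estimates \(\beta_0, \beta_1\) (with \(R^2\)) from a
standard series and `slope_to_amount()` inverts the line, flagging amounts
outside the standard range as extrapolations. No lag-phase trimming is
applied: with synthetic linear traces all points are informative, and no
kinetic-window rule is part of the assay definition here.

Two derived quantities use subtraction:

* **DHA by difference.** Total ascorbate is measured after DTT reduction,
  free AsA directly; DHA = total − AsA, clipped at zero (and flagged) when
  noise makes the difference negative.
* **Glutathione split.** The DTNB recycling assay measures the total
  glutathione pool on untreated extract and GSSG alone after 2-VP
  masking. Because the recycling assay counts GSH equivalents and each
  GSSG carries two of them, the default convention is
  GSH = total − 2·GSSG. The factor is exposed
  (`glutathione_split(..., equivalents = 1)`) because assay write-ups are
  often ambiguous between GSH-equivalent totals and mole-of-species sums;
  the 2× convention is the standard reading of the recycling assay and is
  the default.

Negative recovered amounts and negative differences are always clipped to
zero and counted (`attr(x, "clips")`), never propagated: every downstream
ratio and Nernst term requires non-negative concentrations.

## NAD(P)-originated physiological indices

With pools in any common unit (units cancel in every index):

* **Catabolic redox charge** CRC = NADH / (NADH + NAD⁺) — the reduced
  fraction of the NAD pool, rising when catabolism runs reduced.
* **Anabolic redox charge** ARC = NADPH / (NADPH + NADP⁺) — the reduced
  fraction of the NADP pool; values above 0.5 signal capacity to drive
  biosynthesis.
* **NADK phosphorylation capacity** — product:substrate proxies for the
  two NAD kinase routes: NADK1 uses NAD⁺ (capacity NADP⁺/NAD⁺), NADK3
  uses NADH (capacity NADPH/NADH). These are concentration ratios, not
  enzyme activities.
* **Dormancy depth** — the NAD/NADP ratio. The default uses total pools,
  (NADH + NAD⁺)/(NADPH + NADP⁺), consistent with describing dormancy via
  the ratio of the two pools; an oxidized-only variant
  (`dormancy_mode = "oxidized"`) is available since the bare phrase
  "NAD/NADP ratio" admits both readings.
* **Reducing power (nicotinamide redox charge)** —
  (NADH + NADPH) / ((NAD⁺ + NADH) + (NADP⁺ + NADPH)). The defining
  formula is sometimes printed with ambiguous parenthesization; the
  reduced-sum-over-total-sum reading adopted here is the only one bounded
  in [0, 1], which the quantity is asserted to be. Algebraically it is
  the pool-weighted mean of ARC and CRC, a property the test suite
  asserts.

Zero denominators yield missing values (`NA`), never zeros or infinities,
and missingness propagates through the statistics (listwise per ANOVA
cell, pairwise in correlations).

## Half-cell reduction potentials

The Nernst equation for a couple with standard potential \(E_0\) (mV at
pH 7), \(n\) electrons and reduced-form stoichiometry \(s\):

\[ E = E_{pH} - \frac{RT}{nF}\,\ln\frac{[\mathrm{red}]^s}{[\mathrm{ox}]},
\qquad R = 8.314\ \mathrm{J\,K^{-1}\,mol^{-1}},\;
F = 9.6485\times10^4\ \mathrm{C\,mol^{-1}} . \]

Built-in couples: GSSG/2GSH with \(E_0 = -240\) mV, \(n = 2\), \(s = 2\),
and DHA/AsA with \(E_0 = +80\) mV, \(n = 2\), \(s = 1\). The GSH-squared
numerator follows from the half-reaction GSSG + 2H⁺ + 2e⁻ → 2GSH: the
glutathione potential therefore depends on the *absolute* GSH
concentration, not only the GSH/GSSG ratio — diluting both forms at fixed
ratio raises \(E\) by \((RT\ln 10 / 2F)\log_{10} 2\) per two-fold
dilution, a property tested numerically. A literal-ratio mode
(`stoichiometry = 1`) exists for sensitivity comparison. The mass-action
logarithm is natural log under the \(RT/nF\) prefactor; the equivalent
base-10 form with the 59.16/n mV-per-decade slope at 298.15 K is available
via `log_base = "log10"` and is used as a cross-check in the tests.

Choices where the convention is genuinely open:

* **pH** defaults to 7.0 (the standard potentials are quoted at pH 7);
  `adjust_e0_for_ph()` applies a linear −59.1 mV/pH correction (the
  25 °C slope for 2e⁻/2H⁺ couples) for other cytosolic pH values in
  [5, 9].
* **Temperature** defaults to 298.15 K; the cold-stratification
  temperature (276.15 K) can be passed instead. Reported figures in this
  field rarely state which temperature entered the equation, so computed
  potentials should be read as patterns, not absolute reproductions.
* **Molarity conversion.** The assays yield nmol per g dry weight, the
  Nernst equation needs mol L⁻¹. `to_molar()` assumes the analytes
  dissolve uniformly in the tissue water: a tissue at fresh-weight water
  content `wc` holds wc/(1 − wc) g water per g dry weight, so
  100 nmol g⁻¹ DW at wc = 0.5 is 10⁻⁴ M. This is the standard
  approximation when subcellular compartmentation is unknown; it is also
  why water content is carried on every sample record.

## Statistical layer

Per variable and series (stages within one species × tissue, and — since
figure-legend conventions differ on this — also jointly over
tissue × stage cells within species), `anova_tukey_letters()` runs
classical one-way ANOVA followed by Tukey's HSD (pooled variance,
studentized-range distribution, α = 0.05) and assigns a compact letter
display with the insert-and-absorb algorithm: groups sharing a letter do
not differ at α, groups sharing none do, exactly — the display is
consistent with the p-matrix by construction, and the suite asserts this
on every emitted grouping and cross-checks the sharing pattern against
`multcomp::cld`.

Pearson correlations (`correlation_matrix()`) are computed
pairwise-complete per species × tissue stratum with two-sided p-values;
cells with p > α are masked (the "crossed-out" cells of a correlogram),
zero-variance variables are marked missing. The arcsine square-root
transformation is applied before ANOVA and correlation to exactly the
[0, 1]-bounded variables — ARC, CRC, reducing power and the reduced
fractions of the ascorbate and glutathione pools — never to unbounded
ratios, which the transform would reject anyway.

## What the generator emulates — and what it does not

`make_default_truth()` encodes the study's qualitative contrasts as
orderings of cell means: Norway maple NAD(P) pools exceed sycamore's at
every matched stage and peak at G in embryonic axes; sycamore pools
decline monotonically; sycamore reduced:oxidized ratios exceed Norway
maple's; sycamore carries ~7× more total ascorbate in axes with a
DHA-dominated pool (AsA/DHA < 1); the sycamore axis glutathione pool
stays ~80% reduced; dry-seed water content is 0.10 / 0.30. The numeric
levels between those constraints are invented configuration, not
measurements. Stage profiles are piecewise-linear over normalized
germination progression, so designs with other stage grids interpolate
the same shapes.

Replicate noise is multiplicative lognormal with CV 0.1 by default —
concentrations are positive and assay CVs are scale-free, and ~10% is a
realistic between-replicate CV for plate-reader metabolite assays with
three biological replicates. Water content is carried per cell without
noise (a gravimetric measure, far more precise than the assays).
Concentrations are expressed as nmol g⁻¹ DW throughout; this is a
declared convention (the indices are unit-invariant; only the molarity
conversion consumes it).

Not emulated: extraction dilution and tissue-mass bookkeeping, assay
interference and plate-position effects, mechanistic cycling-assay
enzymology, and any seed biology beyond the measured analytes (hormones,
ROS). Passing tests therefore demonstrate that the *calculation path* is
correct and that the statistics behave as designed on data with the
study's structure — not that real plate-reader data are this well
behaved. In particular, real traces can be nonlinear early (lag phases)
and real replicate noise can be heavier-tailed than lognormal.

## Numerical choices and degenerate inputs

* OLS everywhere (calibration, kinetic rate): closed-form, no iteration.
* Ties in Tukey p-values at exactly α count as "not different"
  (`p ≥ alpha` shares a letter).
* Letter columns are ordered by each column's highest-mean member and
  lettered alphabetically, the common presentation convention.
* Zero denominators → `NA`; clipped subtractions → 0 plus a flag; samples
  with a clipped (zero) concentration on either side of a couple get a
  missing potential rather than an error.
* Generators restore the caller's RNG state; all randomness flows from
  the design's / function's seed argument.

## Problem sizes used in the checks

The test and acceptance workloads are sized for a single CPU: 10,000
random couple tables for the index-oracle equivalence (tolerance 1e-12),
2,000 null series of 7 stages × 3 replicates for the ANOVA type-I
calibration (0.05 ± 0.01), 25 seeded study replicates for the
correlation-sign recovery, and the full default design (78 samples) for
round-trip and structural checks.

## Known limitations

* The compact letter display is exact but not minimal in pathological
  non-transitive significance patterns (insert-and-absorb can emit more
  letters than the minimum); it is always consistent.
* The type-I calibration uses lognormal null noise at CV 0.1, where
  ANOVA's normality assumption is mildly violated — the observed
  rejection rate stays within the stated band, but heavier noise would
  shift it.
* Below the standard range the kinetic slope approaches the blank rate
  and recovered amounts are noise-limited; the pipeline reports them
  (flagged as extrapolation when outside the range) rather than
  censoring, mirroring how low-concentration samples are handled in
  practice.
* No multiple-testing correction is applied across the correlation
  matrix, matching the analysis style this pipeline reproduces; treat
  individual masked/unmasked cells accordingly.
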