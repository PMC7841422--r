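---
title: "Mechanistic prediction of human Vd,ss: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic prediction of human Vd,ss: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdsspredict)
```

## The problem

The volume of distribution at steady state, V~D,ss~ (L/kg), relates the
amount of drug in the body to its plasma concentration. Physiologically it
is a volume-weighted sum of tissue-to-plasma partition coefficients:

$$V_{D,ss} = V_P + V_E \cdot E/P + \sum_T K_{p,T} \, V_T$$

where $V_P$ and $V_E$ are plasma and erythrocyte volumes per kg body weight,
$E/P = (\mathrm{BPR} + \mathrm{Hct} - 1)/\mathrm{Hct}$ converts the measured
blood-to-plasma ratio into erythrocyte partitioning, and $K_{p,T}$ is the
plasma-referenced partition coefficient of tissue $T$. Everything in this
package serves the estimation of the $K_{p,T}$ vector from a handful of
measurable compound properties: log P, log D at pH 7.4, pKa values, the
fraction unbound in plasma (f~up~) and BPR.

## The unified partition equation

Tissue-composition Kp models in the Rodgers–Rowland lineage decompose a
tissue into extracellular water, intracellular water, neutral lipids,
neutral phospholipids, acidic phospholipids and extracellular protein, and
sum the drug's affinity for each compartment. The original formulation used
*different equations* for moderate-to-strong bases versus acids, weak bases
and neutrals, switching at basic pKa 7 — which creates a discontinuity for
compounds near the switch. This package implements the unified (single
continuous) variant: **all five terms are evaluated for every compound**,
and each term vanishes naturally when its driver is zero:

$$K_{pu} = f_{EW}
 + \frac{1 + X_T + Z_T}{1 + X_P + Z_P} f_{IW}
 + \frac{P f_{NL} + (0.3P + 0.7) f_{NP}}{1 + X_P + Z_P}
 + \frac{K_{a,AP}\, \mathrm{AP}\, X_T}{1 + X_P + Z_P}
 + K_{a,PR}\, \mathrm{RA}$$

with $X = 10^{pK_{a,\mathrm{basic}} - \mathrm{pH}}$ and
$Z = 10^{\mathrm{pH} - pK_{a,\mathrm{acidic}}}$ the Henderson–Hasselbalch
ratios at the tissue intracellular pH (subscript $T$) and plasma pH
(subscript $P$), and $P = 10^{\log P}$. $K_p = f_{up} K_{pu}$. The test
suite verifies continuity by sweeping the basic pKa from 4 to 11 in steps of
10^-3^ and bounding every step change by a local Lipschitz estimate — there
is no jump at pKa 7 (or anywhere else).

Two calibrations anchor the equation to measured data:

- **Protein affinity** $K_{a,PR}$ from f~up~, by writing plasma itself as
  water + lipid + protein (protein ratio 1 by definition):
  $K_{a,PR} = 1/f_{up} - 1 - (P f_{NL,P} + (0.3P + 0.7) f_{NP,P})$,
  floored at 0. It then scales by each tissue's protein ratio RA — the
  lipoprotein ratio for bases, the albumin ratio otherwise (the convention
  of this method family; the choice is a package decision, held fixed in
  all property tests so it cannot masquerade as an equation switch).
- **Acidic-phospholipid affinity** $K_{a,AP}$ from BPR, by inverting the
  same equation for the erythrocyte:
  $K_{pu,BC} = (\mathrm{BPR} - (1 - \mathrm{Hct}))/(\mathrm{Hct}\, f_{up})$,
  subtract the blood cell's water and neutral-lipid uptake, and attribute
  the remainder to AP binding of the cationic species. Compounds with no
  cationic species return 0; so does a BPR at the physical floor
  $1 - \mathrm{Hct}$ (with a warning naming the compound).

### Numerical and degenerate-input choices

- **Floors, not errors.** Negative calibration brackets (e.g. a highly
  lipophilic compound whose plasma lipid term alone explains 1/f~up~) floor
  at 0 with a warning; batch functions muffle and count these so sweeps
  complete. The same policy applies to $E/P < 0$.
- **The water limit keeps the phospholipid water.** As $P \to 0$ the lipid
  term tends to $0.7 f_{NP}$, not 0 — the 0.7 coefficient is the aqueous
  behaviour of drug in neutral phospholipid. The exact closed-form limit of
  the equation is therefore $f_{EW} + f_{IW} + 0.7 f_{NP}$, which the tests
  assert to 10^-12^; the residual above pure tissue water is below 0.02
  everywhere in the packaged physiology.
- **Adipose runs on log D.** Bulk fat behaves like an oil phase for the
  *distributed* (partly ionized) drug, so the adipose neutral-lipid term
  uses $10^{\log D_{7.4}}$ in place of $P$; a missing log D is derived as
  $\log D = \log P - \log_{10}(1 + X + Z)$ at pH 7.4.
- **Missing BPR defaults to 1.** Assuming BPR = 1 is the recommended
  fallback when no measurement exists; it outperforms plugging in weakly
  predictive model estimates (the package's sensitivity experiment below
  makes the same point on synthetic data).
- **Missing f~up~ is a hard error** — nothing can be calibrated without it.
- **Ionization classes** (used for stratified reporting and the RA choice)
  are: acid if an acidic pKa < 7.4 is present, base if a basic pKa > 6.0 is
  present, zwitterion if both, neutral otherwise. The classification rule is
  a documented package decision; no chemistry engine is involved.

## Physiology

`load_physiology("human_70kg")` ships a 12-tissue human table (adipose,
bone, brain, gut, heart, kidney, liver, lung, muscle, skin, spleen, plus a
"rest" lump for tissues not listed) with per-kg volumes, composition
fractions, acidic-phospholipid concentrations (mg/g), albumin/lipoprotein
ratios and intracellular pH, together with plasma (V~P~ = 0.0424 L/kg,
pH 7.4, neutral lipid 0.0023, phospholipid 0.0013) and erythrocyte rows
(V~E~ = 0.0347 L/kg, pH 7.22, AP 0.5 mg/g). The hematocrit is derived from
the blood volumes (0.450), so $V_E = \mathrm{Hct}/(1-\mathrm{Hct}) \cdot V_P$
holds by construction. Composition values follow the published
tissue-composition tables of the Rodgers–Rowland method lineage with
human-adapted adipose water/lipid fractions (the literature rodent adipose
row sums slightly above 1, which would violate the fraction-sum invariant);
intracellular pH defaults to 7.0 for all tissues. Total body volume is
0.968 L/kg, and adipose + muscle hold ≈60% of body volume — which is why
cell-partition assays target exactly those two tissues. Vendor
implementations may use slightly different tables; the file format is
documented and any table satisfying the invariants can be loaded instead.

## Allometry

Single-species scaling is
$V_\mathrm{human} = V_\mathrm{animal} \cdot f_{up,\mathrm{human}}/f_{up,\mathrm{animal}}$
with the correction on, or the identity with it off (useful when animal
f~up~ estimates are unreliable — the correction magnifies their errors).
Two-species scaling is log-linear,
$V_\mathrm{human} = 10^{a_0 + a_r \log_{10} V_\mathrm{rat} + a_d \log_{10} V_\mathrm{dog}}$,
defaulting to the unweighted geometric mean ($a_0 = 0$,
$a_r = a_d = 0.5$). Published fitted coefficients for a specific
two-species calibration can be supplied through the config
(`two_species = list(a0 =, a_r =, a_d =)`); the geometric mean is the
neutral default because it is scale-equivariant and parameter-free.

## Cell partitioning and the five strategies

Adipocyte/myocyte uptake assays yield peak-area ratios in cell lysate and
medium plus a protein measurement. Per replicate:
cell volume = 6.5 µl/mg protein; amount in cells = lysate area ratio ×
150 µl; Kp~cell~ = intracellular concentration / medium concentration.
Triplicates are averaged after per-replicate computation; zero medium signal
marks an analytical failure and excludes the replicate with a warning.

Because the medium is essentially protein-free, Kp~cell~ is referenced to
unbound drug; plasma referencing multiplies by f~up~
(`Kp_tissue = Kp_cell * fup`). The assay protocol leaves the referencing
algebra open, so the inverse convention (`"divide"`) is switchable in
`plasma_referenced_kp()` and the pipeline config.

The five V~D,ss~ strategies then fill the Kp vector: `adipocyte_only`
(fat measured, all else 1), `myocyte_only` (muscle measured, all else 1),
`combined` (both measured, all else 1), `average` (both measured, the
fat/muscle mean elsewhere), `separate` (both measured, mechanistic Kp
elsewhere). All five include the $V_P$ and $V_E \cdot E/P$ terms so they are
consistent with the mechanistic assembly; `separate` fed the mechanistic
fat/muscle values reproduces the full mechanistic prediction exactly (a test
asserts this equivalence).

## Evaluation metrics

Fold error is symmetric, $\max(p/o,\, o/p)$; percent-within-k counts
$FE \le k$ (boundary inclusive — the choice matters for ties and is
documented here because conventions differ); AAFE is
$10^{\mathrm{mean}|\log_{10}(p/o)|}$; and r² is the squared Pearson
correlation of $\log_{10}$ values, because V~D,ss~ spans orders of magnitude
and comparisons live on log-log axes (a linear-scale option exists behind
`log_scale = FALSE`). All metrics are invariant to row permutation and to a
common positive rescaling of predictions and observations.

## What the synthetic generator emulates — and what it does not

`sample_compounds()` draws a base-heavy ionization mix (45% bases, 25%
acids, 20% neutrals, 10% zwitterions — typical of small-molecule drug
sets), log P ~ Normal(2.5, 1.5) truncated to [−3, 7.5], acidic pKa ~
U[2, 7.4], basic pKa ~ U[5, 11] (raised above 6 so labels stay consistent),
a logit-normal f~up~ that falls with lipophilicity
(logit(f~up~) = −1.2 − 0.6(logP − 2.5) + N(0, 1.2), clipped to the 0.1%
assay floor), and BPR built from a latent blood-cell partition,
$\mathrm{BPR} = (1-\mathrm{Hct}) + \mathrm{Hct}\, f_{up}\, K_{pu,BC}$, with
$K_{pu,BC}$ log-normal and lipophilicity-linked for bases and ≈0.7 for
everything else. This construction guarantees $\mathrm{BPR} \ge 1 -
\mathrm{Hct}$ and makes the BPR→Ka~AP~ calibration meaningful by design.

**Ground truth is the mechanistic model itself**: observed values are the
model's own predictions times $10^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma)$, $\sigma = 0.3$ by default (about 2-fold
scatter, a realistic reproducibility level for clinical V~D,ss~
compilations). This self-consistency design makes parameter recovery
well-defined and exactly checkable: with $\sigma = 0$ recovery is exact
(AAFE = 1, 100% within 2-fold), and with $\sigma = 0.3$ the expected AAFE
is $10^{\sigma\sqrt{2/\pi}} \approx 1.74$ and the expected fraction within
3-fold is $2\Phi(\log_{10}3 / \sigma) - 1 \approx 88.8\%$ — the acceptance
tests check the computed statistics against these closed forms. What passing
these tests **does not** show: that the mechanistic model predicts *real*
human V~D,ss~ to any particular accuracy. Recovery statistics validate the
arithmetic and the pipeline, not the biology; real-data performance depends
on measurement quality and on mechanisms (e.g. transporter-mediated uptake)
the model does not capture.

The BPR-sensitivity experiment mirrors a qualitative finding: predictions
using the true BPR dominate predictions using the BPR = 1 fallback, which in
turn dominate predictions using a noisy BPR (true BPR ×
$10^{N(0, 0.6)}$ — a spread representative of weakly trained BPR
predictors). Observation noise is set to 0 in this experiment so the
ordering isolates BPR sensitivity; it is asserted strictly at n = 1000.

## Problem sizes and runtime choices

The package's own test and acceptance runs use n = 100 compounds for
oracle-equivalence checks, n = 500–2000 for recovery statistics, n = 1000
for the sensitivity ordering, and a 7001-point pKa sweep for the continuity
property — sizes at which every statistic above is stable to well within its
assertion band while the full suite runs in well under a minute on one core.

## Known limitations

- No transporter-mediated disposition, lysosomal trapping, or tissue-pH
  heterogeneity beyond the single intracellular pH per tissue.
- One acidic and one basic pKa per compound; multiprotic molecules must be
  reduced to their two most relevant constants upstream.
- The packaged physiology is a healthy 70-kg adult; no age, sex or disease
  adjustments.
- Rat/dog support is limited to scalar V~D,ss~/f~up~ allometry; no animal
  tissue tables ship with the package.
- The exact algebraic form of proprietary implementations of the unified
  equation is unpublished; this package documents its own form fully (above)
  and should be expected to differ in detail from vendor software.
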