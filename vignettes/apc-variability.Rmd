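---
title: "Quantifying cross-site and cross-platform variability of APC potency data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-site and cross-platform variability of APC potency data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcvar)
```

## The problem

Automated patch clamp (APC) platforms measure how strongly a drug blocks a
cardiac ion current, summarised as an IC50 — the concentration producing
half-maximal inhibition. Safety-pharmacology decisions (hERG safety
margins, CiPA-style proarrhythmia modelling) depend on these numbers, yet
when many laboratories measure the same blinded drugs on the same class of
instruments, the IC50s they report can differ by an order of magnitude.
`apcvar` implements the statistical pipeline for quantifying that
variability in a multi-site, multi-platform ring trial: well-level quality
control, concentration-response fitting, log-scale spread summaries,
between/within-platform variance components, repeatability coefficients,
and Bland-Altman platform agreement — plus a synthetic study generator so
the whole pipeline can be exercised and validated without any external
data.

The default study design carried by `apc_config()` is a 12-drug panel
(high, intermediate and low torsadogenic risk) tested against four
recombinant cardiac currents (hERG, peak and late Nav1.5, Cav1.2) across
17 sites running five anonymised APC platform lines (p1–p5 with 6, 4, 4,
2 and 1 datasets respectively); 16 sites contribute hERG data, 15 peak
Nav1.5, 8 Cav1.2 and 4 late Nav1.5.

## From raw wells to IC50s

Each well contributes three scalar currents: the pre-drug control, the
steady-state current in drug, and the residual current after a saturating
end-blocker (E-4031 for hERG, lidocaine for Nav1.5, cadmium for Cav1.2),
which estimates non-specific leak.

**Quality control** (`passes_qc()`) applies three inclusive criteria to
every well: membrane resistance ≥ 200 MΩ, leak current ≤ 25% of the
pre-drug peak, and a leak-subtracted baseline current ≥ 0.2 nA. The leak
criterion is operationalised as |end-blocker| / |pre-drug| ≤ 0.25, the
end-blocker current being the only leak proxy available in scalar
summaries, and the baseline criterion is evaluated on the leak-subtracted
amplitude |pre-drug − end-blocker|; whether the historical threshold was
applied before or after leak subtraction is not documented, so the choice
is stated here rather than inferred.

**Percent inhibition** (`percent_inhibition()`) is computed after
subtracting the end-blocker current from both the control and the drug
steady state:

$$
\mathrm{inhibition} = 100 \left(1 -
  \frac{I_\mathrm{drug} - I_\mathrm{leak}}
       {I_\mathrm{pre} - I_\mathrm{leak}}\right).
$$

Values are *not* clipped to [0, 100]: clipping would bias the
lowest-concentration (NOEL/LOEL) means toward positive block, which the
site-level bias summary (`noel_loel_summary()`) is designed to expose.
Rundown correction beyond an optional vehicle-shift
(`vehicle_correction()`, off by default, deliberately a plain
non-idempotent subtraction) is out of scope because historical practice
varied too much across sites to standardise.

**Curve fitting** (`fit_hill()`) uses the standard sigmoidal
four-parameter logistic on per-concentration *mean* inhibition,

$$
Y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
  {1 + 10^{(\log_{10}\mathrm{IC}_{50} - X)\, h}},
$$

with Top fixed at 100%, Bottom at 0%, the Hill slope $h$ constrained to
$(0, 2)$ (implemented as the box $[10^{-3}, 2 - 10^{-6}]$ since the upper
constraint is strict) and $\log_{10}\mathrm{IC}_{50}$ bounded to within
two decades of the tested range. Fitting per-concentration means,
unweighted, mirrors how the source datasets were produced; a weighting
scheme was never specified and none is invented here. The optimiser is
bounded Levenberg-Marquardt least squares (via `minpack.lm`) with a
three-point multi-start for $\log_{10}\mathrm{IC}_{50}$ (min, mid and max
of the tested log-range, $h_0 = 1$); the best RSS wins and near-ties go to
the slope closest to 1. Tests verify the fit against a dense independent
grid-search oracle.

**The no-fit rule.** Historically no curve was fitted when there was an
obvious lack of concentration-dependent inhibition and/or a small effect
size (≈ ≤ 20%). That informal rule needs a computable form; here a group
is censored as `no_fit` when the maximum mean inhibition is ≤ 20%
(`nofit_max_effect_pct`) *or* the Spearman rank correlation between
concentration and mean inhibition is ≤ 0. Groups with fewer than four
usable concentrations (each needing ≥ 3 wells) are
`insufficient_data`. Censored records never enter any downstream
statistic; they are counted as censored in the summaries.

**Single-concentration inversion.** For comparison with legacy
single-concentration screens, `invert_single_concentration()` inverts the
same curve exactly: $\mathrm{IC}_{50} = C\,((100 - I)/I)^{1/h}$. Applied
to a historical manual-patch dataset (60 nM terfenadine eliciting
81.7 ± 7.0% hERG block; 90 nM cisapride, 83.4 ± 7.7%), evaluating at the
mean ∓ 2 SD brackets the implied IC50 at about 3–29 nM for terfenadine
and 42–1093 nM for cisapride.

## Study-level statistics

All statistics operate on $\log_{10}$ molar IC50s — the scale on which
replicate potency measurements are approximately normal and differences
are fold ratios. Internally every concentration is molar; files use a µM
column by convention, converted on read, so a silent 10³ unit error
cannot propagate.

**Spread summaries** (`summarize_ic50()`): median, 25/75 percentiles
(linear interpolation between order statistics, the common
statistical-software default; no quantile convention was specified),
min/max and the interquartile span, reported both in log units and as
`fold_range` $= 10^{p75 - p25}$ (0.22 log units ↔ 1.7-fold).

**Variance components** (`variance_components()`): a one-way
random-effects ANOVA per drug × current with platform as the factor,
estimated by method of moments so it remains well-defined on the heavily
unbalanced rosters these studies produce:
$\hat\sigma^2_w = MS_\mathrm{within}$ and
$\hat\sigma^2_b = \max(0, (MS_\mathrm{between} - MS_\mathrm{within})/n_0)$
with $n_0 = (N - \sum_i n_i^2/N)/(k-1)$. Negative moment estimates are
truncated to zero and flagged. A decomposition is only attempted
(`feasible`) when at least three platforms carry ≥ 2 measurements —
scarcer designs cannot separate the two levels. REML mixed models are a
deliberate non-goal: with $k \le 5$ platforms the moment estimator is the
transparent, assumption-light choice, and confidence intervals on the
components are not reported.

**Repeatability** (`repeatability_coefficient()`): $1.96\sqrt{2}\,
\hat\sigma_\mathrm{resid}$ on the log scale, i.e. the typical (95%)
difference between two same-platform measurements; $10^{rc}$ expresses it
as a fold difference. The per-drug ANOVAs give one residual per drug, but
practice reports one coefficient per platform, so `repeatability()` pools
drug-mean-centred values within each platform across all drugs with ≥ 2
records there — the minimal bridge between the per-drug model and the
per-platform report, stated here as an interpretation.

**Agreement** (`bland_altman()`, `agreement_matrix()`): per-drug
differences of platform mean log IC50s (sites averaged first, since the
comparison is between platforms and replicate counts are inconsistent
across them), mean difference ± 2 SD limits of agreement — the multiplier
is 2, not 1.96, following the stated definition, and configurable — with
the HTS acceptance bound (−0.48, 0.48) log units, i.e. 3-fold. The sample
(n − 1) SD is used given the small number of shared drugs. All ordered
pairs are emitted to mirror a full comparison matrix; antisymmetry under
pair swap and invariance under global potency shifts are tested
properties.

## The synthetic study generator

`generate_study()` draws the hierarchical model the one-way ANOVA
assumes: for drug $d$ on site $s$ of platform $p$,

$$
\log_{10}\mathrm{IC}_{50}^{(d,s)} = \mu_d + b_p + e_s,\quad
b_p \sim N(0, \sigma_b^2),\; e_s \sim N(0, \sigma_w^2),
$$

then per-well inhibition
$\mathrm{maxblock}_d \cdot \mathrm{hill}(c)/100 + \varepsilon$,
$\varepsilon \sim N(0, \sigma_\mathrm{well}^2)$, converted back into
consistent (pre-drug, steady-state, end-blocker) current triples so the
QC and inhibition stages see realistic inputs. Random streams are keyed
per platform and per site × drug × current, so adding a site never
perturbs another site's data — a property the regression tests rely on.

Defaults, chosen once as realistic study conditions and documented here:

* `sigma_between = 0.3`, `sigma_within = 0.15` log units — mid-range of
  the spreads such ring trials report (interquartile spans from ~0.2 to
  ~1 log unit).
* `well_noise_sd = 5`% — no empirical well-to-well SD was published; 5%
  is a free parameter representing a well-behaved assay.
* `wells_per_conc = 5` with `qc_fail_rate = 0.1` — sites record more
  than the minimum three wells precisely because some fail QC; these
  values leave most concentration groups analysable while exercising the
  QC path.
* Current magnitudes: baseline 1 nA over a 0.1 nA end-blocker residual;
  membrane resistance lognormal with median 500 MΩ (σ_log = 0.3) floored
  at 125% of the QC threshold so that exactly the deliberately corrupted
  wells fail QC (each corrupted well violates exactly one criterion).
* True potencies (`apc_truth()`) are placed inside each drug's nominal
  tested range; all 12 drugs block hERG, six block peak Nav1.5, four
  Cav1.2 and four late Nav1.5, so the censoring path (no-fit rule) is
  exercised with the same blocker/non-blocker balance the four-current
  design produces.

The `study_preset()` uses the full 17-site roster and nominal
concentration panels; `minimal_preset()` is a compact hERG-only design
(concentrations centred on the true IC50) for fast end-to-end checks.
`generate_study(..., wells = FALSE)` returns only the site-level truth —
the identical draws — for Monte Carlo work on the statistics layer.

What the generator does *not* emulate: voltage-protocol and gating
kinetics (wells are scalar summaries by design), temperature dependence
of block, drug adsorption/solubility losses, rundown, or any systematic
(non-random) inter-site protocol deviation. Passing tests on synthetic
data therefore demonstrate the correctness of the statistical pipeline
under its own model, not the field behaviour of any instrument.

## Numerical choices and degenerate inputs

* Exact noiseless Hill data are recovered to ≤ 10⁻⁶ in both parameters;
  the fitted RSS is ≤ 10⁻¹⁰ (tested).
* A constant response has undefined Spearman correlation; it is treated
  as non-monotone and censored.
* `percent_inhibition()` refuses a zero denominator (pre-drug equal to
  end-blocker) rather than returning infinity; QC separately fails
  zero-amplitude wells.
* Empty post-QC studies degrade to empty tables with a warning, never an
  error; groups without usable records are omitted from summaries rather
  than emitted as NA rows.
* Ties in the multi-start optimiser resolve to the Hill slope closest
  to 1.

## Validation at desk scale

The test suite validates the statistics against independent oracles:
hand-computed unbalanced ANOVA on a three-platform toy
($\sigma_w^2 = 0.02$, $\sigma_b^2 = 0.24$), `stats::aov` on balanced
designs, a dense grid-search fit oracle, and a hand-computed Bland-Altman
example. Parameter recovery is checked by simulation: with
$\sigma_b = 0.3$, $\sigma_w = 0.15$ (a true between-platform share of
80%), 4 platforms × 4 sites × 12 drugs and 200 replicates, pooling each
replicate's per-drug variance components before forming the percentage
(the ratio-of-means aggregation) recovers the between-share to within a
point of 80%. Averaging the per-drug percentage ratios instead lands
near 69%: the individual moment-ratio estimates carry a substantial
downward Jensen-plus-truncation bias at $k = 4$ platforms. Users should
keep this in mind when reading a single drug's variance-component split
from a small platform roster — the components are unbiased, their
percentage ratio is not. The full-roster preset (~10⁰⁰⁰ wells, ~500 fits) runs
the complete pipeline in seconds; these problem sizes keep the whole
validation suite comfortably interactive.

## Limitations

* Variance components and repeatability inherit the small-$k$ bias noted
  above; they describe this study design, not platform truth.
* The no-fit rule is a computable stand-in for an expert judgement call;
  borderline blockers near 20% maximal effect are censored conservatively.
* Pre-fitted IC50 tables ingested via `read_ic50_table()` bypass QC
  entirely; their quality is the supplier's responsibility.
* Temperature class is carried as metadata only; no temperature-stratified
  modelling is attempted.
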