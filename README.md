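# apcvar

Cross-site and cross-platform variability analysis of automated patch
clamp (APC) drug-potency data.

## What this is for

Safety-pharmacology labs measure how strongly drug candidates block
cardiac ion currents (hERG, peak/late Nav1.5, Cav1.2) on automated patch
clamp platforms, summarised as IC50 values. When many sites measure the
same drugs on different instruments, the reported potencies scatter —
sometimes by an order of magnitude — and that scatter propagates straight
into hERG safety margins and CiPA-style proarrhythmia risk estimates.
`apcvar` is a pipeline for quantifying that scatter in a multi-site ring
trial, for statisticians and safety pharmacologists running (or
reanalysing) such studies:

- **QC and inhibition** — well-level quality gates (membrane resistance
  ≥ 200 MΩ, end-blocker leak ≤ 25% of peak, baseline ≥ 0.2 nA) and
  leak-corrected percent inhibition,
  `100·(1 − (I_drug − I_leak)/(I_pre − I_leak))`.
- **Hill fitting** — constrained four-parameter logistic
  `Y = Bottom + (Top − Bottom) / (1 + 10^((logIC50 − X)·h))` with
  Top = 100, Bottom = 0, h ∈ (0, 2), fitted to per-concentration means by
  bounded least squares, with a computable no-fit rule (≤ 20% maximal
  effect or non-positive concentration-response rank correlation) for
  non-blocking drugs.
- **Variability statistics** — log10-scale spread summaries
  (median, 25/75 percentiles, fold range `10^(p75−p25)`), one-way
  between/within-platform variance components by unbalanced method of
  moments, and repeatability coefficients `1.96·√2·σ_resid`
  (fold scale: `10^rc`).
- **Agreement** — Bland-Altman mean difference ± 2 SD limits of
  agreement per platform pair on log10 IC50, with the high-throughput
  acceptance bound (−0.48, 0.48) log units (3-fold).
- **Synthetic studies** — a hierarchical generator
  (`log10 IC50 = truth + platform effect + site effect`, plus well noise
  and deliberate QC failures) emulating a 12-drug × 4-current ×
  17-site / 5-platform design, so the whole pipeline is testable with no
  external data.

See `vignettes/apc-variability.Rmd` for the methods, model assumptions
and design choices.

## Worked example

```r
library(apcvar)

study <- generate_study(study_preset(seed = 42))  # full 17-site design
res   <- run_pipeline(study$wells)
res
#> <apc_study>
#>   wells: 10320  ( 9305 passed QC )
#>   fits: 516  ( 325 ok, 175 no_fit, 16 insufficient )
#>   drug x current summaries: 26  agreement pairs: 64
```

10,320 simulated wells pass through QC (about 10% fail, each for exactly
one reason); 516 site × drug × current groups are fitted, of which the
non-blocking drug/current combinations (e.g. most drugs against late
Nav1.5) are censored by the no-fit rule rather than given meaningless
IC50s. The per-drug hERG spread across the 16 contributing sites:

```r
subset(res$summaries, current_type == "hERG")
#>    drug_id  n n_censored median span_log fold_range
#> 1      bep 16          0  -6.96    0.152       1.42
#> 5      dof 16          0  -7.46    0.237       1.73
#> 8      qui 16          0  -5.86    0.400       2.51
#> 12     ver 16          0  -7.07    0.858       7.21   # (4 of 12 rows)
```

`fold_range` is the 25/75-percentile ratio on the concentration scale:
verapamil's IC50s here span 7.2-fold across sites while bepridil's agree
within 1.4-fold. Per-platform repeatability (hERG):

```r
subset(res$repeatability, current_type == "hERG")
#>   platform_id current_type n_drugs df sigma_resid rc_log rc_fold
#> 1          p1         hERG      12 47       0.159  0.442    2.77
#> 2          p2         hERG      12 36       0.143  0.396    2.49
#> 3          p3         hERG      12 36       0.141  0.391    2.46
#> 4          p4         hERG      12 12       0.150  0.416    2.60
```

`rc_fold` ≈ 2.5–2.8 means two same-platform measurements typically agree
within ~2.5–2.8-fold (the generator's within-platform SD of 0.15 log
units implies 2.6). Platform agreement, hERG, unordered pairs:

```r
subset(res$agreement, current_type == "hERG" & platform_a < platform_b)
#>    platform_a platform_b n_drugs mean_ratio loa_fold_low loa_fold_high pass_criterion
#> 1          p1         p2      12      0.958       0.1220          7.53          FALSE
#> 2          p1         p3      12      0.682       0.2065          2.25          FALSE
#> ...
```

No pair keeps both limits of agreement inside 3-fold
(`pass_criterion FALSE` throughout) — with a between-platform SD of
0.3 log units, platforms genuinely disagree by more than the
high-throughput screening acceptance bound allows, the same qualitative
conclusion multi-site comparisons of real APC data reach.

Single-concentration back-calculation (legacy screen data; 60 nM
terfenadine blocking 67.7% = mean − 2 SD):

```r
invert_single_concentration(60, 67.7)   # nM in, nM out
#> [1] 28.63072
```

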