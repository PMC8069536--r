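---
title: "Validating low-pass PGT-A mosaicism detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating low-pass PGT-A mosaicism detection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpmosaic)
```

## The problem

Preimplantation genetic testing for aneuploidy (PGT-A) infers chromosome
copy number (CN) from low-pass whole-genome sequencing of a
whole-genome-amplified (WGA) 5–10-cell trophectoderm biopsy. A mosaic
embryo carries a fraction *f* of aneuploid cells, so the expected CN of
the affected chromosome in the biopsy is intermediate — `2 + f` for a
euploid/trisomic mixture — and the question a clinical laboratory must
answer before reporting mosaicism is: *what is the smallest f the
platform can distinguish from a euploid sample (the limit of detection,
LOD), and how small a segmental event can it resolve?*

`lpmosaic` re-creates, as a fully simulated and tested pipeline, the
classic validation design for this question: reconstructed mixtures of
karyotyped cell lines (a 46,XY euploid line against 47,XX,+21 or
47,XX,+18) on the 10% fraction grid, two platform profiles with
different noise and bin size, euploid-range calibration, concordance
scoring with exact binomial confidence intervals, and a panel of
microdeletion cell lines (4.5–17 Mb, including Coriell lines GM08331
and GM06918 with their published hg19 coordinates) for segmental
resolution.

## The generator

One sample is a vector of per-bin read counts on an hg19-like grid
(0.9 Mb bins for profile A, 1.0 Mb for profile B; ~3,100–3,450 bins).
Counts are one multinomial draw whose bin probabilities factor as

> bin weight × GC amplification bias × (expected CN / 2) × per-bin
> lognormal WGA jitter,

with the total fixed at `round(total_reads × pf_fraction)` (profile A:
750,000 × 0.75; profile B: 600,000 × 0.75), so read totals are
conserved exactly and every quantity downstream is reproducible from a
single integer seed. The expected CN track of a mixture is the
fraction-weighted average of the component karyotypes' integer copy
tracks (a bin belongs to a segment when its midpoint falls inside it).
The GC track is a seeded, smoothed random walk mapped into [0.30,
0.60]; the GC bias is a smooth unimodal multiplicative curve of
amplitude 0.15 (A) / 0.20 (B) that the normalizer must remove without
being told its shape. The WGA jitter σ (0.05 on A, 0.08 on B at the
10-cell scale) shrinks with `sqrt(10 / cell_count)`, so the 100-cell
reference-curve sets are quieter than the 10-cell biopsy-scale sets.

What the generator deliberately does **not** emulate: mappability
structure, chimeric WGA artifacts, residual mismapping to absent
chromosomes (a simulated pure 47,XX sample reads Y ≈ 0.00 where real
platforms report a small background such as 0.08), fractional CN in
bins straddling a segment boundary, and GC bias that varies between
samples. Passing tests therefore demonstrate the *logic* of the
pipeline under a calibrated, well-behaved noise model — not platform
performance on real biopsies.

## Noise calibration — why these numbers

The central free parameter is the per-chromosome CN noise. We chose it
by a power analysis of the outcomes the pipeline must produce, *before*
running any acceptance check, and it is config
(`platform_profile()`), not code:

* With ~560k pass-filter reads on a 0.9 Mb grid, the multinomial
  counting floor alone puts the CN SD of the smallest autosome (chr21)
  at ≈ 0.021; the chosen jitter brings it to ≈ 0.026 on profile A and
  ≈ 0.036 on profile B, with a pooled autosomal SD of ≈ 0.016 / 0.023.
* The euploid range (the mosaicism band) must sit *between* the last
  undetectable and the first detectable mixture level: ±0.15 CN on
  profile A (10% inside, 20% outside) and ±0.25 CN on profile B (20%
  inside, 30% outside). With the pooled SDs above this fixes the band
  multipliers at `range_k` = 9 (A) and 11 (B).
* Those choices make the published error structure *statistically
  stable*: the detection margin at the levels adjacent to the band is
  ≈ 2σ on the noisiest chromosome and ≥ 4σ elsewhere, so the
  chromosome-level false negatives concentrate at 10% (profile A,
  36 = 12 samples × 3 chromosomes) and 10%+20% (profile B, 72), and
  2,550 expected-disomic comparisons at ≥ 6σ margins yield zero false
  positives run after run.

A much-discussed alternative — a narrow ±3 SD band on noise of SD
0.05 — cannot do this: a 3-SD band over 2,550 disomic trials produces
~7 false positives in expectation, misses at the 10% level only with
probability Φ(1) ≈ 0.84 (so ~6 of the 36 expected misses leak to 20%),
and makes the LOD unstable from seed to seed. We therefore treat the
band width, not the SD multiplier, as the platform's validated
quantity.

## Limit-of-detection rule

For each mixture level the replicate CN estimates of the trisomic
chromosome (both sets pooled, on the deviation-from-euploid-mean scale)
are compared with the euploid replicates. A level is **detected** when
its mean CN falls outside the calibrated euploid range *and* a
two-sample two-tailed Welch t-test against the euploid replicates is
significant at α = 0.05 (per-comparison, no multiplicity correction);
the LOD is the smallest detected level with all larger levels also
detected. The range carries the platform's validated cutoff; the
t-test guards against levels whose shift is not statistically
supported.

A pure t-test rule (`method = "ttest"`) is provided but is not the
default, for a structural reason worth recording: a t-test's rejection
probability at effect δ can never fall below α while its power at 2δ is
bounded by the same noncentrality scale, so *no* noise level makes
"non-significant at 10%, reliably significant at 20%" reproducible
across seeds — the best achievable per-run probability of that pattern
is ≈ 0.6. The euploid-range definition, by contrast, is an interval
property of the reference curve and is stable. With the calibrated
noise both components of the default rule agree on every level at or
above the band.

## Sex chromosomes

All calls are made against a declared 46,XY reference (in-silico
reference counts use CN 2 on autosomes, CN 1 on X/Y), so X mosaicism
appears as CN 1 + f and Y as 1 − f. A pure 47,XX line, however, is a
*normal female complement*, not aneuploidy: classification evaluates
(X, Y) jointly and scores the pair disomic when it is consistent with
XY (both within the band of their euploid means) or with XX (X within
the band of one copy above its euploid mean *and* Y consistent with
zero, tolerance 0.05 CN). The Y-zero condition is what separates a
pure XX sample from 90% mosaicism: at f = 0.9 the residual Y signal is
0.10 ± 0.005 — ten standard errors away from absent. Samples failing
both complements have X and Y classified against the male baselines
with the platform band.

## Normalization

Profile A bin counts are divided by the in-silico reference
expectation, corrected by GC-decile median factors estimated on
autosomal bins, and rescaled so the **autosomal** median ratio is
exactly 1. Scaling on autosomes only matters: in an XY/XX mixture the
X gain contributes ~5% of bins and the Y loss only ~2%, so a
genome-wide median would drift with the very signal being measured
(about −0.9% CN bias at high f, which we measured before excluding the
sex chromosomes from the scale). Bins with reference expectation below
the 1st percentile are masked. Profile B estimates CN as the reference
copy state times the ratio of the chromosome's read fraction to a
baseline averaged from 11 simulated euploid normals, then recenters the
median autosomal CN to 2 — read fractions are relative, so a genuine
trisomy compresses every other chromosome's fraction by ~3%, which the
recentering removes (the per-bin path gets the same effect from its
median scaling).

The discrete callers follow their published descriptions exactly: the
Gaussian caller scores states 0–4 with σ = 0.33, averages normalized
per-bin posteriors, and applies the ambiguity/median-fallback rule with
the printed constants (0.011 margin; gain > 2.5, loss < 1.5, strict).
The printed fallback condition triggers on *unambiguous* chromosomes —
textually backwards, but implemented literally by default with an
inverted mode available; on clean integer states both modes give
identical calls, and the continuous CN estimate (the quantity all
mosaic logic uses) is identical under either. The fraction caller's
printed discrete thresholds (gain CN > 3, loss CN < 1) are likewise
implemented as printed; they would leave a full trisomy at CN 3.0
undetected about half the time, which is precisely why mosaic
classification relies on the euploid range and never on them.

## Segmental detection

Sub-chromosomal events are called as maximal runs of at least
`min_run` consecutive bins outside a bin-level band of 3 robust SDs
(estimated from successive bin differences, so true segments do not
inflate it), with single interrupting bins merged and whole-chromosome
runs excluded. `min_run` is 4 on the 0.9 Mb grid and 5 on the 1.0 Mb
grid, giving nominal resolutions of 3.6 and 5.0 Mb: a 4.5 Mb deletion
covers 5 bin midpoints on the finer grid (detected) but only 4 on the
coarser one (missed), while 5.04 Mb covers ≥ 5 on both — the
resolution asymmetry between the platforms is geometry plus
configuration, not tuning. The two undetected samples on profile B are
both duplicates of the same 4.5 Mb line. A run-length detector was
chosen over CBS-style segmentation because the validated quantity here
is detection/non-detection at known sizes, not breakpoint accuracy.

One coordinate subtlety: GM08331's small chr21 deletion
(27,316,123–29,519,188) lies *inside* GM06918's 17 Mb chr21 deletion,
so in GM08331×GM06918 mixtures the shared region is deleted in both
components and carries no mosaicism signal. The mosaic segmental
series therefore quantifies the 17 Mb deletion on its private region,
which runs from 2.0 copies (100% GM08331) to 1.0 (100% GM06918)
exactly as the mixture arithmetic predicts.

## Concordance accounting

The 120-sample design yields 2,880 chromosome comparisons: each mosaic
sample contributes 3 expected-aneuploid chromosomes (trisomic autosome,
X, Y), each full-aneuploid sample 1 (its X/Y form a normal female
complement), totalling 330 expected aneuploid and 2,550 expected
disomic. Sensitivity and specificity use the standard TP/(TP+FN) and
TN/(TN+FP) definitions with exact Clopper–Pearson 95% intervals
(closed-form beta quantiles; for x = n the lower bound is
(α/2)^(1/n), reproducing the characteristic 99.86% bound for
2,550/2,550 and 54.07% for 6/6). The pipeline reports
formula-consistent point estimates from its own counts — e.g. 294/330
= 89.09% chromosome-level sensitivity on profile A.

## Problem sizes and numerical choices

Default runs use the full hg19-scale grid (~3,450 bins on profile A);
a whole 120-sample design simulates, normalizes and classifies in
about a second, so the packaged analyses use 6 replicates per mixture
level (the design), 30 euploid samples for range calibration, 11
normals for the profile-B baseline, 50–200 replicates for
recovery/curve summaries, and 1,000 euploid samples for the
false-positive floor. Ties in the Gaussian caller's per-bin state
assignment break toward the lower state; all seeds derive from one
master seed through a 31-bit string hash, so any sub-experiment can be
reproduced in isolation.

## Known limitations

* Calibration is outcome-anchored: the band widths are platform
  validation constants chosen so the documented detection limits
  emerge; applying the pipeline to a real platform requires
  re-estimating them from real euploid replicates.
* The LOD is defined on the trisomic autosome of the mixture design;
  chromosome-specific LODs (small, GC-extreme chromosomes) will be
  worse and are not reported separately.
* Segment boundaries are bin-resolution; no sub-bin refinement.
* The sample-level category collapses to euploid / aneuploid / mosaic /
  mosaic-aneuploid; clinical reporting bands (e.g. 20–70% rules) are
  out of scope.
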