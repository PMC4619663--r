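---
title: "Calling tissue-specific and developmental methylation dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tissue-specific and developmental methylation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
```

## The analysis model

`methdyn` works on beta values — per-CpG methylation fractions in
[0, 1] — from a methylation array measured over a factorial design of
tissues and gestational weeks with biological replicates. All calling
is threshold-based on replicate means, not model-based testing: the
scientific claim being encoded is "a reproducible difference of at
least Δβ", not "a statistically significant difference", so no
moderated variance model (limma-style) is involved. Two callers share
this logic:

**Tissue-specific hypomethylation** (`call_tissue_hypomethylation()`):
a CpG is called for tissue *t* when, at every week and against every
other tissue, the other tissue's replicate mean exceeds *t*'s mean by
at least `delta` (default 0.20, inclusive). CpGs whose beta SD across
all samples of tissue *t* (replicates pooled over weeks) is at least
`sd_max` (default 0.1) are discarded first as unstable. The
"against every other tissue" reading is the strict one; the weaker
"against the most methylated other tissue" is available via
`compare = "max"`.

**Gain/loss of methylation** (`call_dynamic()`): within one tissue, a
gain (GOM) requires `mean(W22) − mean(W9) ≥ delta` with the mid week
allowed to undershoot W9 or overshoot W22 by at most `w18_tol`
(default 0.05); a loss (LOM) is the mirror image. The SD filter here
is per (tissue, week) replicate cell — a different pooling than the
hypomethylation caller, matching the different stability concern
(an unstable time-point estimate rather than an unstable tissue
profile). Cells with fewer than two replicates leave the SD undefined
and exclude the probe, with a warning. Sample SDs use the n−1
denominator throughout; all threshold comparisons are inclusive (≥).

**Regions** (`call_regions()`): called CpGs are clustered into tHRs
(tissue-specific hypomethylated regions) or dDMRs (developmental
DMRs). A region is a run of array probes whose first and last members
match the criterion, containing at least `min_matching = 3` matching
CpGs and at most `max_nonmatching = 3` non-matching CpGs *in total*,
with at most `max_gap = 1000` bp between adjacent member probes. The
mismatch budget is read as a per-region total, not per consecutive
run; the normative semantics is the exhaustive one: among all probe
intervals satisfying the four constraints, keep those not contained in
another valid interval, then resolve overlaps deterministically by
preferring the leftmost-starting (and on equal starts the longer)
candidate and skipping candidates that share probes with an already
accepted region. The linear-time scan in `call_regions()` is checked
against a brute-force implementation of exactly this semantics in the
test suite. Probes discarded by the SD filters count as non-matching
by default (`drop_na = FALSE`); treating them as absent instead is a
one-flag change.

One non-obvious consequence of this semantics, found while testing:
*coverage is not monotone in the constraints*. Relaxing `max_gap` can
merge two probe segments so that an earlier-starting maximal candidate
spends its mismatch budget part-way into what was previously a
separate region; the leftmost-first tie-break then drops that region's
tail. The tie-break is what makes output deterministic, so we accept
non-monotonicity and verify behaviour by oracle equivalence across
parameter settings rather than by a monotonicity invariant.

## Annotation

Probes are classified on two independent axes.

*CGI axis*: a probe inside a (merged) CpG island is `CGI`; within 2 kb
of an island edge, a shore (`SHO`); within 2–4 kb, a shelf (`SHE`);
otherwise `NC`. Islands are half-open intervals on disk (BED); the
boundary is inclusive toward the island: a probe at exactly 2,000 bp
is a shore and at exactly 4,000 bp a shelf.

*Genic axis*: windows are strand-aware around the TSS. Offsets (in the
direction of transcription) of [−1500, +500] are proximal promoter
(`PP`), [−10000, −1501] distal promoter (`DP`), [+501, TES] gene body
(`GB`), (TES, TES + 5000] downstream (`DS`); everything else is
intergenic (`IG`). When a probe falls into windows of several genes or
types, precedence `PP > DP > GB > DS` applies (configurable): promoter
assignments dominate because a promoter context is the strongest
functional statement the annotation can make. A zero-length gene
(`tx_start == tx_end`) is legal; its gene body is empty and its TSS
equals its TES.

`median_by_feature()` reports, per combined (CGI × genic) feature and
(tissue, week) cell, the median over probes of the replicate-mean
beta; empty cells are `NA`, never zero. `methylation_class_fractions()`
bins replicate means into three classes split at 0.25 and 0.75 using
left-closed intervals `[0, 0.25)`, `[0.25, 0.75)`, `[0.75, 1]`.

## Enrichment and overlap statistics

`enrichment_or()` forms, per category, the 2×2 table *a* (called in
category), *b* (called out), *c* (background in), *d* (background
out), where the background is all QC-passing probes and contains the
called set. `OR = ad/bc`, with the Haldane–Anscombe +0.5 applied to
all four cells when any cell is zero; the p-value is the Pearson
chi-squared (1 df, no continuity correction) on the uncorrected
table. No multiple-testing correction is applied across categories —
raw chi-squared significance is reported, as is conventional for this
descriptive use.

`nearest_gene()` minimises the distance from a query position (probe
coordinate or region midpoint) to the nearer of a gene's TSS and TES,
with distance 0 anywhere inside the gene span; ties break by smaller
TSS distance, then lexicographic gene id, making output deterministic.

`permutation_overlap_test()` asks whether called regions intersect a
peak track more often than chance. The statistic is the number of
regions with ≥ 1 bp peak intersection. The null redraws the same
number of "DMR-like" regions — runs of `k = 3 + Poisson(2)` (mean 5,
minimum 3, matching the region caller's minimum) consecutive manifest
probes with inter-probe gaps under 1 kb — uniformly from the array's
probe space, `n_perm` times (default 20,000). Null regions are drawn
from probe space, not genome base space, because the observed regions
are themselves probe-defined. The two-sided p doubles the smaller
add-one-corrected tail, capped at 1, so the smallest attainable value
is `2/(n_perm + 1)` and p is never zero. No GC- or chromatin-matched
null (regioneR/GAT-style) is attempted.

## Expression trends

`cpm_matrix()` is plain counts-per-million (column sums exactly 10⁶);
no TMM or other normalization is layered on top. `geneset_trend()`
averages CPM over biological replicates per gene and week, then
reports the median and IQR over the genes of a set, plus per-gene
direction (sign of last-week mean minus first-week mean).
`direction_test()` is a two-sided exact binomial sign test of the
up-count among non-tied genes at p₀ = 0.5 — the simplest test of
"enrichment of up- or downregulation"; ties (including genes at zero
in both endpoint weeks) are dropped, and an all-tie set returns `NA`.

## What the synthetic data emulates — and what it does not

`simulate_dataset()` generates the full input bundle from one seed,
with a documented draw order (manifest geometry, betas, expression,
peaks), so identical configs are byte-identical on disk.

- *Design*: 4 tissues × 3 weeks × 3 replicates by default.
- *Geometry*: CpGs in clusters with 50–900 bp intra-cluster gaps
  (inside the 1 kb region limit) and 5–20 kb inter-cluster gaps
  (beyond the 4 kb shelf horizon); every planted block is one
  cluster, so planted effects are region-callable by construction.
- *Noise*: each observation is `Beta(μκ, (1−μ)κ)` around the planted
  mean μ. The bounded support matches beta values, and the
  concentration default κ = 200 gives SD ≈ √(0.25/201) ≈ 0.035 at
  μ = 0.5 — a replicate variability comfortably below the 0.1 SD
  discard threshold, as observed array data is after normalization.
  Real replicate variance magnitudes vary by dataset, so κ is a free,
  exposed choice.
- *Effects*: default planted blocks carry an effect of 0.30
  (hypomethylation 0.20 vs 0.50; GOM 0.20 → 0.35 → 0.50; LOM the
  reverse) — 50% above the 0.20 calling threshold, i.e. ≈ 3.5
  replicate-mean SDs of margin at κ = 200.
- *Peaks*: exactly `round(frac × n_LOM_blocks)` peaks centred in LOM
  blocks, decoys rejected away from every planted block.
- *Expression*: NB counts with lognormal baselines, library-size
  factors spanning a 2.5-fold range, and geometric 2-fold trends for
  block-linked gene sets. Linked sets are capped at 5% of the
  transcriptome each: with larger fractions the trend genes shift the
  library composition enough to bias CPM ratios visibly (a one-third
  split biases a 2-fold trend to ≈ 1.7), which is also why bulk RNA
  analyses treat CPM fold changes as interpretable only when
  differential genes are a small minority.

Not emulated: IDAT intensities, type I/II probe chemistry bias, SNP
probes, sex chromosomes, cell-type mixtures, spatially varying CpG
density, or correlated noise between neighbouring probes. Passing
recovery tests on this generator therefore demonstrates that the
calling logic implements its definitions correctly under realistic
noise — not that the thresholds are optimal for any particular real
dataset, where probe-level artefacts and inter-probe correlation
change the operating characteristics.

## Numerical choices and degenerate inputs

- Coordinates: probe positions are 1-based (manifest convention);
  interval tracks are 0-based half-open on disk and `GRanges` in
  memory, converted in exactly one place (`granges_from_bed0()`). A
  1-based position *p* overlaps a BED interval (s, e) iff s < p ≤ e.
- Readers reject rather than coerce: betas outside [0, 1], negative
  or fractional counts, `.` strands, `start ≥ end` BED lines (with
  line number) are errors naming the offender.
- Missing betas: a probe missing any value in a replicate cell gets
  `NA` for that cell's statistics and is excluded from callers that
  need the cell.
- QC: an observation fails on bead count < 3 or detection p > 0.01; a
  probe is removed when its pass fraction drops below 95% — the
  boundary is inclusive, so exactly 95% is retained.
- The permutation sampler truncates region lengths at the longest
  eligible probe run and errors if the requested number of
  non-overlapping regions cannot be placed.

## Problem sizes used in the test suite

The suite validates the callers at the default study scale — 20 seeds
of 20,000 probes (2,000 planted) for sensitivity and false-call rate;
1,000 random instances (≤ 30 probes) for region-caller oracle
equivalence; 200 repetitions × 1,000 permutations for the calibration
of the overlap test; 500 null gene sets for the direction test's
type-I error; 20 simulations for 2-fold CPM trend recovery. These
sizes keep Monte Carlo error well below the margins being tested
while the full suite runs in a few minutes on one core.

## Known limitations

- Threshold calling has no error control; counts of called CpGs are
  descriptive and depend directly on `delta`, `sd_max` and replicate
  number.
- The region semantics' non-monotonicity (above) means region counts
  can change non-intuitively when constraints are relaxed.
- The permutation null conditions on probe geometry only; peaks that
  preferentially fall in probe-dense regions (e.g. CpG islands) will
  inflate significance, as any unmatched null would.
- Chi-squared p-values are asymptotic; for very small categories the
  odds ratio is still reported but the p-value should be read with
  the usual small-count caution.
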