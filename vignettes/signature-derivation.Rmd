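---
title: "Deriving TF target-gene signatures from ChIP-seq and RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving TF target-gene signatures from ChIP-seq and RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfsig)
```

## The problem

A signal-dependent transcription factor such as STAT5 can change a gene's
expression directly, by binding regulatory DNA near the gene, or
indirectly, through intermediate factors. Neither a binding map nor a
differential-expression list alone separates the two: genome-wide binding
maps contain thousands of peaks near genes that never respond to the
upstream cytokine, and responsive genes are often not bound at all. `tfsig`
operationalises the standard resolution — call a gene a *direct target*
only when both lines of evidence agree — as a reproducible, parameterised
pipeline, and ships a synthetic-data generator with planted ground truth so
that every stage, and the end-to-end derivation, can be validated against a
known answer.

## Expression preprocessing

The expression model works on RPKM tables with 2–3 replicates per
condition, mirroring typical sorted-cell experiments.

1. **Transcript collapse.** When several transcripts are detected per gene,
   only the most abundant (highest mean RPKM across all samples) is kept.
   Exact ties break to the lexicographically smallest transcript id so the
   result is deterministic.
2. **Abundance filter.** A gene is kept iff its mean RPKM reaches 1 in at
   least one condition, evaluated on raw values. Condition means rather
   than single samples are used because replicate means are the unit of
   comparison throughout.
3. **Offset.** The second quartile (median) of *all* RPKM cells, pooled
   over genes and samples, is added to every cell. This pseudocount damps
   fold-change artifacts: a gene moving from 0.001 to 0.1 RPKM would show
   a 100-fold change, but with an offset of 1 shows 1.099. The pipeline
   fixes the order collapse → filter → offset → fold changes; filtering on
   raw values matches the "RPKM < 1" reading literally, and computing the
   offset after collapse keeps it a property of the analysed table. The
   applied offset is recorded on the table and double application is an
   error.
4. **DEG rule.** FC = ratio of post-offset replicate means
   (treated ÷ reference). A gene is differentially expressed iff FC
   strictly exceeds the threshold in either direction (default 1.5) *and*
   p < 0.05. Both inequalities are strict; no multiple-testing correction
   is applied at this stage (FDR control enters only in the enrichment
   analysis).

**P-values.** Precomputed p-value columns are first-class input, since
variance modelling engines are deliberately out of scope. For self-contained
runs the package provides `nb_exact_test()`: an exact conditional test under
a negative-binomial model with a common dispersion. Conditional on the
total count, the group-A sum has probability
∝ NB(s; n_A μ, n_A/φ) · NB(T−s; n_B μ, n_B/φ), and the two-sided p-value
sums all outcomes no more likely than the one observed. The common
dispersion is the method-of-moments estimate (v − m)/m² averaged over genes
and groups, floored at 1e-6 (the Poisson limit, where the test reduces to a
conditional binomial — this identity is used as a cross-check in the test
suite). The test holds its nominal size at n = 3 per group (empirical
type-I error ≈ 0.04–0.06 at the 5 % level over 2000 null genes), but it is
a simple stand-in: it shares no empirical-Bayes shrinkage with full
differential-expression engines and is not expected to reproduce their
p-values.

## Peak analytics

All coordinates are BED-native 0-based half-open internally; 1-based
tabular gene inputs are converted on read. The TSS of a minus-strand gene
is `end − 1`, the last covered base.

- **Assignment.** Peak → gene iff ≥ 1 bp gene-body overlap (the full
  transcript span; exon-level structure is not modelled) or minimum
  peak-to-TSS distance strictly below the window (default 50 kb, both
  directions). A pair satisfying both criteria is recorded once as
  `in_body`. Distances are signed, downstream-positive relative to the gene
  strand, 0 when the peak spans the TSS. Equidistant ties assign to every
  tied gene. The implementation stands on GenomicRanges interval trees; an
  all-pairs brute-force scan exists only as the independent oracle in the
  test suite, which checks exact equality on hundreds of random instances.
- **Condition comparison.** Overlap = ≥ 1 bp intersection with no
  reciprocal-fraction requirement. Shared counts are per side (A-peaks
  overlapping any B-peak), so many-to-one overlaps legitimately make the
  report asymmetric.
- **Amplitude quantile.** "Top 25 % of peaks" uses the type-7
  linear-interpolation quantile with a ≥ comparison, so an all-equal peak
  set is entirely flagged. Both the convention and the quantile are
  configurable because the underlying rule is stated without one.
- **Profiles and co-occupancy.** TSS-distance profiles bin each assigned
  peak once at its absolute distance to the nearest assigned TSS; empty
  bins report fraction 0 and undefined amplitude. Co-occupancy reports the
  fraction of anchor peaks overlapped by a partner factor plus signed
  midpoint distances for co-localisation histograms.

## Signature tiers

- **Full:** bound (≥ 1 assigned peak) ∧ |FC| more than twofold with
  p < 0.05 ∧ mean RPKM > 2 in at least one condition.
- **Compact:** bound through ≥ 1 top-quartile-amplitude peak ∧ more than
  threefold change ∧ the same expression floor.

The expression floor is attached to both tiers; its placement is ambiguous
in prose statements of such rules, and applying it to both preserves the
subset law compact ⊆ full, which the pipeline interface additionally
enforces by rejecting a compact fold-change threshold below the full one.
"Responsive" counts both directions, consistent with repressive TF activity
being common. Per-gene evidence records the highest-amplitude assigned peak
(ties to the smallest peak id). Gene identifiers are matched as exact
strings; no symbol aliasing is attempted, which is a real limitation when
mixing annotation vintages on real data.

Bound-versus-responsive summary statistics (the "donut" numbers) are plain
set arithmetic on the same two universes: the fraction of bound genes that
are DEGs, the fraction of DEGs that are bound, and the up/down split.
`signature_collapse_stats()` classifies a consumed gene set as
reduced/enhanced/unchanged under a contrast, either significance-gated or
on raw fold changes — both readings are provided because collapse-style
statements ("52 of 76 genes reduced") rarely specify the gate.

## Enrichment analysis

`gsea()` implements the weighted Kolmogorov–Smirnov running sum: hit
increments proportional to |metric|^p normalised to 1 over hits (default
p = 1), miss decrements 1/(N − N_h), ES = signed extremum. The null is
**gene-set permutation** — random same-size sets from the ranked universe —
rather than phenotype permutation, which is degenerate at 2–3 replicates
per group; this matches common practice at small n but is a documented
divergence from the original method's default. NES divides ES by the mean
|null ES| of matching sign; the nominal p is add-one smoothed over
same-sign nulls, (b + 1)/(n_same + 1), which keeps p strictly positive and
uniform under the null (verified by a Kolmogorov–Smirnov check against
U(0,1) over 2000 random sets in the test suite); FDR q pools observed and
null NES of matching sign. The default ranking metric is log2 fold change;
`signed_log10p` is available when precomputed p-values exist. Results are
exactly reproducible given the seed, and sets sharing a size share null
draws.

## The synthetic-data generator

`simulate_dataset()` plants: a bound gene set, a responsive gene set
(bound genes over-weighted by `overlap_rho`), per-gene |log2FC| =
`lfc_min` + a lognormal draw with a 60 % down-regulated majority, NB counts
(common dispersion 0.05, BCV ≈ 0.22 — the sorted-cell replicate regime),
and two-condition peak sets in which every bound gene receives at least one
treated-condition peak wholly inside the assignment window.

Design points worth knowing:

- **Condition sharing is exact by construction.** Each treated peak gains
  an overlapping reference twin with probability `shared_frac_treated`
  (default 0.25); reference-only peaks are placed by rejection against the
  whole treated set and sized so the reference-side shared fraction equals
  `shared_frac_exvivo` (default 0.5). So "a quarter of treated peaks shared,
  half of reference peaks shared" holds up to binomial error on one side
  and exactly on the other.
- **Expression skew.** Bound/responsive genes draw NB baselines from a
  high-expression lognormal (meanlog log 200), background genes from a
  lower one with a 35 % near-silent fraction. Real RPKM distributions are
  strongly right-skewed with a large silent mass — that is precisely what
  makes the pooled-median offset "small" relative to expressed genes. A
  generator without the silent mass produces an offset comparable to
  typical expression and the fold-change rules stop working; this is a
  faithful property of the method, not of the generator.
- **Identifiability geometry.** Default gene density is ~1 gene per 250 kb
  (1000 genes on 250–300 Mb), so neighbouring ±50 kb TSS windows rarely
  overlap and background peaks rarely create spurious bound calls. Real
  mammalian genomes are denser; on real data a peak frequently assigns to
  several genes, and gene-level binding calls are correspondingly noisier.
  Passing recovery tests on synthetic data therefore demonstrates the
  correctness of the rules, not immunity to assignment ambiguity.
- **Library-composition coupling.** Because RPKM divides by realised
  per-sample depth, strong planted inductions inflate treated-library depth
  and bias the measured fold change of every other gene downward — a real
  phenomenon the generator reproduces. The default magnitude distribution
  (lfc_min + lognormal(log 0.25, 0.4)) keeps this bias moderate; pushing
  `lfc_meanlog` up recreates visibly biased null fold changes, which is
  instructive but degrades planted-truth recovery.
- **Presets.** `strong_effect` (1000 genes, 120 bound, 100 responsive,
  |log2FC| ≥ 2, 3 replicates) is the planted-recovery setting: the derived
  full signature matches the planted bound ∩ responsive truth with Jaccard
  ≥ 0.9. `nk_cytokine` (4000 genes, 1000 bound, 400 responsive,
  overlap weighting 3) reproduces the donut structure: ≈ 20 % of bound
  genes responsive, ≈ 50 % of responsive genes bound, ≈ 60 % of responses
  negative.

What the generator does **not** emulate: read-level noise, peak-calling
uncertainty, replicate correlation beyond NB dispersion, chromatin-domain
background structure, multi-transcript genes (the collapse rule is
exercised by hand-built fixtures instead), and annotation mismatches.

## Numerical and degenerate-input conventions

- Medians of even cell counts are midpoints of the central pair; an
  all-zero table gets offset 0 and is unchanged.
- A reference mean of zero post-offset (possible only at offset 0) yields
  an undefined fold change; the gene is flagged and excluded from DEG and
  ranking universes.
- `nb_exact_test()` returns 1 for all-zero inputs and requires ≥ 2
  replicates per group.
- An enrichment set with no overlap with the ranked universe is skipped
  with a warning (an error for the single-set entry point); a set larger
  than the universe is an error.
- Empty signatures serialise as header-only TSVs and round-trip.
- Every stochastic routine takes an explicit seed, restores the caller's
  RNG state, and derives per-stage child seeds below 2^31, so stages can be
  re-run independently and whole runs are byte-reproducible (the output
  manifests contain checksums and no timestamps).

## Problem sizes used in validation

The shipped test suite validates the interval engine against a brute-force
oracle on 100 random instances of 200 peaks × 50 genes, the subset law over
100 simulated datasets of 200 genes, null calibration of the enrichment
p-values over 2000 random sets on a 1000-gene ranking with 1000
permutations, the NB test's size over 2000 null genes, and planted-truth
recovery on the `strong_effect` preset. These sizes were chosen to keep the
whole suite in the low minutes on a single core while leaving the binomial
error of each empirical check well inside its asserted band.
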