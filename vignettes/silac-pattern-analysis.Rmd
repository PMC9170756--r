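---
title: "Methods: triple-SILAC fatty-acid response patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triple-SILAC fatty-acid response patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacpatterns)
```

## The experimental design and its model

A triple-SILAC experiment labels three cell populations with light, medium
and heavy isotopic amino acids and mixes them before MS, so each protein is
quantified as two channel ratios in a single run: light/medium and
heavy/medium. Here the medium channel always carries the vehicle control;
the light and heavy channels carry a palmitic-acid (PA) treatment and a
combined treatment (PA plus oleic acid, or PA plus eicosapentaenoic acid).
Replicates alternate orientation — *forward* (light = PA, heavy = combined)
and *reverse* (swapped) — to cancel any systematic labeling bias. The
canonical design is two forward replicates and one reverse.

`harmonize_orientation()` inverts the labeling map per replicate, giving
per-replicate treatment/control ratios

$$r^{(PA)}_{j},\; r^{(comb)}_{j} > 0, \qquad j = 1 \ldots 3,$$

after which no stage needs to know the orientation. A property the package
tests end-to-end: the same truth simulated under a forward-only and a
reverse-only design yields *identical* harmonized summaries.

### Aggregation

A replicate counts as quantified only when **both** ratios are present,
because the pattern taxonomy needs both axes; proteins quantified in fewer
than `min_quantified = 2` replicates are dropped (the quantified-at-least-
twice rule). Per protein we report the arithmetic mean and sample SD
(denominator $n-1$; 0 when $n=1$) of the linear ratios — classification
statistics live on the linear scale because that is how summary values such
as "1.11 ± 0.16" are conventionally reported for this kind of data — plus
the mean per-replicate combined/PA ratio, and the per-replicate log2 ratios
kept only for the volcano t-tests. No ratio renormalization is applied by
default; `median_center_ratios()` exists behind an explicit call because
published mean ratios for such experiments sit near 1.0–1.45, suggesting no
recentering in the reference workflow.

## DEP calls and the volcano table

A protein is differentially expressed purely by fold change: mean ratio
$\bar r \ge \theta$ (up) or $\bar r \le 1/\theta$ (down) with
$\theta = 2$, boundaries **inclusive** exactly as the taxonomy defines them
(`0.5 < r < 2` is "no change"). Two-sided one-sample t-tests of the log2
ratios against zero annotate the volcano output; log2 is used because ratios
are multiplicative and up/down should be symmetric. p-values never gate DEP
status, and no multiple-testing correction is applied by default (raw
volcano p-values are the convention being reproduced; a Benjamini–Hochberg
column is available via `volcano_table(..., adjust = TRUE)`).

Degenerate inputs are flagged, not fudged: fewer than two replicates gives
`insufficient_replicates`; zero variance with nonzero mean gives
`degenerate` (t undefined); the all-zero vector is the exact null, t = 0,
p = 1.

## The canonical pattern taxonomy

The source tables for the nine patterns are glyph-coded drawings, not
machine-readable rules, so this package fixes a canonical interpretation —
a 3×3 category grid plus an enhancement subcell — and documents it as such:

| PA \\ combined | none | up | down |
|---|---|---|---|
| **none** | P1 | P2 | P3 |
| **up**   | P6 | P5 (or **P4** if enhanced) | P6 |
| **down** | P8 | P9 | P7 |

*Enhancement*: an up-regulated protein is P4 when its mean combined/PA
ratio again crosses the threshold ($\ge \theta$); symmetrically a
down-regulated protein with combined/PA $\le 1/\theta$ folds into P7. The
only threshold the reference analysis ever uses is two-fold, so enhancement
reuses $\theta$ rather than introducing a new tunable. (up, down) — PA-up
pushed below baseline — folds into P6, the reversed-up pattern. This map
reproduces the verbal anchors for P1/P2/P3/P5/P6/P7/P8, and leaves P9
(down under PA, up under combined) nearly empty, matching its observed
single-protein occupancy.

**Divisor choice.** Published per-pattern counts do not sum to the published
quantified-protein totals (4803 vs 4633 in the PA+OA table; 5281 vs 5471 for
PA+EPA) — an internal inconsistency of the source tables. `summarize_patterns()`
therefore reports both the count sum and the divisor, and computes
proportions over the divisor: that is the arithmetic under which P1 is
94.9% (= 4399/4633) and 58.5% (= 3200/5471), which the acceptance suite
verifies through the classifier rather than by quoting constants.

## Enrichment

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, computed by exact
summation of the mass function; the test suite checks it against an
independent binomial-coefficient enumeration on every instance with
$N \le 50$ and against a Monte-Carlo resampling oracle. A term passes when
$p < 0.01$ (strict), observed $\ge 3$, and enrichment factor
$k/(nK/N) > 1.5$ (strict) — comparison strictness exactly as those filters
are printed. Two background modes are explicit config rather than silent
defaults: the annotation universe (union of gene-set members and quantified
genes; a stand-in for a genome-wide background, which would be external
data) and `quantified_only`. Term redundancy is reduced by single-linkage
clustering over Jaccard similarity of member genes (threshold 0.5, each
cluster labeled by its lowest-p term); this approximates kappa-statistic
clustering and is documented as an approximation, not a reimplementation.

## TF-target overlap

Predicted TF targets are kept when **both** binding scores are strictly
positive and the binding site lies within 1 kb of the transcription start
site (inclusive). Whether the reference filter required both scores or
either is ambiguous; "both" is implemented and the threshold arguments are
exposed. The responder total is the intersection of the filtered targets
with the union of all non-P1 patterns — deliberately wider than P6 ∪ P8,
since reported responder totals exceed the P6 + P8 overlap counts alone.
The printed counts (173/65/25) depend on external ChIP and proteome
depositions and are out of reach offline; the pipeline stage itself is
fully implemented and property-tested.

## The synthetic-data generator

`simulate_dataset()` states a world and sticks to it:

* **Pattern mix** defaults to the nine-pattern proportions observed in the
  PA+EPA comparison (the more populated of the two published tables), so a
  default simulation exercises every pattern.
* **Effects** are 4-fold (`fold_up = 4`, `fold_down = 0.25`, one extra
  4-fold for P4 enhancement): comfortably outside the two-fold band, as the
  planted-effect recovery criterion specifies.
* **Noise** is i.i.d. multiplicative log-normal per protein × replicate ×
  axis with `log2_noise_sd = 0.2`, chosen so the linear-ratio SD near ratio
  1 is ≈ 0.14–0.16, the scale reported for real triple-SILAC replicate
  summaries. Ratios are strictly positive by construction.
* **Missingness** is completely at random per protein × replicate at 10% —
  a realistic dropout rate given that roughly 85–95% of proteins in the
  reference runs were quantified at least twice; intensity-dependent
  missingness is explicitly out of scope.
* **Seeding**: one master seed; protein *i* draws from a substream seeded by
  stable arithmetic on (seed, *i*), so growing `n_proteins` never reshuffles
  earlier proteins. Noise is drawn on the treatment-ratio scale *before*
  orientation mapping, which is what makes the forward/reverse invariance
  exact rather than statistical.

`simulate_annotations()` adds uniform background gene sets, one planted set
over-sampling a target pattern at configurable odds (odds 1 reduces exactly
to a background set), and TF-target flags elevated inside configured
patterns with a configurable fraction of filter-failing score/TSS rows.

What a green test on this world does **not** establish: peptide-level
effects (rollup, isotope impurity, labeling efficiency), search-engine FDR,
intensity-dependent dropout, or correlated noise across replicates. The
generator validates the statistics pipeline, not the MS acquisition chain.

## Numerical and degenerate-input choices

* Boundary semantics are frozen exactly as printed: `>= 2` up, `<= 0.5`
  down, open interval no-change; filter comparisons strict/strict/non-strict
  as listed above.
* An empty classification yields an all-zero summary flagged `degenerate`
  with undefined (NA) proportions, never a division by zero.
* Proportions must sum to 1 within 1e-9 when the divisor is the classified
  count; with a published divisor the count sum is reported alongside.
* The hypergeometric tail returns exactly 1 at observed = 0 without
  summation.
* Readers reject invariant violations (non-positive ratios, duplicate
  protein × replicate rows, undeclared replicates, negative TSS distances)
  with errors naming the offending row; missing-value tokens are "", "NA",
  "NaN".

## Known limitations

* The P4/P7 enhancement rule and the 3×3 canonical map are an
  interpretation of glyph-coded source tables; alternative readings (e.g. a
  dedicated over-reversal cell feeding P6) would shift borderline proteins
  between P4/P5 and P6/P7.
* Jaccard single-linkage is a coarser term-clustering than kappa-based
  membership clustering; cluster boundaries should not be over-interpreted.
* One-sample t on three log2 ratios has 2 degrees of freedom; volcano
  p-values are descriptive, which is precisely why they do not gate DEP
  calls.
* The genome-wide enrichment background of the reference workflow is not
  shipped; both available background modes change expected counts and hence
  factors.
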