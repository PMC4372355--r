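---
title: "Methods: single-library digital gene expression for root salinity responses"
author: "rootdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-library digital gene expression for root salinity responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootdge)
```

## Scope and model

`rootdge` implements the analysis chain of a single-library digital gene
expression (DGE) study of maize primary (PR), crown (CR) and seminal (SR)
roots under salt stress: one sequencing library per root type × condition,
no biological replicates, per-gene clean-tag counts compared directly
between the control and the salt-treated library of each root type.

The statistical core is the exact between-library test for tag counts.
Conditional on observing `x` tags for a gene in a library of `N1` total
clean tags, the probability of observing `y` tags in a second library of
`N2` total tags under the null of equal relative transcription is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!}
\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

a probability mass over `y` that is algebraically a negative binomial with
size `x + 1` and success probability `N1/(N1 + N2)`. The key assumptions
are those of the design: tag counts are Poisson samples of a library-
specific sampling depth, and the two libraries are the only information
about the two conditions. There is no between-replicate variance component
— with one library per condition none is estimable — so p-values measure
sampling noise only, not biological variability. This is why the package
also ships a replicate-free generator matching exactly this sampling model
(below) rather than pretending to validate properties the design cannot
deliver.

### Two-sided p-value

The printed mass defines probabilities of single outcomes; a test needs a
tail construction. `ac_pvalue()` doubles the smaller of the two cumulative
tails at the observed `y`,

$$p = \min\!\Big(1,\; 2\min\big(\textstyle\sum_{k \le y} p(k \mid x),\;
\sum_{k \ge y} p(k \mid x)\big)\Big),$$

the standard two-sided construction for discrete exact tests. The upper
tail is evaluated as one minus the lower tail below `y`, so no infinite
summation occurs. One-sided tails are exposed via `ac_tails()` for audit.

### Calling thresholds

A gene is a differentially transcribed gene (DTG) when its
Benjamini–Hochberg q-value is at most `fdr_max = 0.001` and its
|log₂(treatment/control)| is at least `min_abs_log2 = 1`; both boundaries
are inclusive, following the threshold wording ("≤", "≥"). Three choices
here were genuinely open and are resolved as follows:

* **FDR procedure.** Benjamini–Hochberg step-up is the default;
  Benjamini–Yekutieli is selectable (`fdr_method = "BY"`) for users who
  want dependence-robust control. Adjustment is per comparison (PR, CR, SR
  separately), since DTG sets are reported per root.
* **Which genes enter the adjustment.** The p-value is defined for every
  gene, including those with zero expression in one library, so the
  adjustment runs over all genes of the comparison; the "undetected" call
  then overrides any significance for zero-expression genes. The
  alternative (adjusting only over detected genes) gives slightly smaller
  q-values; with the design's very strict 0.001 cutoff the difference is
  immaterial in all simulations the suite runs.
* **Scale of the log ratio.** The ratio is computed on RPKM, not raw
  counts, so library size and gene length cancel consistently. Genes with
  zero RPKM in either library are flagged `undetected` — the "gray" class
  of the heatmap displays — rather than rescued with pseudocounts, which
  would manufacture ratios the data cannot support.

## Quantification and summary arithmetic

RPKM is `1e6 * C / (N * L / 1e3)` with `N` the reads uniquely aligned to
*genes* (not to the genome); the formula's own definition of `N` decides
this. Within a library the formula conserves mass:
`sum(RPKM * L / 1e3) = 1e6` exactly, which the suite asserts.

Printed summary percentages (mapping rates at two decimals, down-regulated
fractions at one decimal) use half-away-from-zero rounding
(`round_half_up()`); published tables of this kind are consistent with
that convention, and base R's half-to-even would disagree on exact halves.

Cross-root aggregation treats "regulated" as call ∈ {up, down}. A gene
regulated in several roots — even in opposite directions — counts once in
the union and is not root-specific; specific sets are therefore pairwise
disjoint by construction.

## Clustering

Profiles are rows of log₂ ratios (one column per root-type comparison).
Distances are Euclidean; linkage is complete (inter-cluster distance = the
maximum pairwise member distance). The agglomeration is implemented in the
package so its tie-break is specified: among minimal-distance pairs, the
pair with the lowest cluster indices merges first (leaves numbered in input
order, merged clusters in creation order). `stats::hclust` is used as an
independent cross-check on tie-free data in the tests, and a naive
recompute-from-scratch agglomerator is the brute-force oracle on small
inputs. Merge heights are checked to be non-decreasing — a property
complete linkage guarantees — on every clustering the pipeline runs.

Missing (gray) handling was not specified by the upstream tools this
emulates; the package's policy is: rows with any missing ratio are carried
into the output matrix, gray-masked, but excluded from distance
computation (`policy = "complete_rows"`). A `"pairwise"` policy (distances
over shared observed positions, at least one required) is available; rows
are never silently dropped. No row centering or scaling is applied —
profiles are already log ratios, and their sign is the displayed quantity.

## Enrichment

Term over-representation uses the one-sided hypergeometric upper tail
(equivalently one-sided Fisher), the test behind standard GO annotation
tools, with Bonferroni correction over `m` = the number of terms with at
least one annotated background gene, and significance at corrected
p ≤ 0.05. The background is the annotated genes present in the count
table (configurable). Annotations are used as given: no propagation up the
GO graph is performed, so parent terms are enriched only if annotated
directly.

## qPCR concordance

Relative abundance uses the classic ΔΔCt method with amplification
efficiency fixed at 2. Multiple reference genes (the usual trio being
*Zm18S rRNA*, *ZmActin*, *ZmUBQ*) are combined by the arithmetic mean of
their Ct values per replicate; the combination rule is rarely reported and
the arithmetic mean on the Ct (log) scale corresponds to a geometric mean
of abundances, the conventional choice. A qPCR ratio of exactly 1 has no
direction and never counts as agreeing; likewise non-directional RNA-Seq
calls (`not_significant`, `undetected`) never agree. Concordance is the
agreeing fraction over the genes shared between the two assays.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; they are first-class, tested code, not fixtures.

* **FASTQ** (`gen_fastq()`): reads of 49 bp (Phred+33) with exactly
  `round(n × fraction)` reads per planted defect class — adaptor inserted
  verbatim, N fraction strictly above 10 %, or more than half the bases at
  quality ≤ 5 — and defect classes mutually exclusive per read, so the
  retained-count arithmetic is exact. Clean reads are rejection-sampled so
  none violates any rule by chance. Defaults plant 5 % / 3 % / 7 %
  contamination in 10,000 reads.
* **Counts** (`gen_counts()`): six libraries (PR, PR-salt, CR, CR-salt,
  SR, SR-salt). Every gene shares the expected count `baseline_mean`;
  planted genes have their salt-library mean multiplied by `2^log2fc`.
  Counts are negative binomial with the Poisson limit at `dispersion = 0`
  — the default, matching the exact test's own sampling model for a
  replicate-free design. The package-level defaults (20,000 genes at mean
  250) give library totals of ~5 × 10⁶, the depth scale of real DGE
  libraries; validation suites use smaller gene counts so the whole test
  run stays in minutes.
* **Annotations** (`gen_annotations()`): each term annotates background
  genes at `base_rate` (default 0.05); the planted term annotates the
  target set at the probability whose odds are `odds_ratio` (default 10)
  times the background odds.
* **Ct tables** (`gen_qpcr_ct()`): a planted log₂ ratio `r` shifts the
  treated target Ct by `−r` cycles around a baseline of 25, with Gaussian
  Ct noise (default 0.15 cycles, a typical technical-replicate spread);
  references are flat across conditions.

What the generators deliberately do **not** emulate: sequencing error and
base-call miscalibration, alignment ambiguity (counts are taken as given,
as in the original design where alignment is upstream), per-gene expression
heterogeneity, correlated genes, and GO-graph structure. Passing tests
therefore demonstrate that the *statistical machinery* is correct under
its own model; they do not certify behaviour on real libraries, where
overdispersion beyond the single-library model makes the exact test
anticonservative — a known property of replicate-free DGE designs, and the
reason modern studies use replicated negative-binomial models instead.

## Validation suites and problem sizes

The test suite validates each component against an independent oracle:

* exact test: direct binomial-coefficient arithmetic for `x, y ≤ 30`
  (relative agreement 1e-10), the equivalent negative-binomial closed form,
  normalization of partial sums (≤ 1 + 1e-9, converging to 1), and exact
  `(x, y)` symmetry at `N1 = N2`;
* FDR: the hand-worked step-up example, monotonicity, and a null
  simulation — 2,000 genes × 50 seeds at baseline mean 100 — whose
  fraction of genes at q ≤ 0.001 must not exceed the nominal level;
* recovery: 10 planted genes at |log₂FC| = 3, baseline mean 1,000, 300
  genes × 50 seeds, requiring ≥ 95 % correct directional calls;
* filtering: planted-contamination FASTQ of 10⁴ reads retained exactly at
  the planted clean fraction, plus a naive per-read re-check oracle;
* clustering: brute-force agglomeration on ≤ 8 leaves, `hclust`
  cross-check, height monotonicity, permutation invariance;
* enrichment: exhaustive enumeration of all draws for backgrounds ≤ 12,
  planted-term recovery over 20 seeds (majority criterion);
* qPCR: hand-worked 2.0 / 0.5 ratios, identity and inversion properties.

These sizes were chosen once as the smallest scales at which each
property is statistically decisive.

## Numerical choices

* The mass is evaluated as
  `exp(y·log r + lgamma(x+y+1) − (lgamma(x+1) + lgamma(y+1)) − (x+y+1)·log1p(r))`;
  the grouping of the lgamma terms makes the expression bitwise symmetric
  in `(x, y)` when `N1 = N2`.
* Cumulative tails can exceed 1 by a few ulp; complements and doubled
  tails are clamped into [0, 1] rather than allowed to go negative.
* Both filter thresholds are strict inequalities ("greater than 10 %",
  "greater than 50 %"), read literally: 10 N in 100 bases is retained,
  11 is removed.
* Adaptor detection is exact full-substring matching — the simplest
  verifiable reading; mismatch-tolerant or prefix matching is out of scope.
* Removal attribution follows rule order (adaptor, then N, then quality),
  treating the rules as the ordered procedure they are listed as.
* Percentages round half away from zero (two decimals for mapping rates,
  one for down fractions).

## Limitations

* No replicate-aware inference: the exact test is the design's test, with
  the caveats above.
* The cross-root count summaries of any real dataset depend on its raw
  libraries; the package reproduces the arithmetic and the operating
  characteristics, not dataset-specific gene lists.
* GO analysis treats annotations as flat labels; KEGG pathway analysis and
  annotation assignment itself are out of scope.
* Reads failing a filter are removed whole, never trimmed; paired-end
  structure is not modelled.
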