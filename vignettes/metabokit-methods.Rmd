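---
title: "metabokit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metabokit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery inside metabokit, the
assumptions it makes about LC-MS feature tables, and the design choices we
made where several defensible conventions exist. It is written for the
analyst who needs to know exactly what each stage computes before putting
the numbers in front of a collaborator.

## The data model

A feature table is a features × samples matrix of non-negative peak
intensities with unique feature IDs and sample names; missing cells are
`NA`. Orientation is fixed — features in rows — and never guessed: a
transposed table fails the duplicate-name and numeric checks loudly, which
we prefer to silent auto-correction. By default a literal `0` is read as
missing, the common convention for peak-picking exports where zero means
"not detected" rather than "measured as zero"; `zero_as_missing = FALSE`
turns this off.

Sample metadata carries one or more *factors* (group labels), a sample
type (`biological` / `qc` / `blank`) and optional pairing tokens. Pooled
QC samples — repeated injections of a mixture of all study samples — are
recognised by the group label `QC` (case-insensitive) or an explicit
`sample_type` column. Metadata can be parsed out of column names
(`tissue_batch_replicate` with a configurable delimiter, last token
reserved for the replicate index); this convention is a declared dialect
of this package, chosen because it is what most facility naming schemes
reduce to.

## Preprocessing

Stages always run in the fixed order **impute → QC-RSD filter →
normalize → log10 → scale**, and each executed stage is appended to a
provenance table that the report reproduces verbatim. The order is a
design decision: imputation must precede everything that cannot tolerate
holes; filtering on QC RSD should see imputed (not interpolated-later)
values; normalization must see positive intensities, which log10 would
destroy; and scaling is only meaningful on the final, transformed values.

**Imputation.** `one`, `min5`, `mean`, `median` are per-feature
single-value rules. `min5` divides the per-feature minimum *observed
positive* value by 5 — a detection-limit surrogate appropriate for
left-censored (MNAR) holes; applying it per feature rather than globally
keeps the surrogate on each feature's own intensity scale. KNN imputation
works in feature space: neighbours are other features, distance is
Euclidean over co-observed samples rescaled by `sqrt(n / n_co)` so that
thin overlaps are penalised, and a missing cell receives the
`1/d`-weighted mean of the `k = 10` nearest neighbours observed in that
sample (feature mean as fallback). Feature-space neighbours were chosen
over sample-space ones because metabolomics tables are usually much wider
than they are tall, so feature neighbourhoods are better populated.

**QC-RSD filter.** For each feature the relative standard deviation
(`100 · sd/mean`, sample sd) across QC injections measures pure technical
variability; features above the threshold (default 30%, common practice
for untargeted QC) are removed. The filter needs at least two QC
injections and is monotone in the threshold.

**Normalization.** All methods except quantile reduce to dividing sample
`j` by a factor `s_j`:

* *internal standard*: `s_j = IS_j / geomean(IS)` — the geometric-mean
  rescaling keeps normalized data at the original intensity magnitude
  instead of collapsing it to ratios near 1;
* *linear baseline*: `s_j` proportional to the sample mean or median,
  scaled so the grand level is preserved;
* *PQN*: reference spectrum `r_i` = per-feature median over the QC
  samples when at least two exist, otherwise over all samples; then
  `s_j = median_i (x_ij / r_i)`, the most probable dilution factor. Using
  QCs as the reference when available makes the reference independent of
  group composition;
* *quantile*: every sample's sorted values are replaced by the
  across-sample mean of order statistics. Tied input values receive the
  mean of the reference values at the tied rank positions, so tied cells
  stay tied and column multisets are exactly equal afterwards.

PQN applied twice (with the reference recomputed from the normalized QC
columns) changes nothing, which the test suite checks; this is a useful
sanity property because it means the method estimates a *dilution* and
not an iterative rescaling.

**Transformation and scaling.** Log10 addresses the multiplicative,
right-skewed error structure of LC-MS intensities. Six per-feature
scalings are provided (center, auto, pareto, range, vast, level) with
their textbook definitions; pareto (`(x − m)/sqrt(s)`) is the default
because it damps the dominance of high-abundance features without
amplifying noise as aggressively as auto scaling. Features that are
degenerate for the chosen scaling (zero sd, range or mean) raise an error
by default; `drop_degenerate = TRUE` drops them instead and records the
count in provenance.

## Statistics

**Univariate.** Per-feature two-sided t-tests default to Welch's
unequal-variance form — group variances are rarely comparable in
metabolomics — with Student's pooled test and the paired t available by
flag. One-way fixed-effects ANOVA covers multi-group factors; with two
groups its F equals the squared Student t, which the suite verifies
numerically. Multiple testing is controlled with Benjamini–Hochberg
across the features of one analysis call, never pooled across analyses.
When both groups are constant and equal, the statistic is 0 and p = 1 (a
defined answer, not an error); a constant non-zero difference yields
p = 0 with a note flag.

**Fold change** is always computed on positive, untransformed (but
normalized) intensities — `raw_table` in the preprocessed object — even
when the tests run on log/pareto data, because a ratio of pareto-scaled
values has no concentration interpretation. Paired fold change is the
geometric mean of per-pair ratios, which is the only convention symmetric
under swapping the groups. One estimator caveat matters when reporting at
a fold-change cutoff: with multiplicative noise, the ratio-of-means
estimate of a true fold change `F` falls above `F` for only about half
the features, so recovery statements should use cutoffs strictly below
the effect size of interest, not at it.

**PCA** is the column-centred SVD of the samples × features view, with no
further rescaling (scaling belongs to preprocessing). Explained variance
is the eigenvalue share; loadings are unit-norm.

**PLS-DA** regresses the centred feature matrix on the centred one-hot
class matrix with NIPALS PLS2: per component, the weight/score/loading
iteration runs to a relative tolerance of 1e-10 (at most 500 iterations,
non-convergence is an error naming the component), then both blocks are
deflated. Companions follow standard chemometrics practice since a bare
"PLS-DA" underdetermines them: VIP scores (mean squared VIP equals 1 by
construction), R²Y, and Q² from stratified k-fold cross-validation
(default 7 folds; fold assignment is the only random element and is
derived from an explicit seed). Q² uses `1 − PRESS/TSS` with TSS taken
against training-fold class means. Classification is by the largest
predicted class column.

**Clustering** uses Lance–Williams agglomeration (single, complete,
average, Ward-on-distances) on Euclidean or correlation (`1 − r`)
distances. Leaf order is deterministic: at each merge the *tighter*
subtree — the one formed at the lower height, leaves counting as height
0 — comes first, ties broken by smallest original index. The ordered
leaves define heatmap row/column order, so two runs of the same data
always render identically.

**Correlation networks.** Pairwise Pearson or Spearman correlation with
two-sided p-values from `t = r·sqrt((n−2)/(1−r²))`, BH-adjusted over the
upper triangle only (one hypothesis per unordered pair). The network
keeps edges with `|r| ≥ 0.8` and `FDR ≤ 0.05` by default — a deliberately
conservative definition of "network analysis" (thresholded correlation
graph), since tighter definitions (partial correlations, Gaussian
graphical models) need more samples than typical designs provide.
Isolated nodes stay in the node list so degree-0 features remain visible.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a multi-tissue LC-MS study
at desk scale: feature baselines `b_i ~ 10^N(5, 1)` (intensities centred
on 1e5, spanning roughly three orders of magnitude); biological replicate
values `b_i · F_ig · ε` with planted group fold changes `F_ig` and
multiplicative log-normal noise of CV 0.15 (unit mean); pooled-QC
injections drawn around the realized grand-mean profile with CV 0.05,
mirroring what a pooled mixture actually measures; MAR missingness as a
uniform coin flip and MNAR missingness by preferentially (probability
0.8) deleting cells whose underlying intensity falls below a baseline
quantile. Within-group CV 0.15 and QC CV 0.05 are typical mid-range
values for untargeted LC-MS; they were fixed once as the generator's
study conditions. Everything is a pure function of the config, including
the seed.

What the generator does **not** emulate — and what passing tests on it
therefore cannot certify — includes chromatographic drift and
injection-order effects, batch structure, correlated feature blocks from
adducts/isotopes/in-source fragments, and heavy-tailed contamination. The
generator's role is to give every algorithm a ground truth, not to be
mistaken for real biology.

## Numerical and formatting choices

* CSV output writes doubles at 17 significant digits, so written tables
  read back bit-identical; XLSX is read (via readxl) but not written.
* BH adjustment delegates to `stats::p.adjust` and is cross-checked in
  the suite against a literal step-up implementation.
* Ward linkage maps to `hclust`'s `ward.D2` (Ward on Euclidean
  distances).
* KNN distance ties between candidate neighbours break by feature index;
  zero-distance neighbours are averaged unweighted.
* Figures render through deterministic devices (ragg for PNG) with no
  wall-clock state and fixed circular network layouts, so identical
  inputs give identical bytes; report building takes an injected
  timestamp for the same reason.
* The HTML report embeds every figure and table as `data:` URIs; a scan
  for external `src`/`href` references is part of the test suite.

## Problem sizes in the test suite

The suite exercises the oracles on instances small enough to enumerate
(≤ 50 features for brute-force KNN/PQN/clustering checks), a 500-feature
2 × 10 null simulation for type-I-error calibration, and a 14-group ×
6-sample + 6-QC, 1000-feature design with 5% of features planted
1000-fold higher in one group for end-to-end recovery — the scale at
which a desk machine reproduces the extreme-tissue pattern in seconds.

## Known limitations

No batch-effect correction, blank subtraction or drift modelling; no
OPLS-DA or sparse variants; no pathway or annotation layer; ANOVA is
one-way fixed-effects without post-hoc contrasts. The report is static
HTML by design — interactivity would pull in a JavaScript dependency and
break the self-containment guarantee that makes the reports archivable.
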