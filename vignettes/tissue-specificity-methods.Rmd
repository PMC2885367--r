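---
title: "Methods: scoring, comparing and consolidating tissue-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, comparing and consolidating tissue-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuecons)
```

## The problem

Compendia of normal-tissue expression profiles exist for several
microarray and sequencing platforms, but the gene lists they suggest —
"which genes are specific to brain, liver, kidney?" — agree far less across
platforms than one would hope. `tissuecons` implements a complete
workflow for this situation: score tissue specificity within each
dataset on a common scale, attach permutation-based significance that is
comparable across platforms with very different value distributions,
quantify how similar the datasets are globally, correct for unequal
sample numbers per tissue, and integrate the per-dataset rankings into a
consolidated list whose reliability can be cross-validated.

All stages operate on plain numeric matrices (features × samples, `NA`
for missing values) and named sample→tissue-class vectors, so the
package applies equally to merged public compendia and to the bundled
synthetic generator.

## Specificity scores

Both scores start from a class-averaged log2 expression matrix
(`average_by_class()`), with probe-level data first collapsed to genes
by arithmetic mean (`collapse_probes()`).

**PEM** (preferential expression measure). For gene $g$ and tissue class
$t$,
$$\mathrm{PEM}(g,t) = S(g,t) - A(g),$$
where $S$ is the gene's average log2 expression in class $t$ and $A$ the
unweighted mean over all $K$ class averages — i.e. the log2 ratio of
tissue expression to mean expression. Positive values mark
over-expression, negative under-expression; complete rows sum to zero,
and the score is invariant under per-gene additive shifts (so gene-wise
platform offsets cancel).

**MAX.** Per gene, the difference between the largest and
second-largest class fold change, assigned to the tissue of maximal
expression and zero elsewhere. A gene highly expressed in several
tissues gets a large PEM in each but a small MAX; a large MAX singles
out *uniquely* over-expressed genes, the natural marker-gene candidates.
Ties at the top give MAX = 0: such a gene is not uniquely expressed
anywhere.

## Permutation significance

Because the four platforms the method was designed around have wildly
different value distributions, parametric thresholds on the scores are
not comparable. Instead `specificity_scores()` builds, per dataset, a
background by $N = 100$ global shuffles of the sample→class assignment —
conserving every class's size, which is what makes classes with few
replicates behave honestly — and recomputes class averages and scores
each time. For a tissue's observed score $s$ the empirical false
discovery rate is
$$\mathrm{FDR}(s) = \frac{\tfrac1N \#\{ \text{background} \ge s \}}
                        {\#\{ \text{observed} \ge s \}},$$
capped at 1, with the mirrored ($\le$) form for the under-expression
tail. The raw ratio is a step function and not automatically monotone,
so each gene receives the minimum raw estimate over all thresholds whose
called list contains it; without this, list membership would not be
consistent across cutoffs. FDRs are computed per tissue and per dataset,
pooling genes within a tissue — the granularity at which the score
distributions are homogeneous.

Gene lists use the conventions: over-expressed = positive PEM and
FDR < 0.25; under-expressed = negative PEM and lower-tail FDR < 0.25;
uniquely over-expressed = MAX > 0 and FDR < 0.25. The 0.25 default is
deliberately permissive; it is a list-building cutoff, not a per-gene
error rate.

## Comparing datasets

`correlation_of_correlations()` computes, within each dataset, the
Spearman correlations of all feature pairs (gene pairs across tissues,
or tissue pairs across genes) and Pearson-correlates the two vectors of
coefficients between datasets. Its null scale comes from
`randomized_baseline()`, which permutes every gene's profile across
columns independently in both datasets (10 draws by default; the number
is configurable because a single draw already has a very concentrated
null). Ward clustering (`cluster_datasets()`, `ward.D2`) on the
dissimilarity $1 - r$ summarizes which platforms share the most
structure. Differential-expression concordance for a single tissue uses
gene-wise pooled-variance t statistics (`class_vs_rest_tscores()`);
for datasets without within-class replicates the function accepts a
logical super-grouping of arrays (e.g. brain versus non-brain), the only
design under which a two-sample test is defined there.

Spearman correlations on matrices with missing values are computed by
ranking each feature once over its non-missing entries and applying
Pearson with pairwise-complete observations; this is exact Spearman on
complete data and a standard approximation otherwise.

## Sample-size calibration

Detected-gene counts rise steeply with the number of replicates in a
class, so raw per-tissue counts are not comparable.
`subsample_detection_curve()` quantifies the effect;
`adjust_fdr_threshold()` computes, for a reference class reduced to $s$
samples, the smallest achievable FDR cutoff $\alpha'$ at which the
reduced data still yield the full-data count $N_{\mathrm{ref}}$ of
significant genes. Since the empirical-FDR estimator is a step function,
$\alpha'$ is taken as the $N_{\mathrm{ref}}$-th smallest q-value among
positively scored genes (1 when unreachable); exact equality with a
continuous $\alpha$ is generally unattainable, so the degenerate case
$s$ = full class size yields the tightest achievable value just below
$\alpha$ rather than $\alpha$ itself. Over `n_reps` subsampling
repetitions (1000 in the original design; configurable down to 50 for
desk-scale runs) the 5th percentile of the $\alpha'$ distribution —
linear interpolation between order statistics — is reported as a
conservative adjusted threshold.

## Consolidation and cross-validation

`consolidate_by_mean_rank()` ranks genes by descending MAX within each
dataset (average ranks for ties, including the tied-at-zero mass of
genes maximal elsewhere, which keeps non-argmax genes neutral), averages
ranks across datasets, and orders by mean rank with gene-id tie-breaks.
All common genes are rankable by default; `restrict_positive = TRUE`
applies the stricter MAX > 0-in-all-datasets filter used by the
cross-validation. `cross_validate()` holds out each dataset in turn,
consolidates the rest, and compares the held-out MAX scores' Spearman
correlation with the consolidated scores (negated mean rank) against the
mean of its pairwise correlations with the individual datasets.
Averaging independent noise is exactly why the consolidated correlation
should win, and the acceptance checks verify it does on every held-out
platform across ten simulated compendia.

## Enrichment profiling

Tissue gene sets (by default PEM > 0.8, about 1.74-fold over the
gene's mean) are tested against *informative* ontology categories:
propagated annotation count above a threshold (300 for genome-scale GO;
tests use smaller toy thresholds) while every child stays below it.
Enrichment is a one-sided Fisher exact test against the assayed-gene
universe — not the whole genome, since the background must match what
the platform could have detected — with Benjamini–Hochberg adjustment
across categories within each tissue. Profiles are clustered with Ward
on Euclidean distances of $-\log_{10}$ FDR, which spreads the
informative tail better than raw FDRs (the display scale remains FDR).
The OBO reader is a minimal `[Term]`/`id`/`name`/`is_a` parser and only
`is_a` edges propagate annotations.

## The synthetic generator

`simulate_compendium()` emulates the structure of a merged
multi-platform compendium on the log2 scale:

* per gene a global baseline $\mathcal N(8, 2)$, per platform a gene-wise
  additive bias $\mathcal N(0, 0.25)$ — the platform-dependent probe
  effects that PEM and MAX cancel by construction;
* 19 tissue classes by default, with unequal replicate counts (1–10)
  mirroring merged public compendia where brain dominates and several
  tissues have a single array; any per-platform layout can be supplied,
  including a no-replicate platform;
* planted tissue-specific genes drawn from the shared gene core, with a
  fixed log2 effect (default 3, a strong but realistic tissue marker) or
  a uniform range of effects when a heterogeneous true ranking is needed
  (as in the cross-validation experiments), an optional under-expressed
  fraction, Gaussian noise (default sd 0.7 per sample), and missing
  values on the last, cDNA-like platform (rate 0.1).

The generator reproduces what the downstream statistics consume —
shared signal, platform bias, unequal replication, missingness — but
not probe-level effects, spatial artifacts, correlated gene modules
beyond the planted classes, or heavy-tailed noise. Passing tests
therefore demonstrate the estimators' correctness and calibration under
a Gaussian log2 model, not performance guarantees on any particular
real platform.

## Numerical and design choices

* Means ignore missing values everywhere; a gene-tissue cell with no
  observation propagates as an undefined score/FDR rather than a zero.
* Linear-scale inputs are log2-transformed after probe collapsing, with
  values ≤ 0 masked first (MAS5-style summaries can be negative).
* Gene ordering is lexicographic everywhere, so matrices from different
  datasets align positionally after `intersect_genes()`.
* Test and acceptance problem sizes — 2000 genes, 8 classes of 3
  samples, 100 permutations, 10–20 replicates — were chosen as the
  smallest sizes at which the planted-recovery, null-calibration and
  consolidation-benefit properties are stable, and run in well under a
  minute each.
* Null calibration is assessed per tissue-wise gene list (the unit the
  method produces): on a pure-noise compendium any nonempty list is
  entirely false discoveries, so the average per-list false-discovery
  proportion over tissues and replicates is the meaningful realized
  error, and stays within twice the nominal 0.25 level.
* The pipeline (`run_pipeline()`) derives one deterministic seed per
  stage from the master seed, writes every intermediate TSV, and records
  md5 checksums in a JSON manifest so identical configs yield identical
  outputs.

## Known limitations

Empirical FDRs are granular at small $N$ (multiples of $1/N$ per
observed-count step), so thresholds below $1/N$ are not resolvable.
The correlation-of-correlations matrix is quadratic in gene number;
restrict to a few thousand genes or subsample for larger compendia.
Cross-validation requires at least three datasets and at least three
genes with MAX > 0 everywhere, which sparse tissues may not provide.
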