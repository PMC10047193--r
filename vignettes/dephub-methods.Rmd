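---
title: "Effect-size differential proteomics with topological hub consensus: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-size differential proteomics with topological hub consensus: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dephub)
```

## The problem

Label-free DIA proteomics of a two-group animal study (for instance, a
seizure-prone rodent strain against matched controls, six replicates per
group) delivers a protein × sample matrix of log abundances after
quantification and normalization. dephub implements the post-quantification
analysis of such a matrix: handling missing quantifications, calling
differentially expressed proteins (DEPs) on effect size rather than fold
change alone, flagging group-exclusive proteins and extreme fold-change
outliers, sample-level quality control, testing whether DEP direction is
associated with functional categories, condensing a scored protein–protein
interaction (PPI) network to consensus hub proteins, and screening
gene–disease association tables. The matrix values are treated as opaque
log units; no log base is assumed or re-interpreted.

## Stage order and the missingness model

The stages run in a fixed order, and the order is load-bearing:

1. **Group-exclusive detection** on the *raw* matrix. A protein is
   exclusive to a group when every value in the other group is missing and
   at least `min_present = 3` values exist in its own group. Such proteins
   can never survive the NA filter (their ≥ 6 missing values exceed the
   3-NA cap), so running this stage later would silently lose them. The
   pipeline asserts this provenance in its report.
2. **NA filter**: keep a protein only with ≥ 4 observed replicates in
   *each* group and ≤ 3 missing values in total. For the 6+6 design this
   is equivalent to ≤ 2 NAs per group and ≤ 3 overall; the test suite
   checks the rule against a brute-force enumeration of all 49
   `(na_control, na_case)` patterns.
3. **Per-sample mean imputation**: each remaining missing cell takes the
   mean of the observed values of its own sample column, computed before
   any filling. "Sample mean" is read as the per-replicate (column) mean —
   the dataset is subsetted by replicate and each hole filled from that
   replicate's observed proteins. A consequence used as a numerical
   invariant: column means are unchanged by imputation (asserted to
   1e-12). No model-based imputation is offered; the method is defined by
   mean substitution, and the per-protein imputation count is carried into
   the DEP table so heavily imputed calls remain auditable.

Exclusive detection generalizes "all six missing" to "all values in the
group missing" for designs with other replicate counts; `min_present`
stays 3 by default and is configurable.

## Differential expression

Per protein, with the reference (control) group first in `group_levels`:

* fold change `FC = mean_case − mean_control` (a difference of log
  abundances, i.e. a log fold change — the two terms are used
  interchangeably here, and both the FC and Cohen's-d columns are always
  reported side by side);
* pooled SD `= sqrt((sd_control² + sd_case²)/2)` — the equal-n pooled SD,
  with the division by 2 inside the root;
* Cohen's effect size `d = FC / pooled SD`;
* a two-sided two-sample t-test p-value. Welch (unequal variances) is the
  default, Student's pooled-variance t is a config option. The Welch
  formulas are vectorized across proteins for speed and are checked
  against `stats::t.test` to 1e-10 in the tests. Failures are caught per
  protein rather than aborting the map over proteins: a protein in which
  both groups have zero variance admits no finite t statistic and is
  flagged `degenerate` (d and p are `NA`), and degenerate proteins are
  never called DEPs.

A protein is **up-regulated** iff `p < 0.05` and `d > 2`, **down**
iff `p < 0.05` and `d < −2`. All cut-offs are strict inequalities, so
boundary ties (`d = 2.0` exactly) are non-significant; this is the
documented tie-break everywhere in the package (edge scores, outlier
cutoff and disease scores behave the same way).

**Outliers.** Over the called DEPs only, the absolute fold changes are
summarized by their mean and sample SD; the parametric cutoff is
`mean + 2·SD` and a DEP is an outlier when `|FC|` strictly exceeds it.
With fewer than two DEPs no cutoff is defined and the stage errors.

No multiple-testing correction is applied: DEP calling couples the
marginal p-value with a large effect-size requirement instead, which is
the convention this analysis follows; a correction hook would be a
one-line change but defaults off to preserve the method's semantics.

## Multivariate quality control

Sample-level Euclidean distances and Pearson correlations over
protein-vectors, complete-linkage hierarchical clustering (linkage is
configurable; complete is the default of the environment this analysis
style comes from), and k-means (k = 2, Euclidean, seeded, best of 10
restarts on within-cluster SS) followed by PCA on the mean-centered,
unscaled sample × protein matrix (values already share a log scale;
scaling is an option). PCA is reconstructive to 1e-9 and explained
variance fractions are non-increasing — both asserted. When only a few
percent of proteins carry an effect, PC1/PC2 legitimately explain little
variance and groups need not separate; the QC stage reports, it does not
gate.

## Direction–category association

For one ontology (GO-CC, GO-BP, GO-MF or KOG), the contingency table
counts up- and down-regulated DEPs per category; a DEP annotated to
several categories counts once in each (GO is a DAG; no propagation or
genome-background enrichment is attempted). The Pearson chi-squared
statistic is computed against margin-derived expected counts, and the
p-value is Monte-Carlo: `n_sim = 2000` null tables with the same margins
(`stats::r2dtable`, the standard fixed-margins sampler), add-one estimator
`p = (1 + #{sim ≥ obs})/(n_sim + 1)`, which cannot return 0. Two numerical
choices deserve a note:

* Null tables are simulated under *sorted* margins. The null law of the
  statistic depends only on the margin multisets, so this changes nothing
  statistically while making the reported p-value exactly invariant to
  row/column permutations of the input table.
* Zero-margin rows/columns are uninformative and dropped before testing;
  a table reduced to a single row or column equals its own margins, so
  the statistic is 0 and p = 1.

Pearson residuals `(obs − exp)/√exp` localize the association; a cell is
significant when its residual passes ±2 (the headline rule), and display
bands mark |r| in [1.645, 1.960) with "•", [1.960, 2.241) with "*", and
≥ 2.241 with "**" (standard-normal quantiles for 90–95, 95–97.5 and
97.5–99% confidence; residuals past 2.576 are still shown "**" with a
note). The identity `Σ residual² = χ²` is asserted to 1e-9.

## Hub consensus on the PPI network

Edges are kept when their confidence score strictly exceeds 0.9 (the
highest-confidence STRING convention); isolated nodes are retained so
every input protein keeps defined centralities. Three *local* centralities
are computed:

* **Degree** — distinct neighbor count;
* **MNC** — node count of the largest connected component of the subgraph
  induced by the open neighborhood (the node itself excluded);
* **MCC** — over all maximal cliques C containing the node,
  `Σ (|C| − 1)!`, by exact Bron–Kerbosch enumeration with pivoting, with
  a guard (default 10⁶ maximal cliques) against pathological dense
  graphs. When a node's neighborhood induces no edges, MCC equals its
  degree — asserted on stars and random trees, and all three centralities
  are checked against exhaustive subset-enumeration oracles on 100 random
  graphs of ≤ 12 nodes.

Per method a node is selected when its **raw score** is ≥ 2, and the
consensus is the three-way intersection. The published tool this mirrors
ranks nodes in its UI, and whether the original analysis thresholded raw
scores or ranks is not determinable from its description; raw-score
semantics match the stated "score ≥ 2" wording and are the default, with
a top-k rank mode (`mode = "rank"`) exposed. For externally produced
ranked lists, `intersect_hub_sets()` performs the plain intersection.
Node identifiers are opaque strings; synonym reconciliation (e.g. the
rodent RPL23L vs. human MRPL23 naming of the same hub) is the caller's
responsibility.

## Gene–disease screening

Association records (gene, DOID, disease name, evidence channel among
knowledge/experimental/textmining, non-negative confidence score) pass
when the score strictly exceeds 2. A gene passing in *any* channel
counts toward the distinct-gene summary, with the per-channel breakdown
always reported; an optional literal DOID restriction is available (no
ontology traversal).

## The synthetic-data generator

The generator defines the study conditions every statistical guarantee is
tested under, mirroring the target experiment: 5000 proteins, 6+6
replicates, per-protein baselines `Normal(20, 2)` log units, within-group
replicate SD 0.5, 3% of proteins with a planted effect whose size is
drawn uniformly in |d| ∈ [2, 5] with random sign, 2% of those replaced by
extreme effects (|d| ∈ [8, 12]) to exercise the outlier stage, MCAR
missingness at 1.5% per cell, and ten exclusive proteins per group with
3–6 present values on the presenting side. Effects are planted in
Cohen's-d units (`shift = d · within_sd`) so recovery statements address
the ±2 calling threshold directly. Companion generators produce a
planted-hub network (each hub shared by three otherwise-disjoint
4-cliques, so its Degree/MNC/MCC provably dominate a sparse random
background), direction-enriched annotations (an odds factor multiplies
the designated category for one direction and divides it for the other,
so factor 1 is the exact independence null), and a disease table with a
chosen number of genes planted strictly above the score threshold.

What the generator does *not* emulate: intensity-dependent (MNAR)
missingness — real DIA missingness is partly abundance-driven, while the
analysed method specifies no mechanism, so MCAR is the default and the
planted-recovery results should be read as MCAR-conditional; correlated
proteins (complexes/pathways co-vary in real data, inflating effective
test dependence); heavy-tailed measurement error; and batch structure.
Passing recovery tests therefore demonstrate correctness of the
implementation under the stated model, not field performance on any real
tissue.

## Problem sizes and seeds

All randomness is seeded; every generator is bit-reproducible under its
seed, and the pipeline derives per-stage sub-seeds from one global seed by
fixed offsets. The validation suite uses: null calibration at 5000
proteins (t-test level 0.05 ± 0.01) and 500 null 4×2 tables with
`n_sim = 999` (type-I error 0.05 ± 0.02); DEP recovery at 2000 proteins ×
5 seeds with planted |d| ∈ [3, 5] (sensitivity ≥ 90%, false positives
≤ 1%); hub recovery over 50 network seeds; and exhaustive centrality
oracles on graphs of ≤ 12 nodes, where subset enumeration is exact. These
sizes were chosen so each property is measured with comfortable binomial
precision while the whole suite stays quick to run.

## Known limitations

* The per-sample mean imputation biases within-group variances downward
  when several cells of one protein are imputed; the imputation count per
  protein is reported precisely so such calls can be discounted.
* Raw-score hub thresholds (≥ 2) are scale-dependent: on dense networks
  nearly every node passes on MCC. The consensus intersection mitigates
  but does not remove this; the rank mode is preferable there.
* The Monte-Carlo p-value's add-one correction makes it conservative by
  construction, at most 1/(n_sim + 1) above the ideal estimate.
* With both group variances tiny but non-zero, Cohen's d explodes even
  for small mean differences; the joint p-and-d gate keeps most of these
  out, but the FC column should be consulted for biological relevance.
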