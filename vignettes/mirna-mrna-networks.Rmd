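---
title: "Methods: miRNA–mRNA anti-correlation networks of a treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mRNA anti-correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRmRNet)
```

## The model

The package analyzes a two-arm expression experiment — control vs
treated, two cell cultures, three biological and two technical replicates
per arm — on two molecular layers measured on the same samples: miRNAs
and mRNAs, both as log2 intensities. Its core assumption is the canonical
repression mechanism: a functional miRNA→mRNA interaction that
participates in the treatment response should produce a *negative*
Pearson correlation between the miRNA's and the target's expression
profiles across samples. Candidate interactions are therefore pairs of
significantly deregulated features whose correlation falls in
`[-1, -0.5]` (inclusive at −0.5), subsequently restricted to pairs with
experimental support ("strong" or NGS evidence) in a curated interaction
database. The assumption is directional but not causal: a passing edge is
a candidate, and the permutation FDR quantifies how many edges a
structure-free realignment of the two layers would produce.

## Stages and their contracts

**Differential expression.** Technical replicates are averaged before
testing; treating them as independent units would roughly double the
apparent sample size without adding biological information. The test is a
pooled-variance two-sample t on log2 data with empirical-Bayes
moderation: each feature's pooled variance \(s^2_g\) (residual df
\(d = n_T + n_C - 2\)) is shrunk toward the median feature variance
\(s^2_0\),

\[ \tilde s^2_g = \frac{d_0 s^2_0 + d\, s^2_g}{d_0 + d}, \qquad d_0 = 4, \]

and the statistic is referred to a t distribution with \(d_0 + d\)
degrees of freedom. This captures the stabilization that hierarchical
variance models provide for small-replicate arrays while keeping the
estimator in closed form; a full hierarchical fit (marginal-likelihood
estimation of \(d_0\) and \(s^2_0\)) is deliberately out of scope, and
the test suite cross-checks the ranking against an independent
empirical-Bayes implementation. Features with exactly zero moderated
variance (possible only in degenerate synthetic data) get \(p = 1\)
rather than an error so that null pipelines run end to end.
Multiple testing uses Benjamini–Hochberg step-up throughout, cutoff 0.05.

**Clustering.** Heatmap-style QC: agglomerative clustering of samples
with correlation distance (1 − Pearson) and average linkage — the most
common convention for expression heatmaps; both choices sit in the
configuration so alternatives are selectable. miRNA panels use the top 50
features by DE p-value, mRNA panels the top 50 by cross-sample variance
(two conventions in common use; both ranked deterministically, ties by
feature id). The 2-cluster cut is tested against condition labels with a
two-sided Fisher's exact test. All 12 technical-replicate samples enter
the clustering (the replicate structure is part of what the heatmap
displays); a constant sample profile makes correlation distance
undefined and raises an error naming the sample.

**Network.** Correlations use all 12 samples of a culture, both
conditions pooled: the treatment contrast is part of the signal that a
treatment-responsive interaction should show. Computing within one
condition only is a selectable alternative via the feature-set
arguments. Undefined correlations (zero-variance features) binarize to 0
and are reported per pair. The network-level FDR is
\(\mathbb{E}[\text{null edges}] / \text{observed edges}\), attached as a
quality annotation rather than used as an edge filter — the observed
edge set is already conditioned on DE significance and database
evidence, and a network-level rate cannot be attributed to individual
edges honestly.

**Permutation unit.** The null rearranges whole biological-replicate
blocks (the two technical replicates of a biological replicate move
together) of the mRNA matrix relative to the miRNA matrix. Individual
columns are *not* exchangeable under the nested noise model: technical
replicates share their biological-replicate noise, so freely permuting
columns destroys that shared structure in the null while it persists in
the observed data, understating the null edge count (in calibration runs
by a factor near 2.5). Block permutation preserves each layer's internal
replicate covariance and destroys exactly the cross-layer alignment being
tested. Free column permutation remains available (`blocks = NULL`) for
designs without nesting. The default permutation count is B = 1000,
seeded.

**Combination.** Two cultures' networks are combined by intersecting
their miRNA sets and taking the union of those miRNAs' edges, each edge
tagged with its culture of origin — the "shared regulators, all their
contexts" reading of a cross-culture comparison.

**Pathway over-representation.** One-sided hypergeometric upper tail per
pathway, BH-adjusted jointly across the whole multi-source collection
(per-source adjustment would trade power between databases on no
principled basis). The default universe is the union of all pathway
genes — the most consequential unstated parameter of any ORA; it is an
explicit argument so a microarray background can be supplied instead.

**qPCR quantification.** \(\Delta Ct = Ct_{target} - \overline{Ct}_{refs}\)
per sample (arithmetic mean of reference Cts, i.e. geometric-mean
normalization on the expression scale — the natural multi-reference rule
when none is stated), technical PCR replicates averaged within a sample,
\(\Delta\Delta Ct\) as the treated-minus-control difference of means, fold
change \(2^{-\Delta\Delta Ct}\), and a two-sided Student t-test on
per-sample \(\Delta Ct\). Validation pairs the miRNA and mRNA
per-replicate fold-change series by replicate index (a convention; the
pairing is configurable) and applies the Spearman rule \(\rho \le -0.5\).
At n = 3 the Spearman support is only \(\{\pm 1, \pm 0.5\}\), which is
why validation is a threshold count rather than a per-pair test.

## The synthetic-data generator

`simulate_experiment()` emulates the study conditions: two cultures ×
{control, treated} × 3 biological × 2 technical replicates; per-feature
baseline log2 intensities N(8, 1.5²); additive Gaussian noise with the
biological component (SD 0.25) shared by the two technical replicates of
a biological replicate and the technical component (SD 0.1) independent —
this nesting is what induces realistic technical-replicate correlation.
Planted differentially expressed features receive a ±2 log2 shift in the
treated arm. A planted repressive edge sets the target to a negative
affine transform of its miRNA, \(Y = a - bX + \varepsilon\) with
\(b = 1\) and \(\mathrm{sd}(\varepsilon)\) solved analytically from the
target population correlation (default −0.8) given the miRNA's marginal
variance (the balanced condition indicator contributes \(\delta^2/4\)).
The edge's miRNA carries a ±2 treatment shift, which propagates to the
target with inverted sign — so planted edges are discoverable through the
DE gate exactly as real responsive interactions would be. Defaults are
50 miRNAs × 500 mRNAs: desk-scale, but large enough for multiple-testing
behavior to be non-trivial.

What the generator does *not* emulate: array-specific artifacts
(background, spatial effects, spike-ins, probe–gene mapping), heavy-tailed
or intensity-dependent noise, correlated co-expression among null genes,
and database version drift. Passing tests therefore demonstrate the
statistical machinery under a clean nested-Gaussian world, not robustness
to platform artifacts; the normalization and preprocessing that real
arrays need are assumed done upstream.

The companion generators plant known structure for every downstream
stage: `simulate_interaction_db()` (all planted edges with admissible
evidence, plus decoys with a configurable evidence mix),
`simulate_pathway_collection()` (random sets from five tagged sources
plus one pathway concentrated on the planted targets), and
`simulate_qpcr()` (Ct tables whose expected \(\Delta\Delta Ct\) is
\(-\log_2 FC\), exact at zero noise).

## Numerical choices and degenerate inputs

- Thresholds: DE FDR 0.05; anti-correlation cutoff −0.5 *inclusive*;
  top-k 50. All live in `pipeline_config()` and are validated.
- Ties in feature ranking break lexicographically by id; all stochastic
  steps take explicit seeds; reruns with identical config + seed are
  byte-identical, manifest included (the manifest carries config hash,
  seed and per-artifact md5, and no timestamps).
- Zero observed edges make the network FDR undefined (`NA`), reported as
  not-applicable rather than 0 or Inf.
- A noiseless qPCR plate has zero \(\Delta Ct\) variance: the fold change
  is still exact and the t-test p is reported as `NA` (or 1 when the
  difference is also zero).

## Problem sizes

The test suite and the acceptance script run Monte-Carlo checks at
50–200 seeds with the generator at 20–50 miRNAs × 100–500 mRNAs and
B = 20–200 permutations; the full suite completes in about a minute.
These sizes were chosen as the smallest at which the binomial/Fisher-z
tolerances used in the checks are meaningful.

## Limitations

- The network is correlational; directions come from DE signs, not from
  perturbation evidence.
- The network-level FDR is a global rate, not an edge-wise posterior.
- The moderated test's plug-in prior (median variance, fixed \(d_0 = 4\))
  is slightly conservative when true variances are strongly heterogeneous.
- Small-n Spearman validation is intentionally coarse; it counts
  threshold crossings rather than estimating correlations.
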