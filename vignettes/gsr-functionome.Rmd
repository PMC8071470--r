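---
title: "Gene set regularity analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set regularity analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsreg)
```

## The model

gsreg quantifies the *regularity* of a biological function — a gene set —
in a single sample, relative to the ordering of gene expression that is
typical of normal tissue. The statistic is purely ordinal, a modification
of the differential rank conservation (DIRAC) idea:

1. For a gene set with $m$ measured genes, encode each sample as the
   $\binom{m}{2}$ binary comparisons $b_{ij} = \mathbf{1}[e_i < e_j]$ of its
   expression values. Any strictly increasing transformation of one
   sample's values leaves these bits unchanged, which is what makes
   multi-platform cohorts analyzable without normalization.
2. From the control samples alone, form the **rank template**: for every
   pair, the majority bit across controls — the most common expression
   ordering of the normal group.
3. The **GSR index** of a sample is the fraction of its pair bits matching
   the template. It lies in $[0, 1]$: 1 means the set's internal ordering
   is exactly the normal consensus, 0 means every pair is oppositely
   ordered, the maximally dysregulated state.

The **functionome** is the samples-by-sets matrix of GSR indices over a
whole gene set collection; it is the feature representation used by every
downstream stage: Mann–Whitney tests with Benjamini–Hochberg false
discovery control to call dysregulated sets, ontology clustering with the
cluster weight index (CWI) to summarize them, a support vector machine to
classify samples from their functionome patterns, ascending-p ranking for
canonical pathway collections, and repetition counting over category gene
sets to nominate representative genes.

## Numerical and procedural choices

Several details of the procedure are not fixed by the statistic itself;
gsreg resolves each one deterministically and documents the choice here.

* **Expression ties.** Exact ties $e_i = e_j$ within a sample are broken by
  ascending gene-symbol order, compared byte-wise (C locale), so results do
  not depend on the session locale. Determinism was preferred over random
  tie-breaking for testability; on continuous intensity data ties are rare.
* **Template ties.** A pair on which exactly half the controls vote 1 gets
  template bit 1. Flipping this convention relabels matched and unmatched
  pairs symmetrically; fixing it makes runs reproducible.
* **Control scoring.** Controls are scored against the template all of them
  voted on (self-inclusive), so heterogeneous control groups score below 1
  — matching how control means behave in practice. A `leave_one_out` flag
  scores each control against the template of the others instead; with the
  package's default simulation settings the self-inclusive choice keeps the
  per-set type-I error of the case-control test within the nominal band
  (see the calibration test), so it remains the default.
* **Set retention.** A set needs at least two measured genes to have any
  pairs; sets below that are skipped and logged, never silently dropped.
  Real collections shrink noticeably under this rule depending on platform
  coverage, which is why every run reports both the raw and the retained
  set counts.
* **Mann–Whitney branch.** The exact null distribution is used when both
  groups have at most 8 observations and no ties; otherwise the normal
  approximation with continuity and tie correction. Fully tied data yields
  p = 1. The exact branch is verified against full enumeration of all
  group assignments in the test suite.
* **Cluster rule.** How significant ontology terms are grouped "in the GO
  tree" admits several readings. gsreg assigns every significant term to
  the cluster headed by its *highest significant ancestor* — the
  significant ancestor farthest from it along `is_a` edges that has no
  significant ancestor of its own; a significant term with no significant
  ancestor heads its own cluster, and ids absent from the ontology are
  singletons. This is the simplest deterministic partition consistent with
  the CWI definition, and it produces high-level heads of the kind seen in
  published cluster tables. It is an interpretation, not the only possible
  one; the weight function is likewise configurable (default
  $-\log_{10} p$, alternatively $1 - p$).
* **Common-term ordering.** The cross-group common list intersects each
  group's top-$k$ cluster heads ($k = 50$ by default) and orders terms by
  the ascending mean of their within-group ranks. The number of common
  terms is an outcome, not a parameter.
* **Classification.** `kernlab::ksvm` with a radial basis kernel, the
  default bandwidth heuristic and unit cost; folds are stratified by class
  because case series are often much smaller than control pools (down to
  13 vs 136 in the simulated conditions), and unstratified folds would
  sometimes contain no case at all. Per repeat, out-of-fold predictions
  are pooled into one confusion matrix; the AUC is computed per repeat from
  pooled decision values (sign-oriented from the fold's own predictions)
  and averaged across repeats. Whether AUC should be averaged per repeat
  or pooled over all repeats is underdetermined; per-repeat averaging is
  implemented and reported. GSR features enter unscaled — they already
  live in $[0, 1]$.
* **Degenerate classifiers.** If the SVM cannot be fitted (for instance on
  constant features), the fold predicts the training majority class with an
  uninformative decision score; accuracy then equals the majority-class
  proportion, which the tests assert.

## What the synthetic generator emulates

`synthetic_config()` + `generate_cohort()` produce cohorts with exactly the
structure the analysis assumes:

* controls are latent standard-normal gene scores plus per-sample Gaussian
  jitter (`noise_sd`, default 0.3);
* cases share the latent scores except that for each *planted* set
  (`planted_fraction`, default 0.25 of the collection) the scores of the
  set's genes are permuted to invert an exact fraction
  (`scramble_strength`, default 0.8) of the set's gene pairs — at strength
  1 the permutation is the full reversal, forcing a GSR of 0 in the
  noiseless case. Because the statistic is ordinal, dysregulation *must*
  move rank orderings; mean shifts that preserve order are invisible;
* each sample's intensities then pass through a random strictly increasing
  transform (`monotone_scales`), emulating platform heterogeneity in a way
  the downstream analysis is provably blind to;
* genes shared between planted and unplanted sets leak signal into the
  latter, as overlapping ontology annotations do in real data — recall is
  therefore evaluated on the planted sets, not precision on the rest;
* noise is applied *after* planting, so realized order inversion is
  attenuated at high noise; the exact planted inversion fraction per set is
  recorded in the truth object.

The default cohort shape (30 vs 30 samples, 1000 genes, 200 sets of 10) is
the size at which the package's calibration and recovery properties were
established: under the null (nothing planted) the per-set Mann–Whitney
type-I error at raw $p < 0.05$ stays within $[0.03, 0.07]$ pooled over 20
seeds, and under the default planting the recall of planted sets at BH
$q < 0.05$ exceeds 0.9. The classification checks use unbalanced cohorts
(13–92 cases against 136 controls, strength 0.9–1.0, noise 0.10–0.15) to
mirror strongly separated disease groups; repeated five-fold
cross-validation then reaches mean accuracy 1.0 on the smallest, most
strongly scrambled group.

What passing these tests does **not** show: the generator makes no attempt
at realistic microarray intensity distributions, probe effects, batch
structure, correlated gene-gene noise, or tissue-composition heterogeneity.
Results on synthetic cohorts certify the implementation and its statistical
calibration, not biological conclusions on any particular real cohort.

## Degenerate inputs and edge behaviour

* One control sample: the template is that sample's ordering and the
  control's own GSR is exactly 1.
* A constant functionome column (all samples identical) gives a fully tied
  test and p = 1.
* An empty significant list produces an empty cluster table; an empty
  common-term intersection is an empty table, not an error.
* Cyclic `is_a` relations, missing labels, non-numeric cells and empty
  gene intersections all fail fast with located error messages; pipeline
  stage failures name the stage and remove partial outputs.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: cohorts up to 228 samples by 1000 genes with collections of 200
sets of 10 genes, 20-seed calibration sweeps, 1000-instance oracle
comparisons, and repeated five-fold cross-validation with 10 repeats.
These sizes were chosen as the smallest at which the statistical
properties of interest are stable; the implementation itself is vectorized
per set and handles ontology-scale collections (10,000+ sets) in
proportional time.

## Known limitations

* Gene symbols are matched exactly and case-sensitively; alias resolution
  is out of scope, so collections and matrices must share a symbol
  convention.
* Only `is_a` edges are used from OBO input; `part_of` and regulatory
  relations are ignored for clustering.
* The cluster rule, cluster weight and combined ordering are documented
  interpretations (see above), configurable where alternatives are
  equally defensible.
* No batch correction or normalization is offered by design; if a
  platform transforms intensities non-monotonically, the GSR's invariance
  argument does not apply.
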