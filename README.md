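# gsreg

Rank-based **gene set regularity (GSR)** analysis of transcriptome
cohorts, for researchers who want to compare the *functional ordering* of
gene expression between disease and normal samples across heterogeneous
platforms — for example borderline ovarian tumour series pooled from many
microarray studies — without any cross-platform normalization.

## The statistic

For a gene set with $m$ measured genes, every sample is encoded by its
$\binom{m}{2}$ pairwise expression comparisons
$b_{ij} = \mathbf{1}[e_i < e_j]$ (a modification of the differential rank
conservation, DIRAC, framework). The control samples' majority bit per
pair forms the **rank template** — the most common expression ordering of
the normal group — and the **GSR index** of a sample is the fraction of
its pair bits that match the template:

$$\mathrm{GSR} \in [0, 1], \qquad 1 = \text{ordering identical to normal}, \quad 0 = \text{every pair oppositely ordered}.$$

Because the encoding is ordinal within each sample, the index is invariant
to any strictly increasing per-sample transform, so platform scale
differences vanish by construction. The samples-by-sets matrix of GSR
indices — the **functionome** — then feeds:

* **Dysregulation calling** — Mann–Whitney U per set, Benjamini–Hochberg
  FDR, significance at q < 0.05;
* **Ontology clustering** — significant GO terms grouped under their
  highest significant `is_a` ancestor, clusters ranked by the **cluster
  weight index** (CWI, the cluster's summed $-\log_{10} p$ weight divided
  by the total over clusters; CWIs sum to 1), and cross-group common
  top-term tables;
* **Classification** — SVM (RBF kernel) on functionome patterns under
  stratified five-fold cross-validation repeated ten times, reporting
  sensitivity/specificity/accuracy means, SDs and AUC;
* **Pathway ranking** — the same set-level test on a canonical-pathway
  collection, ordered by ascending p;
* **Representative genes** — genome-wide DEGs intersected with a
  category's gene set annotations and ranked by repetition count;
* **IHC quantification** — the immunostaining score Q = I × P (intensity
  0–3 × percent positive cells, maximum 300) used when validating
  nominated genes in tissue.

A seeded synthetic-cohort generator with *planted* order dysregulation
(latent gene scores permuted to invert an exact fraction of a set's gene
pairs in cases) makes every stage testable end to end with known ground
truth.

## Worked example

Simulate the package's default study conditions (30 cases vs 30 controls,
200 gene sets of 10 genes, a quarter of the sets planted at strength 0.8,
noise SD 0.3), build the functionome, call dysregulated sets and classify:

```r
library(gsreg)

cfg <- synthetic_config(n_case = 30, n_control = 30, n_sets = 200,
                        planted_fraction = 0.25, scramble_strength = 0.8,
                        noise_sd = 0.3, seed = 7)
collection <- generate_collection(cfg)
cohort <- generate_cohort(cfg, collection)

f <- build_functionome(cohort$matrix, collection)
f
#> <functionome> 60 samples x 200 gene sets (GSR in [0.111, 1.000]); 0 sets skipped
corrected_group_mean(f)
#> # A tibble: 2 × 5
#>   group    mean     sd n_samples n_sets
#>   <chr>   <dbl>  <dbl>     <int>  <int>
#> 1 case    0.601 0.190         30    200
#> 2 control 0.909 0.0527        30    200

tests <- call_dysregulated(f, alpha = 0.05)
sum(tests$significant)
#> [1] 193
mean(cohort$truth$planted_set_ids %in% tests$set_id[tests$significant])
#> [1] 1

cv <- cv_classify(f, n_folds = 5, n_repeats = 10, seed = 1)
glance(cv)
#> # A tibble: 1 × 9
#>   sensitivity_mean sensitivity_sd specificity_mean specificity_sd accuracy_mean
#>              <dbl>          <dbl>            <dbl>          <dbl>         <dbl>
#> 1                1              0                1              0             1
```

Reading the numbers: the case group's mean GSR (0.601) sits well below the
control mean (0.909) — cases have lost the normal within-set ordering.
All 50 planted sets are recovered at FDR 0.05 (recall 1); the 143 further
significant sets are leakage through genes shared with planted sets, which
the generator produces deliberately to mirror overlapping ontology
annotations. With dysregulation this strong, repeated cross-validated SVM
classification is perfect (accuracy and AUC 1.0). `autoplot(f)` draws the
case/control GSR histograms; `summarize_histogram()`, `build_clusters()`,
`rank_clusters()`, `common_top_terms()`, `pathway_rank()` and
`rank_repetition()` cover the remaining stages, and `run_pipeline()`
orchestrates everything into TSV reports plus a JSON manifest
(`inst/scripts/gsreg-cli.R` wraps it for the shell).

Curated reference tables for the borderline ovarian tumour application —
the 41 recurrently deregulated GO terms with functional category
assignments (3 immune/inflammatory, 9 membrane/transporter, 16 cell
cycle/signaling, 9 metabolism, 4 others) and the 19 representative genes —
ship as `bot_common_go_terms()` and `bot_category_genes()`.

## Documentation

The methods vignette (`vignettes/gsr-functionome.Rmd`) describes the
model, its assumptions, the deterministic tie-break and clustering
conventions, what the synthetic generator does and does not emulate, and
the package's known limitations.
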