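---
title: "Methods: evolutionarily informed transcriptome-to-trait prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionarily informed transcriptome-to-trait prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Predicting a quantitative phenotype (the motivating case is nitrogen use
efficiency, NUE, in plants) from genome-wide expression runs into a
dimensionality problem: thousands of genes, a few dozen genotypes. evotrait
implements a three-step strategy for this setting:

1. **Feature selection by evolutionary conservation.** Genes that respond
   to the treatment (low vs high nitrogen) are called per species with a
   negative-binomial GLM, under a leave-one-genotype-out round-robin so the
   genotype later used for testing never influences feature choice. The
   per-fold gene lists are intersected within species, then linked across
   two species through a homolog map: a gene is kept only if some homolog
   responds in the other species as well. In the crop species the set is
   further intersected with genes whose response depends on genotype
   (G×N interaction), because genotype-dependent response is what a
   cross-genotype predictor must exploit.
2. **Gradient-boosted prediction with honest evaluation.** For each
   genotype, an XGBoost regression is trained on all other genotypes'
   `log2(CPM+1)` profiles of the selected features and evaluated on the
   held-out genotype, repeated over many seeded iterations; performance is
   the Pearson correlation between predicted and observed trait values.
   The same protocol is run on control feature sets (equally many
   top-ranked DEGs, equally many random expressed genes) and compared with
   one-tailed Mann–Whitney tests on the per-genotype correlations.
3. **Candidate ranking.** Per-gene gain importance is summed across all
   genotype models; separately, a random-forest network is inferred from
   treatment-responsive transcription factors to the selected features,
   pruned to its top edges, and regulators are ranked by connectivity.
   TFs high in either list are reported as candidates.

# Differential expression model

Counts are filtered (`CPM > 1` in at least 10 samples by default),
normalized by per-sample upper-quartile offsets, and modelled per gene as
negative binomial with log link:

`log mu = offset + genotype + condition` (main-effect contrast), or
`... + genotype:condition` (interaction contrast).

The contrast is a likelihood-ratio test between nested fits sharing the
same per-gene dispersion, referred to a chi-square distribution, with
Benjamini–Hochberg control (`FDR < 0.05` by default).

Choices that needed pinning:

- **Upper-quartile offsets.** The normalization quantile is the 75th
  percentile (linear-interpolation definition, so it is bit-reproducible)
  of a sample's *nonzero* counts. The relative factors `UQ/library size`
  are scaled to unit geometric mean; the offset is
  `log(library size × factor)`. Consequences used as tests: doubling one
  sample's counts shifts its offset by exactly `log 2`, and the mean
  offset equals the mean log library size.
- **Dispersion.** Per gene, a moment estimator: the dispersion at which
  the Pearson statistic under NB variance `mu + phi mu^2` (with `mu` from
  a Poisson pre-fit) equals the residual degrees of freedom. The
  residual-df correction matters: without it dispersions are biased low
  and the LRT is anti-conservative. Gene-level estimates are then shrunk
  toward a lowess mean–dispersion trend with trend weight
  `20 / (20 + residual df)`, borrowing strength at small sample sizes
  while letting large designs speak for themselves. Genes at dispersion 0
  are fitted as Poisson. This scheme is deliberately simpler than the
  Cox–Reid machinery of dedicated DE packages — it is fully specified,
  testable against brute force in the Poisson limit, and calibrated
  (uniform null p-values by KS test) at the sample sizes this pipeline
  targets.
- **Ties.** DEG tables sort by FDR, then p-value, then gene ID, so output
  order is deterministic.
- **Unwanted variation.** Replicate-based factor removal is not built in;
  `fit_nb_glm(nuisance = )` accepts user-supplied covariates appended to
  the design, which covers the same need when the nuisance structure is
  known.

# Feature selection

- The consensus DEG list is the exact intersection of all per-fold lists
  (the *unified list*). A per-fold alternative exists in the literature;
  the unified list is used because it yields one feature ranking across
  genotypes rather than one per fold.
- **Homolog strictness.** With many-to-many homology, a gene counts as
  conserved if *any* homolog responds in the other species
  (`strictness = "any"`, configurable to `"all"`). The "any" rule matches
  the asymmetry seen in real homolog maps, where one model-species gene
  often maps to several crop-species genes.
- The G×N set is computed once on all samples (not per fold): it is a
  species-level property of the design, and the interaction LRT needs all
  genotypes for power.
- **Control sets.** Random control features are drawn (seeded, without
  replacement) from the genes surviving the expression filter on the full
  data; the top-DEG control takes the k smallest-FDR genes from the
  full-data DEG table. One random draw per run is the default: keeping a
  feature set immutable within a run keeps the benchmark comparison
  well-defined; `n_random_draws` raises the number of draws when a
  distribution over draws is wanted.

# Prediction protocol

- **Tuning.** Five-fold internal CV over a small grid
  (`nrounds ∈ {50,100,200}`, `eta ∈ {0.05,0.1,0.3}`,
  `subsample ∈ {0.7,1}`, `colsample_bytree ∈ {0.5,1}`,
  `max_depth ∈ {2,3}`), minimizing mean squared error. Internal CV folds
  split whole genotypes, not samples: with replicated genotypes,
  sample-level folds let memorization of genotype identity win the CV,
  selecting hyperparameters that transfer poorly to unseen genotypes —
  the very thing the outer protocol measures. Tuning runs once per fold
  on that fold's training genotypes and is reused across iterations. The alternative — one hyperparameter set per species — is
  available (`tune = "once"`) but not the default, because tuning on data
  containing a fold's test genotype would leak it into that fold's model
  and break the leave-one-genotype-out guarantee that this package treats
  as non-negotiable (it is asserted by mutation tests: perturbing a
  held-out genotype's counts and phenotypes changes neither its fold's
  DEG list nor its fold's fitted model).
- **What varies across iterations.** Per-iteration seeds drive the
  boosting row/column subsampling; everything else is fixed. Iteration
  variability therefore reflects model-fitting stochasticity, not data
  resampling.
- **Expression transform.** Models see `log2(CPM+1)`. CPM is a per-sample
  quantity, so no training statistics leak into test samples.
- **Importance.** Gain (total loss reduction) rather than split count:
  it is the conventional importance for boosted trees and stable under
  feature rescaling. Per fold, gains are averaged over iterations; the
  aggregated table sums fold means and counts the folds giving a gene
  positive importance. Ranking is done within a stated gene universe
  (genes never used rank last at importance 0), so "top 10%" statements
  are anchored to the expressed-gene universe, not to the feature set.
- **Evaluation modes.** `per_genotype` (Pearson r per genotype and
  iteration, then mean ± SD; needs ≥ 3 test points per fold) and `pooled`
  (one r per genotype over all pooled iteration predictions) mirror the
  two reporting situations: many replicates per genotype vs very few.
- **Benchmark test.** One-tailed Mann–Whitney on per-genotype mean r;
  exact enumeration when both groups have ≤ 10 values without ties,
  normal approximation with tie correction otherwise.
- Binary outcomes (e.g. symptomatic vs asymptomatic) use the same trainer
  with `objective = "binary:logistic"`; evaluation stays correlation-based
  for comparability.

# Regulatory network

Per target, a 1000-tree random forest regresses the target's standardized
expression on all regulators (minus itself); `mtry = sqrt(#regulators)`.
Importances (impurity / variance reduction, the original algorithm's
choice) are clamped at zero and normalized to sum to one per target.
"Top 1% of edges" means 1% of all candidate regulator×target pairs
excluding self-pairs, with cutoff ties broken lexicographically.
Per-gene standardization before inference equalizes scale across genes;
without it, high-variance genes dominate importances for reasons that have
nothing to do with regulation.

# Phenotype-panel statistics

Coefficient of variation exposes its aggregation level explicitly
(per-plant values vs genotype means) because the two answer different
questions and published CVs rarely say which was used. The two-way ANOVA
partition uses sequential (type-I) sums of squares in the order genotype,
condition, interaction — exactly defined, additive, and order-invariant
for balanced designs; unbalanced data trigger a warning that the
partition is order-dependent.

# The synthetic testbed

`generate_dataset()` plants known structure so every stage has a ground
truth:

- Negative-binomial counts (`variance = mu + phi mu^2`, default
  `phi = 0.1`), log-normal baselines, log-normal library sizes
  (default spread 0.25 on the log scale), and per-(genotype, gene-block)
  log-normal multipliers (SD 0.2) that create genotype clustering.
- 100 responsive genes per species with signed log2 effects centred on 2;
  half are conserved: their homologs in the second species carry the same
  effect (± 10% scaling). G×N genes are responsive genes whose log2
  effect is scaled per (gene, genotype) by a uniform multiplier in
  [0.25, 1.75]: each gene keeps a main effect while the panel mixes
  strong, weak and near-silent responders, which is how
  genotype-dependent treatment response manifests in real panels and
  what makes a cross-genotype predictor non-trivial. The second species'
  G×N set includes the homologs of the conserved G×N genes, so the
  conserved-and-interacting feature funnel has a cross-species truth.
- 10 causal genes — conserved, genotype-modulated responders — define the
  trait: a weighted sum of their standardized `log2(CPM+1)` passed
  through a scaled `tanh` (`2 tanh(score/2)`: genuinely non-linear
  without flattening entire genotypes), plus Gaussian noise. The noise SD
  is set from the within-(genotype × condition) signal SD divided by
  `sqrt(SNR)` (default SNR 3): measurement error on a weighed or assayed
  trait does not grow with panel diversity, and the within-cell signal is
  the repeatable per-plant variation a matched transcriptome/phenotype
  design exploits. Under the default configuration the resulting trait
  partitions into sizeable genotype and genotype-by-treatment components,
  a significant treatment main effect, and a modest residual — the
  variance structure reported for diverse panels of this kind. Traits are
  emitted per sample, matching transcriptome and phenotype on the same
  individuals.
- Hub TFs (out-degrees 20/10/10 by default) are responsive genes whose
  realized expression multiplies their targets' expected counts, giving
  the network stage true edges to find.
- The default design — 2 species × 16 genotypes × 2 conditions × 3
  replicates, 2000 genes — is the reference configuration all end-to-end
  validation runs on; its scale keeps a full benchmark (20 iterations,
  three feature sets) within minutes on a laptop core.

What the generator does *not* emulate: correlated gene-gene noise beyond
the planted block/TF structure, composition effects from a few extremely
abundant transcripts, batch effects, or mapping ambiguity in the homolog
table. Passing the end-to-end tests therefore demonstrates internal
correctness of the pipeline under its stated model, not robustness to
every artefact of real RNA-seq.

# Degenerate inputs and numerical conventions

- All-zero samples, samples missing from metadata, duplicate IDs,
  negative or fractional counts: typed errors, never silent coercion.
- Genotypes observed in only one condition make the interaction design
  rank-deficient; the error names the confounded genotype.
- Empty intersections (fold consensus, conserved set, interaction filter)
  warn and return empty sets rather than erroring: downstream stages
  decide whether an empty feature set is fatal.
- Constant features are legal in the boosted models (importance 0);
  constant targets give zero importance everywhere in the network stage.
- Missing phenotypes are flagged on read and excluded per trait at
  analysis time, with a log message stating how many samples were
  dropped.

# Limitations

- The DE numerics intentionally do not replicate any specific published
  implementation; when exact concordance with a particular tool matters,
  export the count matrices and run that tool — the feature-selection
  interfaces accept any DEG table with `gene`, `pvalue`, `fdr` columns.
- Connectivity ranks regulators by out-degree only; edge sign and
  directionality beyond the regulator→target convention are out of scope.
- With very few genotypes (< ~5) the leave-one-genotype-out benchmark has
  little power and the Mann–Whitney comparison is close to meaningless;
  the package runs but the caller should interpret accordingly.
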