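---
title: "Stratified genotype imputation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified genotype imputation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratimpute)
```

## The problem

Resequencing panels of livestock and other managed populations routinely
carry 5–20% missing genotype calls, and — unlike most human cohorts — they
are often strongly stratified: a panel may mix several breeds whose allele
frequencies have diverged substantially. Haplotype-copying imputation
models every target chromosome as a mosaic of reference haplotypes, and its
accuracy depends on how much haplotype sharing exists between target and
reference. In a stratified panel, most of the reference haplotypes belong
to the *wrong* subpopulation: they dilute the state space and shorten the
shared segments the model can exploit.

`stratimpute` implements the obvious but effective remedy as a complete,
tested pipeline: partition the individuals into genetic subgroups first,
impute each subgroup against its own reference panel, and merge the results
back in the original input order. Each subgroup shares longer haplotype
segments than the pooled panel, so each per-cluster HMM works with fewer,
longer haplotypes — which helps accuracy under structure and reduces
computation (the per-window distinct-haplotype accounting is available via
`haplotype_count_report()`).

## The imputation model

The engine is a diploid Li–Stephens-style haplotype-copying hidden Markov
model. The state space at each marker is the set of ordered pairs of
reference-panel haplotypes. Three ingredients define the chain:

* **Initial distribution** — uniform over all ordered pairs.
* **Transition** — each of the two copied haplotypes independently switches
  with probability `switch_prob` per adjacent marker interval to a
  uniformly chosen haplotype (possibly itself). No genetic map is used:
  the panels handled here live on a single pseudo-chromosome, so a flat
  per-interval rate is the honest choice. Default `switch_prob = 0.01`.
* **Emission** — each copied allele is observed through a symmetric flip
  channel with probability `mismatch_prob` (mutation and genotyping error
  folded together; default `0.005`); the genotype emission sums over the
  two consistent allele assignments for heterozygotes. Missing markers
  emit probability one.

Because the switch kernel factorises over the two haplotypes and the
genotype emission is a rank-≤2 outer product, a forward–backward sweep
costs `O(H² M)` rather than `O(H⁴ M)`; it is implemented in C++ with
normalisation at every step and log-scale likelihood accounting. Genotype
posteriors at missing cells are obtained by collapsing the pair-state
posterior through the emission channel; the imputed call is the posterior
argmax with ties broken toward the heterozygote, then the major
homozygote. Posterior triples always sum to one (asserted in tests to
1e-9), and the forward–backward recursion is verified against exhaustive
path enumeration on every panel with ≤ 3 haplotypes and ≤ 4 markers to
1e-10.

Reference panels are built in-package by iterative conditional phasing:
heterozygote phases start random, then window-chained sweeps re-phase each
individual against all other haplotypes, keeping or switching each
50-marker window's suffix according to which configuration best matches a
reference haplotype across the window and its left context. Missing sites
contribute nothing to the score and are filled afterwards by local copying
from the best-matching reference. Each individual is always imputed
against a panel *excluding* its own two haplotypes (leave-one-out), and
panels are capped at `max_haplotypes = 200` rows (random subsample) to
bound the quadratic state space — the stratification itself is what keeps
per-cluster panels small.

## Clustering

Subgroups are found by K-means on the raw 0/1/2 genotype coordinates
(no standardisation — all markers live on the same scale), with missing
calls replaced by the heterozygote placeholder `1` for the clustering step
only. For each candidate `k` in 2..10, K-means runs with 25 random
restarts; the `k` maximising the mean silhouette coefficient wins, with
ties broken toward smaller `k` (larger clusters mean richer reference
panels). Clusters smaller than 3 individuals are merged into their
nearest-centroid neighbour, since a copying model needs at least two other
individuals to copy from. For large panels the silhouette (quadratic in
individuals) is evaluated on a capped random subsample (2,000 individuals
× 5,000 markers by default).

Note the selection range starts at `k = 2`: on genuinely homogeneous data
the pipeline still splits the panel, and the per-cluster panels are then
smaller than the pooled one. Worse, the raw mean silhouette tends to
*increase* slowly with `k` on unstructured data, so the argmax often lands
near the top of the search range and fragments a homogeneous panel into
many small clusters. At desk-scale panel sizes this costs real accuracy
relative to whole-panel mode (the acceptance suite measures the effect
rather than hiding it); under genuine structure the stratified mode wins.
Users with panels they believe homogeneous should prefer `mode = "whole"`.

## The synthetic population generator

`sim_population()` emulates the salient structure of a multi-breed
resequencing panel without any real data:

* Ancestral allele frequencies ~ Uniform(0.05, 0.95) — the 0.05 floor
  keeps major/minor coding stable.
* Subpopulation frequencies follow a Balding–Nichols Beta model whose
  `divergence` parameter plays the role of F_ST (verified against a
  Weir–Cockerham estimate in tests). `divergence = 0.3` is the default
  "strongly structured" regime; `0` gives a homogeneous panel.
* Each subpopulation has a pool of `pool_size = 8` founder haplotypes;
  individuals receive two mosaic haplotypes copied from the founders with
  switch probability `recomb_rate = 0.01` per interval. Few founders and
  rare switches produce the long shared haplotype blocks that
  haplotype-copying imputation exploits; these two defaults intentionally
  mirror a closed breeding population rather than a large outbred one.
* Genotypes are exactly the sums of the two haplotypes, and columns are
  oriented so 0 is always the major homozygote.

What the generator does **not** emulate: mutation, sex chromosomes,
pedigree structure, genotyping-error correlation, variable marker density
and ascertainment bias. Results on it demonstrate correctness of the
machinery and the direction of the structure effect, not absolute
accuracies on any real panel.

`mask_genotypes()` hides an exact `round(rate × cells)` uniform subset of
cells and records the truth; a re-draw rule prevents any marker from
losing all its calls (an all-missing column carries no frequency
information — the generator refuses to create an unimputable instance).

## Evaluation harness

* `matching_rate()` is the strict identity fraction over masked cells —
  no partial credit for half-right heterozygotes.
* `simulate_phenotype()` draws QTNs uniformly, effects from a standard
  normal, and sets the residual variance from the *realized* additive
  variance, `V_E = V_A(1−h²)/h²`, so the target heritability refers to
  the sample actually generated. Defaults: 20 QTNs for the GWAS harness,
  10 for genomic prediction, `h² = 0.75`.
* `gwas_scan()` is a single-marker linear-model scan (closed-form t-test
  per marker). Multi-locus association models are deliberately out of
  scope: the harness isolates the effect of imputation on downstream
  detectability, and a simple scan keeps the power/FDR accounting exact
  and fast. `power_fdr_type1()` reports power as the detected QTN
  fraction (each of 20 QTNs contributes 5%), plus two false-positive
  summaries: `fdr` = FP / (non-QTN markers) — kept because it is the
  convention of the harness this reproduces — and the conventional
  FP / detections as `fdr_conventional`, never silently swapped.
  Detection defaults to Bonferroni 0.05/markers; QTNs must be hit at
  their exact index (no linkage-window credit — conservative and
  deterministic).
* `gblup_fit()` fits the one-random-effect GBLUP mixed model by REML:
  one eigendecomposition of the VanRaden method-1 GRM reduces the
  restricted likelihood to a 1-D profile over the variance ratio, which
  `optimize()` maximises on a log scale (bounds 10^±6, tolerance 1e-8;
  a 1e-8 diagonal jitter is applied if the GRM has a negative
  eigenvalue). Held-out individuals are predicted by BLUP from the
  training records. `cross_validate()` wraps 5-fold partitions (sizes
  within one of equal) and reports the Pearson correlation between pooled
  predictions and phenotypes, averaged over replicates.

## Numerical and design choices

* All randomness flows through explicit seeds; nested stages derive child
  seeds with a counter scheme (`child_seed()`), so per-cluster concurrent
  imputation is bit-identical to sequential execution, and adding
  replicates to a benchmark grid never perturbs earlier cells.
* Forcing one cluster makes the stratified pipeline bit-identical to
  whole-panel mode — a regression anchor asserted in the suite.
* Baseline control: `impute_baseline()` fills each missing cell with the
  marker's modal genotype. The HMM must beat it on haplotype-structured
  data; that margin is what the copying model buys.
* Markers entirely missing within a cluster (possible after splitting)
  are pre-filled from the whole-panel modal genotype before the cluster's
  HMM runs.
* HapMap adapter: with unknown alleles the surrogate coding
  0→"AA", 1→"AG", 2→"GG", missing→"NN" is used; the `alleles` metadata
  column written alongside makes the numeric→HapMap→numeric round-trip an
  exact identity, while foreign tables without it fall back to
  major-by-frequency with alphabetical tie-breaks. Half-missing diploid
  calls normalise to missing. VCF I/O is GT-only, biallelic, unphased.
* Wall time is recorded by the benchmark harness but never asserted in
  tests — it is hardware, not science.

## Problem sizes

The shipped test-suite and acceptance studies run at desk scale, chosen to
finish in minutes while leaving the qualitative contrasts clearly visible:
structure-benefit comparisons use three subpopulations of 20 individuals
at 1,200 markers (10 paired seeds per regime); heritability recovery uses
200 individuals × 3,000 markers × 30 replicates; cluster-count recovery
uses three subpopulations of 30 at 2,000 markers over 10 seeds. Larger
panels behave the same way, only slower; the `max_haplotypes` cap and the
silhouette subsample are the two scale guards.

## Known limitations

* The phasing heuristic is greedy and window-based; it is accurate on
  panels with strong haplotype sharing (the target regime) but will not
  match a full phasing engine on weakly structured data.
* The HMM treats markers as exchangeable in distance; panels with very
  heterogeneous marker spacing would need a map-aware switch rate.
* K-means with silhouette selection assumes roughly convex, comparable-
  scale clusters; admixed individuals sit on cluster boundaries and get
  hard labels (no fuzzy membership).
* The external-Beagle shell only adapts formats; it does not attempt to
  reproduce that tool's internal state-space pruning, and it is excluded
  from the test suite.
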