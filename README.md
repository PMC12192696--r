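# stratimpute

Stratified genotype imputation for structured populations, with a complete
benchmarking and downstream-evaluation harness.

## The problem

Resequencing panels in animal and plant genetics are rarely homogeneous:
a panel often mixes several breeds or lines whose allele frequencies have
diverged strongly. Haplotype-copying imputation reconstructs each missing
genotype by modelling the target chromosome as a mosaic of reference
haplotypes, so its accuracy hinges on haplotype sharing between target and
reference. In a stratified panel most reference haplotypes come from the
wrong subpopulation; they shorten the shared segments and dilute the state
space.

`stratimpute` implements the cluster-then-impute strategy end to end:

1. **Cluster** individuals into genetic subgroups by K-means on the 0/1/2
   genotype matrix (missing calls replaced by the heterozygote placeholder
   `1` for clustering only), choosing the cluster count `K` over `k = 2..10`
   by the mean silhouette coefficient with 25 restarts per `k`.
2. **Impute** each subgroup independently with a diploid Li–Stephens-style
   haplotype-copying HMM over ordered reference-haplotype pairs
   (leave-one-out panels, forward–backward posteriors in C++), jobs running
   concurrently with bit-identical results to sequential execution.
3. **Merge** the per-cluster results and restore the original taxa order.

Accuracy is scored by the imputation matching rate

    R_match = N_correct / N_total

over deliberately masked cells, and imputed datasets are validated
downstream by a QTN-simulation GWAS harness (power / FDR / Type-I error
with 20 QTNs at h² = 0.75; power quantum 5% per QTN) and by GBLUP genomic
prediction (REML heritability `h² = V_A / (V_A + V_E)` and 5-fold
cross-validated Pearson prediction accuracy with 10 QTNs).

A synthetic structured-population generator (Balding–Nichols divergence
between subpopulations, mosaic haplotypes from founder pools) makes every
stage testable without any external data.

## Worked example

```r
library(stratimpute)

# a structured panel: 3 subpopulations x 20 individuals, 1,200 markers
pop <- sim_population(n_subpops = 3, n_per_subpop = 20, n_markers = 1200,
                      divergence = 0.3, seed = 42)
mk  <- mask_genotypes(pop$genotypes, rate = 0.10, seed = 7)

res   <- cluster_impute(mk$masked, mode = "cluster", seed = 11)
whole <- cluster_impute(mk$masked, mode = "whole",   seed = 11)
base  <- impute_baseline(mk$masked)

res$K_used
#> [1] 3
matching_rate(res, mk$mask)
#> [1] 0.8501389
matching_rate(whole, mk$mask)
#> [1] 0.8386111
matching_rate(base, mk$mask)
#> [1] 0.6594444
```

The silhouette-guided clustering recovers the three simulated
subpopulations (`K_used = 3`). On this structured panel the stratified
pipeline imputes 85.0% of the masked genotypes exactly right, ahead of
whole-panel imputation (83.9%) and far ahead of the per-marker modal
baseline (65.9%) -- the strategy pays off exactly where population
structure exists.

Downstream validation on the imputed matrix:

```r
sim <- simulate_phenotype(pop$genotypes, n_qtn = 20, h2 = 0.75, seed = 1)
ev  <- power_fdr_type1(gwas_scan(res$completed, sim$phenotype), sim$qtn$indices)
c(power = ev$power, fdr = ev$fdr, type1 = ev$type1)
#>      power        fdr      type1 
#> 0.05000000 0.01864407 0.01833333 

cv <- cross_validate(res$completed, sim$phenotype, folds = 5,
                     replicates = 5, seed = 3)
round(c(h2_hat = cv$h2_hat, accuracy = cv$accuracy), 3)
#>   h2_hat accuracy 
#>    0.376    0.431
```

With only 60 individuals the Bonferroni scan detects 1 of the 20 QTNs
(each detection contributes 5% power -- the power quantum of the
accounting), and GBLUP recovers a positive but conservative heritability
estimate, as expected at this sample size.

A command-line wrapper is available at `exec/stratimpute`
(`simulate`, `mask`, `cluster`, `run`, `convert` between numeric/HapMap/VCF).

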