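# nephroclust

Chronic kidney disease (CKD) is not one disease: the hundreds of genetic
variants associated with reduced kidney function act through different
physiological routes — urate handling, inflammation, hematopoiesis, body
mass, lipid metabolism. nephroclust deconstructs this heterogeneity from
published GWAS summary records. It is written for statistical geneticists
who want to subtype a complex disease from variant–trait association
catalogs and validate the subtypes in a genotyped, phenotyped cohort.

The pipeline:

1. **Association matrix** — harvest GWAS records for the
   linkage-disequilibrium proxies (r² ≥ 0.6) of kidney-function lead
   variants; filter (no gender-specific studies, n ≥ 100, p < 1e-6, ≥ 5
   variants per trait, kidney-function traits excluded); standardize each
   effect to a z-score β = B/SE; orient every effect to the lead variant's
   kidney-function-decreasing allele; and arrange |β| as a non-negative
   matrix X with one "+" and one "−" feature row per trait.
2. **Soft clustering** — non-negative matrix factorization X ≈ W·H
   (W: trait features × K, H: K × variants) by Lee–Seung multiplicative
   updates with random restarts; the cluster count K is selected over
   K = 2..20 by the highest mean silhouette width, ties broken by the
   lower Frobenius error ‖X − WH‖_F. A Bayesian NMF whose automatic
   relevance determination prior shrinks superfluous components
   (`bnmf_ard()`) cross-checks K.
3. **Cluster polygenic scores** — cPGS_i,k = Σ_v H[k,v]·dosage_i,v,
   z-scored within each cluster; Anderson–Darling normality and
   Mann–Whitney group comparisons; top-decile risk membership.
4. **Cohort & PheWAS validation** — KING-robust kinship pruning
   (φ > 0.0884 removed), genotype PCA, random-forest ancestry assignment;
   then for every (cluster, trait) pair a linear (quantitative) or
   logistic (binary Phecode, case = ≥ 2 diagnosis codes) regression of the
   trait on the standardized cPGS adjusting for sex, age and ten PCs,
   Bonferroni-controlled at alpha = 0.05/(K·(n_quant + n_binary)).
5. **Enrichment** — per-cluster gene ranks (max variant weight per gene),
   preranked GSEA and hypergeometric overrepresentation against GMT gene
   sets.

Every input can be emulated by the bundled synthetic-data generator with
planted cluster structure, so the whole pipeline is testable end to end
without any external data.

## Worked example

Plant a 4-cluster truth, build the matrix, recover the clusters, and score
a simulated cohort:

```r
library(nephroclust)

truth   <- generate_truth(K = 4, n_traits = 60, n_variants = 120, seed = 7)
records <- generate_association_records(truth, noise_sd = 0.1, n_decoys = 10, seed = 7)

kept <- filter_associations(records)
kept$log
#> gender_specific           low_n  excluded_trait     p_threshold    few_variants
#>               2               2               2               2               2
#>            kept
#>            7200

aligned <- align_to_lead(standardize_effects(kept$records),
                         synthetic_proxy_table(truth),
                         synthetic_variant_table(truth))
X <- build_matrix(aligned)
X
#> Association matrix X: 60 trait features x 120 variants (min 15.3)

scan <- rank_scan(X, K_range = c(2, 8), n_restarts = 4, max_iter = 400,
                  conv_window = 40, seed = 1)
scan
#> Rank scan over K = 2..8; selected K = 4
#>  K frobenius_error mean_silhouette
#>  2     4626.642917       0.8091272
#>  3     3205.722411       0.8265893
#>  4        8.351411       0.9940395
#>  5        8.189015      -1.0000000
#>  ...

fit <- scan$fit
cluster_match_accuracy(apply(fit$H, 2, which.max), truth$variant_cluster)
#> [1] 1

geno <- generate_genotypes(2000, 120, seed = 8)
z    <- standardize_cpgs(compute_cpgs(geno$dosages, fit$H))
decile_membership(z)$fraction_ge1
#> [1] 0.328
```

Reading the output: the ten decoy records (two per filter rule) are removed
by exactly the rule they violate, leaving the 7,200 genuine associations.
The rank scan's silhouette peaks at the planted K = 4 — the Frobenius error
keeps shrinking for K > 4 but the extra components split true blocks, which
the silhouette penalizes (and empty-cluster fits score −1). Every variant
is assigned to its planted cluster, and 32.8% of the simulated cohort sits
in the top risk decile of at least one cluster (clusters built from the
same genotypes are positively dependent, so the fraction falls between the
comonotone bound 10% and the independence value 1 − 0.9⁴ ≈ 34%).

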