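---
title: "Deconstructing CKD heterogeneity: methods and design choices"
author: "nephroclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconstructing CKD heterogeneity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Chronic kidney disease (CKD) is genetically heterogeneous: hundreds of
independent variants are associated with reduced kidney function, but they
act through distinct physiological routes — urate handling, inflammation,
hematopoiesis, body mass, lipid metabolism. nephroclust implements a
soft-clustering pipeline that groups CKD-associated variants by the
*secondary* traits they are associated with, then validates the groups
genetically in a cohort. This vignette explains the model behind each stage,
the tunable parameters, and the design decisions taken where the methodology
was genuinely open.

## 1. The association matrix

The input is a set of GWAS-catalog style records linking proxy SNPs of
kidney-function lead variants to arbitrary traits. Effect sizes from
different GWAS are not comparable in native units, so every effect is
standardized to `beta_std = B / SE` — a z-score. Records pass through a
fixed filter cascade (`filter_associations()`):

1. gender-specific studies removed;
2. studies with fewer than 100 individuals removed;
3. traits matching kidney-function patterns removed (the clusters should be
   built from *secondary* traits, not from eGFR/CKD itself); the pattern
   list defaults to "glomerular filtration rate" and "chronic kidney
   disease" and is configurable, since any fixed list is only exemplary;
4. associations with p ≥ 1e-6 removed (the literal printed threshold;
   exposed as `p_threshold`);
5. traits supported by fewer than 5 distinct variants removed.

The fixed order makes the per-rule removal counts in the filter log
reproducible; filtering is idempotent.

**Signed effects in a non-negative factorization.** NMF requires X ≥ 0, but
standardized effects are signed. We resolve this with a directional trait
split: each trait contributes a "+" feature row carrying |β| of its positive
associations and a "−" row carrying |β| of its negative ones; all-zero rows
are dropped. This mirrors how paired opposite clusters (e.g. increased vs
reduced hematocrit) arise naturally in this kind of analysis, and keeps the
per-trait total |β| exactly preserved. Orientation is fixed before the
split: effects are flipped so that they refer to each lead variant's
kidney-function-decreasing allele (`align_to_lead()`), and when several
proxies of one lead hit the same trait, the record with the largest |β| is
kept (ties: smaller p, then lexicographic rsid).

## 2. NMF and rank selection

`nmf()` minimizes the Frobenius loss ‖X − WH‖²_F with Lee–Seung
multiplicative updates (denominators guarded at 1e-12), the standard choice
when no other objective is specified and the one matching the Frobenius
error used for rank selection. Defaults: 30 random restarts, up to 10,000
iterations, and early stopping once the relative error improvement stays
below 1e-6 for 80 consecutive iterations — an 80-iteration stability
window, the convergence-window semantics familiar from NMF toolkits. The
error is non-increasing within every restart (a property the tests assert),
and the best restart wins.

NMF is gauge-invariant: (W D, D⁻¹H) reconstructs identically for any
positive diagonal D. We fix the gauge by scaling each W column to unit
maximum and pushing the compensation into H, so trait weights are comparable
across clusters; the choice is recorded in the fit's `normalization` field.

`rank_scan()` tries K = 2..20 (clipped to the matrix size) and selects the
K with the highest mean silhouette width, ties broken by lower Frobenius
error, then smaller K. The silhouette construction is our choice, since
only the metric itself is standard: variants are hard-assigned to the
cluster of their largest H weight, and silhouettes are computed on
Euclidean distances between unit-normalized H columns. Degenerate
clusterings (an empty cluster) score −1 and can never be selected over a
valid rank.

## 3. Bayesian NMF with automatic relevance determination

As a cross-check on the cluster count, `bnmf_ard()` fits a
Gaussian-likelihood NMF with half-normal priors on each component's W
column and H row, sharing a per-component relevance scale λ_k with an
inverse-gamma hyperprior. MAP updates shrink the relevance of unneeded
components; a component whose scale falls below 1e-8 of the largest is
pruned, and the modal effective K over many restarts is the consensus.

Hyperparameters: shape a0 = 10 and scale
b0 = sqrt((a0−1)(a0−2)·mean(X)/K_max), which puts the prior mean relevance
on the data scale; both are exposed. The likelihood noise variance defaults
to var(X)/10 — in a strongly block-structured association matrix most total
variance is signal, and recovery of a planted K is insensitive to this
choice across at least a 25-fold range. One numerical choice matters: the
relevance prior is switched off for the first `warm_start = 100`
iterations. MAP ARD started from random factors is bistable — a strong
prior can annihilate every component before any structure has formed, and a
weak one never prunes; letting plain multiplicative updates find the block
structure first removes this pathology (a standard annealing device). The
negative log posterior is non-increasing from the end of the warm start
onwards.

## 4. Cohort preparation

`kinship_filter()` implements the KING-robust between-family estimator
φ = (N_Aa,Aa − 2 N_AA,aa) / (N_Aa(i) + N_Aa(j)) and removes one member of
every pair with φ > 0.0884 (the 2nd-degree bound). Resolution is greedy —
repeatedly drop the individual with the most flagged partners, ties by
lexicographic id — chosen over maximal-independent-set search for
determinism and speed. `dosage_pca()` excludes variants with MAF < 0.05,
mean-imputes missing dosages, scales genotypes by sqrt(2p(1−p)) and returns
the top ten principal coordinates (U·d, so duplicating individuals leaves
coordinates unchanged); each PC's sign is fixed by its largest loading.
`assign_groups()` is a pluggable probabilistic classifier (default: random
forest on reference-panel PCs); individuals with maximum class probability
≤ 0.5 are treated as mixed and excluded from group-specific analyses while
remaining in the pooled cohort. An optional within-group probability
quantile trim (`trim_quantiles`, e.g. 0.25–0.90) exists but is off by
default: trimming targets are analysis-specific and silently discarding
individuals is not a defensible default.

## 5. Cluster-specific polygenic scores

`compute_cpgs()` uses sum scoring, score_i,k = Σ_v H[k,v]·dosage_i,v, with
cohort-mean imputation for missing genotypes. Sum (rather than per-variant
average) keeps the score exactly linear and additive over variant
partitions; standardization removes the scale anyway.
`standardize_cpgs()` z-scores within each cluster using the sample SD
(denominator n−1) over the pooled cohort by default, so that group
distributions share one z axis; the standardization cohort is an argument.
Distribution shape is tested with the Anderson–Darling composite-normality
test and group differences with the Mann–Whitney test (exact enumeration
when n_a·n_b ≤ 400 without ties, otherwise the tie- and
continuity-corrected normal approximation). `decile_membership()` uses the
same linear-interpolation 90th-percentile rule as `top_decile()`, with ties
at the threshold included; under K independent clusters the fraction of
individuals in at least one top decile converges to 1 − 0.9^K.

## 6. PheWAS harness

Binary phenotypes are Phecodes: an individual is a case with ≥ 2 mapped
diagnosis-code events, excluded with exactly 1, a control otherwise. For
every (cluster, trait) pair `run_phewas()` fits
outcome ~ cPGS + sex + age + PC1..PC10; quantitative outcomes and the score
are z-scored on the analysis sample before the fit (refit-style
standardization), so the linear estimate is a standardized beta and the
logistic estimate an odds ratio per 1 SD of score, both with Wald 95%
intervals. Traits observed in fewer than 100 individuals are skipped;
binary traits additionally require ≥ 20 cases, a guard we add because a
logistic fit on a handful of cases is meaningless. Significance is
Bonferroni over the whole family, alpha = 0.05 / (K·(n_quant + n_binary))
(`compute_alpha()`; 9 clusters and 988 + 832 traits give 3.1e-06). A
cluster's top trait counts as validated when its matched PheWAS result is
Bonferroni-significant *and* the effect sign agrees with the trait's
direction in the cluster.

## 7. Enrichment

`gene_ranks()` collapses variant weights to genes by maximum (a gene
annotated to several variants takes the highest weight). `gsea_prerank()`
is the classic weighted Kolmogorov–Smirnov statistic with weight exponent 1
— the conventional choice — with a gene-label permutation null, NES
normalized by the mean |null ES| of the same sign, two-sided empirical
p-values with the +1 correction, and BH q-values.
`ora_hypergeometric()` tests the genes of each cluster's top 25% weighted
variants against the universe of all mapped genes — deliberately not a
genome-wide background, matching how the gene list is constructed. The
variant→gene map is an input, not a computation: "closest gene" rules
(distance definition, ties) vary across annotation pipelines, so the
assignment is left to the user's annotation of choice.

## 8. The synthetic-data generator

Because the real inputs (a GWAS-catalog snapshot and an access-restricted
biobank) cannot be bundled, every pipeline input is emulated with planted
ground truth:

* **Truth** (`generate_truth()`): block-structured factors. Each trait and
  variant has one dominant cluster with weights drawn U(11, 15); every
  cross-cluster loading is a uniform ε = 5% of the within-block mean,
  giving genuine soft overlap. The scale is chosen so that *every* implied
  association is a genome-wide-significant z-score (≥ ~6): association
  catalogs contain only reported significant hits, and this keeps the
  significance filter and the matrix construction mutually consistent.
  Sparsification zeroes entries (cross-loadings first, dominant entries
  protected) so the product keeps rank K.
* **Records** (`generate_association_records()`): β = sign·signal +
  N(0, noise_sd), an SE drawn U(0.02, 0.1), B = β·SE, p from the two-sided
  normal tail of β — self-consistent with β = B/SE, and indistinguishable
  from Student-t at GWAS sample sizes. Decoys each violate exactly one
  filter rule and are labelled with it, so tests can assert that filtering
  removes exactly the planted violations.
* **Genotypes** (`generate_genotypes()`): Hardy–Weinberg draws with
  group-specific allele frequencies; divergent MAF ranges stand in for
  continental ancestry structure.
* **Phenotypes** (`generate_phenotypes()`): quantitative traits are
  planted-score signals plus noise scaled so the score explains h2 of the
  variance (default h2 = 0.3, a typical complex-trait figure); binary
  traits come from a liability threshold at the stated prevalence (default
  0.1) and are emitted as ICD-style event lists, with cases carrying ≥ 2
  events and a small fraction of non-cases carrying exactly 1 to exercise
  the Phecode exclusion. The ICD→Phecode map is a bundled 1:1 toy map,
  since real maps are versioned external artifacts.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: linkage disequilibrium between variants
(every variant is its own proxy; the proxy table is exercised with
hand-built fixtures), realistic ICD ontologies, admixed ancestry,
ascertainment bias in trait reporting, and correlated phenotypes. The
planted block structure is also far cleaner than a real trait-variant
matrix; recovery there demonstrates correctness of the machinery, not
expected field performance.

## 9. Problem sizes and reproducibility

All generators and factorizations are pure functions of their integer
seeds. The packaged experiments use deliberately modest sizes — planted
K = 4 with a 60-feature × 120-variant matrix, rank scans over K = 2..8 with
4 restarts and 400 iterations, 50 ARD restarts at 3,000 iterations,
PheWAS calibration over 1,000 null traits at n = 2,000 — sizes at which
every stage's behaviour (selection of the planted K, ≥ 0.9 Hungarian-matched
variant assignment accuracy, nominal type-I error) is already stable across
seeds. Production settings (30 restarts, 10,000 iterations, K up to 20,
1,000 ARD runs) are the defaults of the exported functions.

## 10. Known limitations

* The bNMF consensus counts effective components per run; it does not match
  components across runs, so it cannot detect label-switching disagreement
  between equally sized solutions.
* The greedy kinship resolution can drop slightly more individuals than a
  maximal independent set would.
* `assign_groups()` probabilities are taken at face value from the
  classifier; random-forest vote shares are not formally calibrated.
* The PheWAS harness fits independent regressions; it does not model
  relatedness (no mixed models) or case-control imbalance corrections.
* GSEA permutes gene labels, which ignores inter-gene correlation of
  weights within a cluster.
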