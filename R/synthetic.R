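#' Generate a planted ground truth for the clustering pipeline
#'
#' Builds block-structured non-negative factors `W_true` (traits x K) and
#' `H_true` (K x variants). Each trait and each variant is assigned one
#' dominant cluster; within-block weights are drawn uniformly on a scale
#' chosen so that every implied trait-variant association is genome-wide
#' significant (standardized effects, i.e. GWAS z-scores, of at least ~6 —
#' mirroring that association catalogs only report significant hits), while
#' all cross-cluster loadings are a uniform epsilon equal to 5% of the
#' within-block mean, giving soft overlap between clusters.
#'
#' A `sparsity` fraction of entries in each factor is set exactly to zero.
#' Zeroing prefers cross-loadings and always protects, for every trait and
#' variant, the entry linking it to its dominant cluster, so the product
#' `W_true %*% H_true` keeps rank `K` with probability 1.
#'
#' The truth also carries planted phenotype effects used by
#' [generate_phenotypes()]: for each cluster, one quantitative and one
#' binary phenotype loads on that cluster's polygenic score, plus null
#' phenotypes with no genetic effect.
#'
#' @param K Number of planted clusters (>= 1).
#' @param n_traits,n_variants Dimensions; both must be >= `K`.
#' @param sparsity Fraction of factor entries set exactly to zero, in [0, 1).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_null_quant,n_null_binary Number of genetically null quantitative /
#'   binary phenotypes added next to the `K` planted ones of each type.
#' @return An object of class `ground_truth`: a list with `W_true`, `H_true`,
#'   `K_true`, `effect_sign` (per-trait +1/-1 direction versus kidney
#'   function), `trait_cluster`, `variant_cluster`, `pheno_effects`
#'   (K x phenotypes, with a `type` attribute marking quantitative/binary
#'   columns), and `seed`.
#' @export
generate_truth <- function(K, n_traits, n_variants, sparsity = 0, seed = 1L,
                           n_null_quant = K, n_null_binary = K) {
  check_number(K, "K", lower = 1)
  check_number(n_traits, "n_traits", lower = K)
  check_number(n_variants, "n_variants", lower = K)
  check_number(sparsity, "sparsity", lower = 0, upper = 1 - 1e-12)
  K <- as.integer(K); n_traits <- as.integer(n_traits)
  n_variants <- as.integer(n_variants)

  with_seed(seed, {
    trait_cluster <- rep_len(seq_len(K), n_traits)
    variant_cluster <- rep_len(seq_len(K), n_variants)

    make_factor <- function(n_rows, row_cluster, transpose = FALSE) {
      # rows = entities, cols = clusters; transposed on return for H
      in_block <- matrix(stats::runif(n_rows, 11, 15))
      m <- matrix(0, n_rows, K)
      m[cbind(seq_len(n_rows), row_cluster)] <- in_block
      eps <- 0.05 * mean(in_block)
      cross <- m == 0
      m[cross] <- eps
      # sparsify: protect the dominant entry of every row, zero cross first
      n_zero <- floor(sparsity * length(m))
      if (n_zero > 0) {
        cross_idx <- which(cross)
        prot <- cbind(seq_len(n_rows), row_cluster)
        prot_idx <- (prot[, 2] - 1L) * n_rows + prot[, 1]
        other_idx <- setdiff(which(!cross), prot_idx)
        pool <- c(sample(cross_idx), sample(other_idx))
        m[pool[seq_len(min(n_zero, length(pool)))]] <- 0
      }
      if (transpose) t(m) else m
    }

    W_true <- make_factor(n_traits, trait_cluster)
    H_true <- make_factor(n_variants, variant_cluster, transpose = TRUE)
    rownames(W_true) <- sprintf("trait_%03d", seq_len(n_traits))
    colnames(W_true) <- sprintf("cluster_%d", seq_len(K))
    rownames(H_true) <- colnames(W_true)
    colnames(H_true) <- sprintf("rs%04d", seq_len(n_variants))

    effect_sign <- sample(c(-1, 1), n_traits, replace = TRUE)
    names(effect_sign) <- rownames(W_true)

    pheno_names <- c(sprintf("quant_%d", seq_len(K)),
                     if (n_null_quant > 0) sprintf("qnull_%d", seq_len(n_null_quant)),
                     sprintf("bin_%d", seq_len(K)),
                     if (n_null_binary > 0) sprintf("bnull_%d", seq_len(n_null_binary)))
    pheno_type <- c(rep("quantitative", K + n_null_quant),
                    rep("binary", K + n_null_binary))
    pheno_effects <- matrix(0, K, length(pheno_names),
                            dimnames = list(rownames(H_true), pheno_names))
    pheno_effects[cbind(seq_len(K), seq_len(K))] <- 1
    pheno_effects[cbind(seq_len(K), K + n_null_quant + seq_len(K))] <- 1
    attr(pheno_effects, "type") <- stats::setNames(pheno_type, pheno_names)

    structure(list(W_true = W_true, H_true = H_true, K_true = K,
                   effect_sign = effect_sign,
                   trait_cluster = stats::setNames(trait_cluster, rownames(W_true)),
                   variant_cluster = stats::setNames(variant_cluster, colnames(H_true)),
                   pheno_effects = pheno_effects, seed = as.integer(seed)),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Planted ground truth: K = %d, %d traits x %d variants\n",
              x$K_true, nrow(x$W_true), ncol(x$H_true)))
  invisible(x)
}

decoy_rules <- c("low_n", "gender_specific", "excluded_trait",
                 "p_threshold", "few_variants")

#' Generate GWAS-catalog style association records from a planted truth
#'
#' Emits one record per nonzero entry of `W_true %*% H_true`. The record's
#' standardized effect is `effect_sign(trait) * signal + Normal(0, noise_sd)`;
#' a standard error is drawn, `B = beta * SE`, and the p-value is the
#' two-sided normal tail of `beta` (GWAS sample sizes make the normal and
#' Student-t indistinguishable, and it keeps `B`, `SE`, `p` self-consistent).
#' Every variant is its own proxy; [synthetic_proxy_table()] supplies the
#' matching identity proxy-LD table.
#'
#' In addition, `n_decoys` records are appended that each violate exactly
#' one of the downstream filtering rules (GWAS sample size below 100,
#' gender-specific study, kidney-function trait name, sub-threshold
#' p-value, or a trait supported by fewer than five variants), labelled in
#' the `decoy_rule` column so tests can assert that filtering removes
#' exactly the planted violations.
#'
#' @param truth A [generate_truth()] object.
#' @param noise_sd Standard deviation of the noise added to the planted
#'   standardized effect (>= 0).
#' @param n_decoys Number of labelled filter-violating records to append.
#' @param seed Integer seed.
#' @return A data.frame with columns `proxy_rsid`, `trait`, `B`, `SE`, `p`,
#'   `n`, `gender_specific`, `study_id`, `effect_allele`, `decoy_rule`
#'   (`NA` for genuine records).
#' @export
generate_association_records <- function(truth, noise_sd = 0.05, n_decoys = 0L,
                                         seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_decoys, "n_decoys", lower = 0)

  with_seed(seed, {
    S <- truth$W_true %*% truth$H_true
    nz <- which(S > 0, arr.ind = TRUE)
    beta <- truth$effect_sign[nz[, 1]] * S[nz] +
      stats::rnorm(nrow(nz), 0, noise_sd)
    se <- stats::runif(nrow(nz), 0.02, 0.1)
    rec <- data.frame(
      proxy_rsid = colnames(S)[nz[, 2]],
      trait = rownames(S)[nz[, 1]],
      B = beta * se,
      SE = se,
      p = 2 * stats::pnorm(-abs(beta)),
      n = sample(10000:500000, nrow(nz), replace = TRUE),
      gender_specific = FALSE,
      study_id = sprintf("GCST%06d", sample.int(999999, nrow(nz))),
      effect_allele = "A",
      decoy_rule = NA_character_,
      stringsAsFactors = FALSE
    )

    if (n_decoys > 0) {
      rules <- rep_len(decoy_rules, n_decoys)
      strong_beta <- stats::runif(n_decoys, 8, 12)
      se_d <- stats::runif(n_decoys, 0.02, 0.1)
      d <- data.frame(
        proxy_rsid = sample(colnames(S), n_decoys, replace = TRUE),
        trait = sample(rownames(S), n_decoys, replace = TRUE),
        B = strong_beta * se_d,
        SE = se_d,
        p = 2 * stats::pnorm(-strong_beta),
        n = sample(10000:500000, n_decoys, replace = TRUE),
        gender_specific = FALSE,
        study_id = sprintf("GCSTD%05d", seq_len(n_decoys)),
        effect_allele = "A",
        decoy_rule = rules,
        stringsAsFactors = FALSE
      )
      d$n[rules == "low_n"] <- sample(10:99, sum(rules == "low_n"), replace = TRUE)
      d$gender_specific[rules == "gender_specific"] <- TRUE
      d$trait[rules == "excluded_trait"] <- "Estimated glomerular filtration rate"
      weak <- rules == "p_threshold"
      d$B[weak] <- 1 * d$SE[weak]
      d$p[weak] <- 2 * stats::pnorm(-1)
      rare <- which(rules == "few_variants")
      d$trait[rare] <- sprintf("Rare decoy trait %d", seq_along(rare))
      rec <- rbind(rec, d)
    }
    rownames(rec) <- NULL
    rec
  })
}

#' Identity proxy-LD table for a planted truth
#'
#' Each lead variant is listed as its own proxy with r2 = 1, matching how
#' [generate_association_records()] keys records by the lead rsID.
#'
#' @param truth A [generate_truth()] object.
#' @return data.frame with `lead_rsid`, `proxy_rsid`, `r2`.
#' @export
synthetic_proxy_table <- function(truth) {
  rs <- colnames(truth$H_true)
  data.frame(lead_rsid = rs, proxy_rsid = rs, r2 = 1, stringsAsFactors = FALSE)
}

#' Lead-variant table for a planted truth
#'
#' All synthetic variants are A/G with the kidney-function-decreasing
#' allele set to the effect allele A, i.e. records are already oriented.
#'
#' @param truth A [generate_truth()] object.
#' @return data.frame with `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `kidney_decreasing_allele`.
#' @export
synthetic_variant_table <- function(truth) {
  rs <- colnames(truth$H_true)
  data.frame(rsid = rs,
             chrom = as.character(rep_len(1:22, length(rs))),
             pos = seq_along(rs) * 1000L,
             effect_allele = "A", other_allele = "G",
             kidney_decreasing_allele = "A", stringsAsFactors = FALSE)
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Draws diploid dosages in {0, 1, 2} for one or more groups
#' (e.g. continental ancestry groups), each with its own per-variant allele
#' frequency drawn uniformly from the group's MAF range. Genotypes follow
#' Hardy-Weinberg proportions p^2 / 2pq / q^2 within each group.
#'
#' @param n_individuals,n_variants Matrix dimensions.
#' @param groups List of `list(label =, fraction =, maf_range = c(lo, hi))`;
#'   fractions must sum to 1 and MAF ranges lie within (0, 0.5].
#' @param seed Integer seed.
#' @return List with `dosages` (n x variants integer matrix, rownames
#'   individual ids), `group` (per-individual labels) and `freq`
#'   (group x variant allele frequencies).
#' @export
generate_genotypes <- function(n_individuals, n_variants,
                               groups = list(list(label = "POP1", fraction = 1,
                                                  maf_range = c(0.05, 0.5))),
                               seed = 1L) {
  check_number(n_individuals, "n_individuals", lower = 1)
  check_number(n_variants, "n_variants", lower = 1)
  fr <- vapply(groups, function(g) g$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8) stop_param("group fractions must sum to 1")
  for (g in groups) {
    if (g$maf_range[1] <= 0 || g$maf_range[2] > 0.5 ||
        g$maf_range[1] > g$maf_range[2]) {
      stop_param("maf_range must lie within (0, 0.5]")
    }
  }
  with_seed(seed, {
    sizes <- diff(round(cumsum(c(0, fr)) * n_individuals))
    labels <- rep(vapply(groups, function(g) g$label, character(1)), sizes)
    freq <- t(vapply(groups, function(g)
      stats::runif(n_variants, g$maf_range[1], g$maf_range[2]),
      numeric(n_variants)))
    rownames(freq) <- vapply(groups, function(g) g$label, character(1))
    colnames(freq) <- sprintf("rs%04d", seq_len(n_variants))
    d <- matrix(0L, n_individuals, n_variants,
                dimnames = list(sprintf("ind_%05d", seq_len(n_individuals)),
                                colnames(freq)))
    start <- 0L
    for (i in seq_along(groups)) {
      if (sizes[i] == 0) next
      rows <- start + seq_len(sizes[i])
      d[rows, ] <- matrix(stats::rbinom(sizes[i] * n_variants, 2L,
                                        rep(freq[i, ], each = sizes[i])),
                          sizes[i], n_variants)
      start <- start + sizes[i]
    }
    list(dosages = d, group = stats::setNames(labels, rownames(d)), freq = freq)
  })
}

#' Simulate phenotypes with planted cluster effects
#'
#' Quantitative phenotypes are built from the planted cluster polygenic
#' scores: for phenotype p, the genetic value is
#' `sum_k pheno_effects[k, p] * z(raw cPGS_k)` where the raw score uses the
#' true variant weights `H_true`; environmental noise is scaled so the
#' genetic value explains fraction `h2` of the phenotypic variance. Null
#' phenotypes are pure standard normal noise. Binary phenotypes come from a
#' liability threshold at the stated population prevalence and are emitted
#' as ICD-style code event lists: cases carry two or more events of the
#' phenotype's code (satisfying the Phecode rule), and a small fraction of
#' non-cases carry exactly one event, which the Phecode rule must exclude.
#'
#' @param dosages Individuals x variants dosage matrix (columns must cover
#'   the variants of `truth`).
#' @param truth A [generate_truth()] object.
#' @param h2 Fraction of variance explained by the planted score, in (0, 1).
#' @param prevalence Population prevalence of each binary phenotype, (0, 1).
#' @param seed Integer seed.
#' @param single_code_frac Fraction of non-cases given exactly one code event.
#' @return List with `phenotypes` (data.frame: individual_id, sex, age, one
#'   column per quantitative phenotype), `code_events` (data.frame:
#'   individual_id, code; one row per event), `code_map` (ICD code to
#'   Phecode toy map), `case_status` (individuals x binary phenotypes
#'   logical), and `true_scores` (raw planted cPGS matrix).
#' @export
generate_phenotypes <- function(dosages, truth, h2 = 0.3, prevalence = 0.1,
                                seed = 1L, single_code_frac = 0.02) {
  stopifnot(inherits(truth, "ground_truth"))
  check_number(h2, "h2", lower = 1e-12, upper = 1 - 1e-12)
  check_number(prevalence, "prevalence", lower = 1e-12, upper = 1 - 1e-12)
  vs <- colnames(truth$H_true)
  if (!all(vs %in% colnames(dosages))) {
    stop_param("dosage matrix does not cover the truth's variants")
  }
  with_seed(seed, {
    n <- nrow(dosages)
    raw <- dosages[, vs, drop = FALSE] %*% t(truth$H_true)  # n x K
    zscore <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    z <- apply(raw, 2, zscore)
    eff <- truth$pheno_effects
    type <- attr(eff, "type")

    sex <- stats::rbinom(n, 1, 0.5)
    age <- round(stats::runif(n, 20, 80))
    phen <- data.frame(individual_id = rownames(dosages), sex = sex, age = age,
                       stringsAsFactors = FALSE)

    liab <- matrix(NA_real_, n, 0)
    for (p in colnames(eff)) {
      g <- as.vector(z %*% eff[, p])
      vg <- stats::var(g)
      if (vg > 0) {
        y <- g + stats::rnorm(n, 0, sqrt(vg * (1 - h2) / h2))
      } else {
        y <- stats::rnorm(n)
      }
      if (type[[p]] == "quantitative") {
        phen[[p]] <- y
      } else {
        liab <- cbind(liab, zscore(y))
        colnames(liab)[ncol(liab)] <- p
      }
    }

    thr <- stats::qnorm(1 - prevalence)
    case <- liab > thr
    codes <- stats::setNames(sprintf("ICD_%02d", seq_len(ncol(liab))),
                             colnames(liab))
    ev_id <- character(0); ev_code <- character(0)
    for (p in colnames(liab)) {
      cases <- which(case[, p])
      n_events <- sample(2:3, length(cases), replace = TRUE)
      ev_id <- c(ev_id, rep(rownames(dosages)[cases], n_events))
      ev_code <- c(ev_code, rep(codes[[p]], sum(n_events)))
      non <- which(!case[, p])
      one <- non[stats::runif(length(non)) < single_code_frac]
      ev_id <- c(ev_id, rownames(dosages)[one])
      ev_code <- c(ev_code, rep(codes[[p]], length(one)))
    }
    code_map <- data.frame(code = codes,
                           phecode = sub("ICD", "PHE", codes),
                           phecode_name = names(codes),
                           stringsAsFactors = FALSE, row.names = NULL)
    list(phenotypes = phen,
         code_events = data.frame(individual_id = ev_id, code = ev_code,
                                  stringsAsFactors = FALSE),
         code_map = code_map, case_status = case, true_scores = raw)
  })
}
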