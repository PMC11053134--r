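#' Relatedness pruning with the KING-robust estimator
#'
#' Estimates pairwise kinship with the KING-robust between-family
#' estimator,
#' \deqn{\phi_{ij} = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)},}
#' where counts run over variants non-missing in both individuals
#' (heterozygous-concordant pairs, opposite homozygotes, and per-individual
#' heterozygote counts). Pairs above `degree_threshold` (default 0.0884,
#' the 2nd-degree kinship bound) are greedily resolved: the member of a
#' flagged pair with more flagged partners is dropped (ties by dropping
#' the lexicographically larger id), until no flagged pair remains.
#'
#' @param dosages Individuals x variants matrix of dosages in {0, 1, 2},
#'   `NA` allowed; rownames are individual ids.
#' @param degree_threshold Kinship above which a pair is flagged.
#' @return List with `retained` (ids), `dropped`, `kinship` (symmetric
#'   matrix), and `log` (ids excluded for having no genotype calls).
#' @export
kinship_filter <- function(dosages, degree_threshold = 0.0884) {
  if (nrow(dosages) < 2L) stop_param("need at least 2 individuals")
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("ind_%05d", seq_len(nrow(dosages)))
  }
  obs <- !is.na(dosages)
  all_missing <- rowSums(obs) == 0L
  excluded <- rownames(dosages)[all_missing]
  d <- dosages[!all_missing, , drop = FALSE]
  obs <- obs[!all_missing, , drop = FALSE]

  het <- (d == 1) & obs; het[is.na(het)] <- FALSE
  hom0 <- (d == 0) & obs; hom0[is.na(hom0)] <- FALSE
  hom2 <- (d == 2) & obs; hom2[is.na(hom2)] <- FALSE
  het <- het * 1; hom0 <- hom0 * 1; hom2 <- hom2 * 1; obsn <- obs * 1

  n_hethet <- tcrossprod(het)
  n_opp <- tcrossprod(hom0, hom2) + tcrossprod(hom2, hom0)
  het_i <- het %*% t(obsn)       # hets of i over sites observed in both
  het_j <- t(het_i)
  denom <- het_i + het_j
  phi <- (n_hethet - 2 * n_opp) / denom
  phi[!is.finite(phi)] <- 0
  diag(phi) <- 0.5
  dimnames(phi) <- list(rownames(d), rownames(d))

  flag <- phi > degree_threshold
  diag(flag) <- FALSE
  keep <- rep(TRUE, nrow(d))
  names(keep) <- rownames(d)
  repeat {
    deg <- rowSums(flag[keep, keep, drop = FALSE])
    if (!length(deg) || max(deg) == 0L) break
    worst <- names(deg)[deg == max(deg)]
    drop_id <- max(worst)  # lexicographic tie-break
    keep[drop_id] <- FALSE
  }
  list(retained = names(keep)[keep],
       dropped = c(names(keep)[!keep], excluded),
       kinship = phi, log = excluded)
}

#' Principal component analysis of a dosage matrix
#'
#' Drops variants with minor allele frequency below `maf_min`, mean-imputes
#' missing dosages, centers each variant at twice its allele frequency and
#' scales by `sqrt(2 p (1 - p))` (the standard genotype standardization),
#' then takes the top left singular coordinates. Each PC's sign is fixed so
#' that its largest-magnitude variant loading is positive.
#'
#' @param dosages Individuals x variants dosage matrix (`NA` allowed).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param n_pcs Number of components (default 10).
#' @return List with `scores` (individuals x n_pcs, principal coordinates
#'   U d), `loadings` (variants x n_pcs), `d` (singular values),
#'   `kept_variants`, `maf`.
#' @export
dosage_pca <- function(dosages, maf_min = 0.05, n_pcs = 10L) {
  d <- as.matrix(dosages)
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(maf) & maf >= maf_min & p > 0 & p < 1)
  if (length(keep) < n_pcs) {
    stop_param(sprintf("only %d variants pass the MAF filter; need >= %d",
                       length(keep), n_pcs))
  }
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  for (j in which(colSums(is.na(d)) > 0)) {
    d[is.na(d[, j]), j] <- 2 * p[j]
  }
  Z <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(Z, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  U <- sweep(sv$u, 2, flip, "*")
  V <- sweep(sv$v, 2, flip, "*")
  scores <- sweep(U, 2, sv$d[seq_len(n_pcs)], "*")
  dimnames(scores) <- list(rownames(dosages), paste0("PC", seq_len(n_pcs)))
  dimnames(V) <- list(colnames(dosages)[keep], colnames(scores))
  list(scores = scores, loadings = V, d = sv$d[seq_len(n_pcs)],
       kept_variants = colnames(dosages)[keep], maf = maf)
}

#' Probabilistic group assignment from principal components
#'
#' Trains a probabilistic classifier (default: a random forest) on labelled
#' reference coordinates — e.g. reference-panel PCs with continental
#' ancestry labels — and assigns each query individual the class with
#' the highest predicted probability. Individuals whose maximum
#' probability is at or below `prob_floor` are flagged as mixed and
#' excluded from group-specific analyses while remaining in the pooled
#' cohort. Optional trimming on the classifier probability within each
#' assigned group (`trim_quantiles`) is available but disabled by default.
#'
#' @param pcs Query coordinates (individuals x dims).
#' @param reference_pcs Labelled reference coordinates (same dims).
#' @param reference_labels Factor/character labels for the reference rows.
#' @param prob_floor Exclusion threshold on the maximum class probability.
#' @param classifier Either `"randomforest"` or a function
#'   `f(train_x, train_y)` returning `function(newdata)` that yields a
#'   class-probability matrix.
#' @param trim_quantiles Optional length-2 probability quantile window
#'   (e.g. `c(0.25, 0.90)`) applied within each assigned group; `NULL`
#'   (default) disables trimming.
#' @param seed Integer seed for the default classifier.
#' @return data.frame with `individual_id`, `group_label`, `group_prob`,
#'   `included_in_group_analysis`.
#' @export
assign_groups <- function(pcs, reference_pcs, reference_labels,
                          prob_floor = 0.5, classifier = "randomforest",
                          trim_quantiles = NULL, seed = 1L) {
  pcs <- as.matrix(pcs)
  reference_pcs <- as.matrix(reference_pcs)
  if (ncol(pcs) != ncol(reference_pcs)) {
    stop_param("query and reference coordinates have different dimensions")
  }
  if (length(unique(reference_labels)) < 2L) {
    stop_param("reference must contain at least 2 labels")
  }
  prob <- if (is.function(classifier)) {
    classifier(reference_pcs, factor(reference_labels))(pcs)
  } else {
    with_seed(seed, {
      rf <- randomForest::randomForest(reference_pcs,
                                       factor(reference_labels),
                                       ntree = 500)
      stats::predict(rf, pcs, type = "prob")
    })
  }
  lab <- colnames(prob)[max.col(prob, ties.method = "first")]
  pmax_ <- prob[cbind(seq_len(nrow(prob)), max.col(prob, ties.method = "first"))]
  included <- pmax_ > prob_floor
  if (!is.null(trim_quantiles)) {
    for (g in unique(lab)) {
      idx <- which(lab == g & included)
      if (length(idx) < 2L) next
      q <- stats::quantile(pmax_[idx], trim_quantiles, names = FALSE)
      included[idx] <- pmax_[idx] >= q[1] & pmax_[idx] <= q[2]
    }
  }
  ids <- rownames(pcs)
  if (is.null(ids)) ids <- sprintf("ind_%05d", seq_len(nrow(pcs)))
  data.frame(individual_id = ids, group_label = lab, group_prob = pmax_,
             included_in_group_analysis = included,
             stringsAsFactors = FALSE, row.names = NULL)
}
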