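#' Compute raw cluster-specific polygenic scores
#'
#' For each cluster k the raw score of individual i is the weight-dosage
#' inner product \eqn{\sum_v w_{k,v} d_{i,v}} (sum scoring; downstream
#' standardization makes the scale immaterial and the sum keeps the score
#' exactly linear in weights and dosages). Missing dosages are replaced by
#' the cohort mean dosage of the variant; weighted variants absent from
#' the genotype panel are dropped with a logged count.
#'
#' @param dosages Individuals x variants matrix (`NA` allowed), columns
#'   named by rsid.
#' @param weights Either a clusters x variants matrix (e.g. the H matrix of
#'   an [nmf()] fit) with rsid column names, or a data.frame with columns
#'   `cluster_id`, `rsid`, `weight`.
#' @return Individuals x clusters matrix of raw scores with a `dropped`
#'   attribute counting panel-absent variants per cluster.
#' @export
compute_cpgs <- function(dosages, weights) {
  d <- as.matrix(dosages)
  if (is.data.frame(weights)) {
    cl <- sort(unique(weights$cluster_id))
    W <- matrix(0, length(cl), length(unique(weights$rsid)),
                dimnames = list(cl, unique(weights$rsid)))
    W[cbind(match(weights$cluster_id, cl),
            match(weights$rsid, colnames(W)))] <- weights$weight
  } else {
    W <- as.matrix(weights)
  }
  if (is.null(colnames(W)) || is.null(colnames(d))) {
    stop_param("both weights and dosages must name their variants")
  }
  present <- colnames(W) %in% colnames(d)
  dropped <- rowSums(W[, !present, drop = FALSE] != 0)
  Wp <- W[, present, drop = FALSE]
  zero_overlap <- rowSums(Wp != 0) == 0 & rowSums(W != 0) > 0
  if (any(zero_overlap)) {
    stop_param(sprintf("no overlapping variants for cluster(s): %s",
                       paste(rownames(W)[zero_overlap], collapse = ", ")))
  }
  dm <- d[, colnames(Wp), drop = FALSE]
  if (anyNA(dm)) {
    mu <- colMeans(dm, na.rm = TRUE)
    idx <- which(is.na(dm), arr.ind = TRUE)
    dm[idx] <- mu[idx[, 2]]
  }
  scores <- dm %*% t(Wp)
  attr(scores, "dropped") <- dropped
  scores
}

#' Standardize cluster polygenic scores
#'
#' z-scores each cluster's raw scores using the mean and sample standard
#' deviation (denominator n - 1) computed on the standardization cohort —
#' by default the full pooled cohort, so that group-level comparisons share
#' one z axis.
#'
#' @param raw Individuals x clusters raw score matrix from [compute_cpgs()].
#' @param cohort Optional ids (rownames of `raw`) defining the
#'   standardization set; default all individuals.
#' @return Matrix of z-scores (same shape as `raw`).
#' @export
standardize_cpgs <- function(raw, cohort = NULL) {
  ref <- if (is.null(cohort)) raw else raw[cohort, , drop = FALSE]
  mu <- colMeans(ref)
  sdev <- apply(ref, 2, stats::sd)
  if (any(sdev <= 0)) {
    stop_param(sprintf("degenerate cluster(s) with zero score variance: %s",
                       paste(colnames(raw)[sdev <= 0], collapse = ", ")))
  }
  sweep(sweep(raw, 2, mu), 2, sdev, "/")
}

#' Anderson-Darling test of score normality
#'
#' Tests the composite normality hypothesis (mean and variance estimated)
#' with the small-sample adjusted Anderson-Darling statistic and Stephens'
#' p-value approximation, as implemented in the nortest package.
#'
#' @param z Numeric vector of scores (n >= 8, non-constant).
#' @return List with `A2` (the statistic) and `p`.
#' @export
ad_normality <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) < 8L) stop_param("Anderson-Darling test needs n >= 8")
  if (stats::sd(z) == 0) stop_param("scores are constant; variance is zero")
  t <- nortest::ad.test(z)
  list(A2 = unname(t$statistic), p = t$p.value)
}

#' Mann-Whitney comparison of two score distributions
#'
#' Rank-sum test with midrank ties. The p-value is exact (full enumeration
#' of arrangements) when `length(a) * length(b) <= 400` and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' corrections is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List with `U` (the U statistic of `a`) and `p` (two-sided).
#' @export
mw_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop_param("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 400
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Top-decile cluster membership of individuals
#'
#' Flags, per cluster, the individuals whose standardized score is at or
#' above the 90th percentile of that cluster's scores (same percentile
#' rule as [top_decile()]), and summarizes how many clusters each
#' individual is at high genetic risk for.
#'
#' @param z Individuals x clusters matrix of standardized scores
#'   (>= 10 individuals).
#' @param prob Percentile defining the high-score tail (default 0.9).
#' @return List with `membership` (logical matrix), `counts`
#'   (per-individual number of clusters), `fraction_ge1` (fraction of the
#'   cohort in at least one top decile), and `distribution` (proportions
#'   of individuals by count; sums to 1).
#' @export
decile_membership <- function(z, prob = 0.9) {
  z <- as.matrix(z)
  if (nrow(z) < 10L) stop_param("need at least 10 individuals")
  thr <- apply(z, 2, stats::quantile, probs = prob, names = FALSE, type = 7)
  member <- sweep(z, 2, thr, ">=")
  counts <- rowSums(member)
  dist <- table(factor(counts, levels = 0:ncol(z))) / nrow(z)
  list(membership = member, counts = counts,
       fraction_ge1 = mean(counts >= 1),
       distribution = dist)
}
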