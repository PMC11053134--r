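# Independent oracles used to check the package's statistics by brute force,
# plus small fixture builders shared across test files.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  all_u <- apply(utils::combn(n, na), 2, u_of)
  p <- 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs))
  min(p, 1)
}

# Hypergeometric upper tail P(overlap >= k) by enumerating every size-n draw
# from a universe of size N whose first K elements form the gene set.
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Brute-force weighted (exponent 1) running-sum enrichment score.
gsea_es_oracle <- function(scores, members) {
  ord <- order(scores, decreasing = TRUE)
  nm <- names(scores)[ord]
  w <- abs(scores[ord])
  inset <- nm %in% members
  nh <- sum(inset)
  n <- length(scores)
  if (nh == 0 || nh == n) return(NA_real_)
  denom <- sum(w[inset])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (inset[i]) {
      run <- run + (if (denom > 0) w[i] / denom else 1 / nh)
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Linear-interpolation percentile threshold computed from first principles.
percentile_oracle <- function(x, prob = 0.9) {
  s <- sort(x)
  h <- (length(s) - 1) * prob
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# One planted dataset run through records -> filter -> standardize -> align
# -> matrix; returns the truth alongside the association matrix.
planted_matrix <- function(K = 4, n_traits = 60, n_variants = 120,
                           noise_sd = 0.1, seed = 1, filter = FALSE) {
  tr <- generate_truth(K, n_traits, n_variants, seed = seed)
  rec <- generate_association_records(tr, noise_sd = noise_sd, seed = seed)
  if (filter) rec <- filter_associations(rec)$records
  al <- align_to_lead(standardize_effects(rec), synthetic_proxy_table(tr),
                      synthetic_variant_table(tr))
  list(truth = tr, X = build_matrix(al))
}

# Variant cluster recovery accuracy of a fitted H against the planted truth.
variant_accuracy <- function(H, truth) {
  assign <- apply(H, 2, which.max)
  cluster_match_accuracy(assign, truth$variant_cluster[colnames(H)])
}
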