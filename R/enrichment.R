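#' Per-cluster gene rank scores from variant weights
#'
#' Collapses variant-level cluster weights to genes: a gene's score in a
#' cluster is the maximum H weight over the variants annotated to it (when
#' a gene tags several variants only the highest weight counts). Variants
#' absent from the map are logged, not fatal.
#'
#' @param H Clusters x variants weight matrix (rsid column names).
#' @param variant_gene_map data.frame with `rsid` and `gene` (each variant
#'   maps to at most one gene, e.g. its closest gene).
#' @return Named list (one element per cluster) of named score vectors,
#'   with an `unmapped` attribute counting unannotated variants.
#' @export
gene_ranks <- function(H, variant_gene_map) {
  if (is.null(variant_gene_map) || nrow(variant_gene_map) == 0) {
    stop_param("variant-gene map is empty")
  }
  H <- as.matrix(H)
  m <- match(colnames(H), variant_gene_map$rsid)
  unmapped <- sum(is.na(m))
  genes <- variant_gene_map$gene[m]
  keep <- !is.na(genes)
  out <- lapply(seq_len(nrow(H)), function(k) {
    s <- tapply(H[k, keep], genes[keep], max)
    stats::setNames(as.numeric(s), names(s))
  })
  names(out) <- rownames(H)
  attr(out, "unmapped") <- unmapped
  out
}

# Weighted (exponent 1) Kolmogorov-Smirnov running-sum enrichment score on
# a descending-ordered score vector.
gsea_es <- function(scores, members) {
  ord <- order(scores, decreasing = TRUE)
  inset <- names(scores)[ord] %in% members
  w <- abs(scores[ord])
  nh <- sum(inset)
  n <- length(scores)
  if (nh == 0L || nh == n) return(NA_real_)
  denom_hit <- sum(w[inset])
  p_hit <- cumsum(ifelse(inset, if (denom_hit > 0) w / denom_hit else
    1 / nh, 0))
  if (denom_hit == 0) p_hit <- cumsum(ifelse(inset, 1 / nh, 0))
  p_miss <- cumsum(ifelse(inset, 0, 1 / (n - nh)))
  run <- p_hit - p_miss
  unname(run[which.max(abs(run))])
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment (weight exponent 1) of
#' each gene set against a descending gene ranking. The null distribution
#' comes from gene-label permutation (random member sets of the same
#' size); NES divides the observed ES by the mean |null ES| of the same
#' sign, and the two-sided empirical p-value uses the +1 correction. Sets
#' are filtered to genes present in the ranking and skipped when outside
#' the size bounds or equal to the whole universe. q-values are
#' Benjamini-Hochberg across the tested sets.
#'
#' @param ranks Named numeric vector of non-negative gene scores for one
#'   cluster (one element of [gene_ranks()]).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param min_size,max_size Post-filter gene-set size bounds.
#' @return data.frame with `set`, `size`, `ES`, `NES`, `p`, `q`; skipped
#'   set names in the `skipped` attribute.
#' @export
gsea_prerank <- function(ranks, gene_sets, n_perm = 1000L, seed = 1L,
                         min_size = 3L, max_size = 500L) {
  check_number(n_perm, "n_perm", lower = 100)
  universe <- names(ranks)
  sets <- lapply(gene_sets, intersect, universe)
  sizes <- lengths(sets)
  ok <- sizes >= min_size & sizes <= max_size & sizes < length(universe)
  skipped <- names(sets)[!ok]
  sets <- sets[ok]
  if (!length(sets)) {
    out <- data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0), q = numeric(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  with_seed(seed, {
    res <- lapply(names(sets), function(nm) {
      s <- sets[[nm]]
      es <- gsea_es(ranks, s)
      null_es <- vapply(seq_len(n_perm), function(i)
        gsea_es(ranks, sample(universe, length(s))), numeric(1))
      null_es <- null_es[is.finite(null_es)]
      same <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(null_es) >= abs(es))) / (1 + length(null_es))
      data.frame(set = nm, size = length(s), ES = es, NES = nes, p = p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    attr(out, "skipped") <- skipped
    out
  })
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests each gene set for overrepresentation among a selected gene list
#' (by default the genes of the top-weighted variants of a cluster)
#' against a finite universe: `p = P(X >= k)` for a hypergeometric draw
#' with universe size N, set size K, draw size n and overlap k;
#' fold-enrichment is `(k/n) / (K/N)`. q-values are Benjamini-Hochberg.
#'
#' @param top_genes Character vector of selected genes (subset of
#'   `universe`).
#' @param universe Character vector, the gene universe (all mapped genes).
#' @param gene_sets Named list of character vectors.
#' @return data.frame with `set`, `set_size`, `overlap`,
#'   `fold_enrichment`, `p`, `q`.
#' @export
ora_hypergeometric <- function(top_genes, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) stop_param("empty gene universe")
  top_genes <- intersect(unique(top_genes), universe)
  N <- length(universe)
  n <- length(top_genes)
  res <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(s, top_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
    data.frame(set = nm, set_size = K, overlap = k, fold_enrichment = fe,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Genes of a cluster's top-weighted variants
#'
#' Selects the top `frac` fraction of variants by cluster weight (ties at
#' the threshold included) and returns the genes annotated to them —
#' the default input of [ora_hypergeometric()].
#'
#' @param h_row Named numeric vector: one cluster's variant weights.
#' @param variant_gene_map data.frame with `rsid`, `gene`.
#' @param frac Fraction of variants taken from the top (default 0.25).
#' @return Character vector of genes.
#' @export
top_fraction_genes <- function(h_row, variant_gene_map, frac = 0.25) {
  thr <- stats::quantile(h_row, 1 - frac, names = FALSE, type = 7)
  rs <- names(h_row)[h_row >= thr]
  unique(variant_gene_map$gene[variant_gene_map$rsid %in% rs &
                                 !is.na(variant_gene_map$gene)])
}
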