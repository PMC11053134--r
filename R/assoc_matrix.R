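#' Filter GWAS-catalog style association records
#'
#' Applies, in a fixed order, the record-level exclusions used to build the
#' trait-variant matrix: (1) gender-specific studies; (2) studies with
#' fewer than `min_n` individuals; (3) traits matching any excluded
#' pattern (kidney-function traits are secondary-trait contaminants);
#' (4) associations with p at or above the significance threshold;
#' (5) traits left with fewer than `min_variants_per_trait` distinct
#' variants. The fixed order makes the per-rule removal counts in the
#' returned log reproducible.
#'
#' @param records data.frame of association records with columns `trait`,
#'   `p`, `n`, `gender_specific` and an rsid column (`proxy_rsid` or
#'   `lead_rsid`).
#' @param excluded_trait_patterns Case-insensitive fixed patterns; a record
#'   is dropped when its trait name contains any of them.
#' @param p_threshold Keep associations with `p < p_threshold`.
#' @param min_n Minimum GWAS sample size.
#' @param min_variants_per_trait Minimum distinct variants per surviving trait.
#' @return List with `records` (survivors) and `log`, a named integer vector
#'   of per-rule removal counts plus `kept`.
#' @export
filter_associations <- function(records,
                                excluded_trait_patterns =
                                  c("glomerular filtration rate",
                                    "chronic kidney disease"),
                                p_threshold = 1e-6, min_n = 100,
                                min_variants_per_trait = 5) {
  check_number(p_threshold, "p_threshold", lower = 1e-300)
  check_number(min_n, "min_n", lower = 1)
  check_number(min_variants_per_trait, "min_variants_per_trait", lower = 1)
  log <- c(gender_specific = 0L, low_n = 0L, excluded_trait = 0L,
           p_threshold = 0L, few_variants = 0L, kept = 0L)
  if (nrow(records) == 0L) {
    return(list(records = records, log = log))
  }
  rsid_col <- intersect(c("lead_rsid", "proxy_rsid", "rsid"), names(records))[1]
  if (is.na(rsid_col)) stop_param("records need an rsid column")

  drop <- records$gender_specific
  log["gender_specific"] <- sum(drop)
  r <- records[!drop, , drop = FALSE]

  drop <- r$n < min_n
  log["low_n"] <- sum(drop)
  r <- r[!drop, , drop = FALSE]

  if (length(excluded_trait_patterns)) {
    hit <- Reduce(`|`, lapply(excluded_trait_patterns, function(p)
      grepl(p, r$trait, ignore.case = TRUE, fixed = FALSE)))
    log["excluded_trait"] <- sum(hit)
    r <- r[!hit, , drop = FALSE]
  }

  drop <- r$p >= p_threshold
  log["p_threshold"] <- sum(drop)
  r <- r[!drop, , drop = FALSE]

  nv <- tapply(r[[rsid_col]], r$trait, function(x) length(unique(x)))
  bad_traits <- names(nv)[nv < min_variants_per_trait]
  drop <- r$trait %in% bad_traits
  log["few_variants"] <- sum(drop)
  r <- r[!drop, , drop = FALSE]

  log["kept"] <- nrow(r)
  if (nrow(r) == 0L) stop_param("no data after filtering")
  rownames(r) <- NULL
  list(records = r, log = log)
}

#' Standardize GWAS effect sizes
#'
#' Sets `beta_std = B / SE`, the dimensionless standardized effect (a
#' z-score) that makes effects comparable across GWAS of traits measured
#' in different units. Sign is preserved.
#'
#' @param records data.frame with numeric columns `B` and `SE`.
#' @return The records with a `beta_std` column added.
#' @export
standardize_effects <- function(records) {
  bad <- which(!(records$SE > 0))
  if (length(bad)) {
    stop_param(sprintf("non-positive SE in record(s): %s",
                       paste(utils::head(bad, 5), collapse = ", ")))
  }
  records$beta_std <- records$B / records$SE
  records
}

#' Attribute proxy-variant associations to their lead variants
#'
#' Joins association records to lead variants through the proxy-LD table
#' (links with `r2 < r2_min` are dropped), flips the effect sign when the
#' record's effect allele is not the lead variant's
#' kidney-function-decreasing allele, and deduplicates: when several
#' proxies of one lead hit the same trait, the record with largest
#' `|beta_std|` is kept (ties broken by smaller p, then lexicographic
#' proxy rsid). Records whose proxy has no known lead are skipped with a
#' warning; records whose effect allele matches neither allele of the lead
#' are skipped and logged.
#'
#' @param records Standardized records (must carry `beta_std`); an optional
#'   `effect_allele` column drives allele orientation (absent = assumed
#'   already oriented to the kidney-decreasing allele).
#' @param proxies data.frame with `lead_rsid`, `proxy_rsid`, `r2`.
#' @param variants Lead-variant table with `rsid`, `effect_allele`,
#'   `other_allele`, `kidney_decreasing_allele`.
#' @param r2_min Minimum linkage disequilibrium r-squared (default 0.6).
#' @return Records keyed by `lead_rsid`, deduplicated per (lead, trait),
#'   with an `alignment` attribute logging skipped records.
#' @export
align_to_lead <- function(records, proxies, variants, r2_min = 0.6) {
  if (is.null(records$beta_std)) {
    stop_param("records must be standardized first (missing beta_std)")
  }
  proxies <- proxies[proxies$r2 >= r2_min, , drop = FALSE]
  unknown_lead <- !(proxies$lead_rsid %in% variants$rsid)
  if (any(unknown_lead)) {
    warning(sprintf("%d proxy link(s) reference unknown lead variants; skipped",
                    sum(unknown_lead)), call. = FALSE)
    proxies <- proxies[!unknown_lead, , drop = FALSE]
  }
  m <- match(records$proxy_rsid, proxies$proxy_rsid)
  no_proxy <- sum(is.na(m))
  r <- records[!is.na(m), , drop = FALSE]
  r$lead_rsid <- proxies$lead_rsid[m[!is.na(m)]]

  allele_skipped <- 0L
  if (!is.null(r$effect_allele) && nrow(r) > 0) {
    vm <- match(r$lead_rsid, variants$rsid)
    ea <- variants$effect_allele[vm]
    oa <- variants$other_allele[vm]
    kda <- variants$kidney_decreasing_allele[vm]
    match_ea <- r$effect_allele == ea
    match_oa <- r$effect_allele == oa
    unresolvable <- !match_ea & !match_oa
    allele_skipped <- sum(unresolvable)
    flip <- ifelse(match_ea, ea != kda, oa != kda)
    r$beta_std <- ifelse(flip, -r$beta_std, r$beta_std)
    r$B <- ifelse(flip, -r$B, r$B)
    r <- r[!unresolvable, , drop = FALSE]
  }

  if (nrow(r) > 0) {
    ord <- order(r$lead_rsid, r$trait, -abs(r$beta_std), r$p, r$proxy_rsid)
    r <- r[ord, , drop = FALSE]
    r <- r[!duplicated(r[, c("lead_rsid", "trait")]), , drop = FALSE]
    rownames(r) <- NULL
  }
  attr(r, "alignment") <- c(no_proxy_link = no_proxy,
                            allele_unresolvable = allele_skipped)
  r
}

#' Build the non-negative trait-by-variant association matrix
#'
#' Arranges lead-aligned, standardized records as the matrix X that NMF
#' factorizes. Signed effects enter a non-negative matrix through a
#' directional trait split: each trait contributes a "+" feature row
#' holding `|beta_std|` where the effect is positive and a "-" feature row
#' holding `|beta_std|` where it is negative; all-zero feature rows are
#' dropped. This mirrors how increased/reduced versions of one physiology
#' (e.g. hematocrit) can occupy opposite clusters.
#'
#' @param records Output of [align_to_lead()] (or any records with
#'   `lead_rsid`, `trait`, `beta_std`).
#' @return Object of class `assoc_matrix`: list with `values`
#'   (features x variants, strictly non-negative), `feature_labels`
#'   (data.frame trait/direction), `variant_labels`, and `provenance`.
#' @export
build_matrix <- function(records) {
  if (is.null(records$lead_rsid) || is.null(records$beta_std)) {
    stop_param("records must carry lead_rsid and beta_std")
  }
  traits <- sort(unique(records$trait))
  rs <- sort(unique(records$lead_rsid))
  pos <- matrix(0, length(traits), length(rs), dimnames = list(traits, rs))
  neg <- pos
  i <- cbind(match(records$trait, traits), match(records$lead_rsid, rs))
  up <- records$beta_std > 0
  pos[i[up, , drop = FALSE]] <- records$beta_std[up]
  dn <- records$beta_std < 0
  neg[i[dn, , drop = FALSE]] <- -records$beta_std[dn]

  rownames(pos) <- paste0(traits, "|+")
  rownames(neg) <- paste0(traits, "|-")
  X <- rbind(pos, neg)
  X <- X[rowSums(X) > 0, , drop = FALSE]
  # interleave back into trait order for readability
  X <- X[order(sub("\\|.$", "", rownames(X)), sub(".*\\|", "", rownames(X))), ,
         drop = FALSE]
  labs <- data.frame(feature = rownames(X),
                     trait = sub("\\|.$", "", rownames(X)),
                     direction = sub(".*\\|", "", rownames(X)),
                     stringsAsFactors = FALSE)
  structure(list(values = X, feature_labels = labs, variant_labels = rs,
                 provenance = attr(records, "alignment")),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("Association matrix X: %d trait features x %d variants (min %.3g)\n",
              nrow(x$values), ncol(x$values), min(x$values)))
  invisible(x)
}

as_matrix_input <- function(X) {
  if (inherits(X, "assoc_matrix")) X <- X$values
  X <- as.matrix(X)
  if (any(X < 0)) stop_param("matrix has negative entries")
  X
}
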