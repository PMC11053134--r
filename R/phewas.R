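#' Construct Phecode case/control status from diagnosis code events
#'
#' Maps ICD-style code events to Phecodes and applies the standard rule:
#' an individual is a case for a Phecode when at least two mapped code
#' events are present in their record, excluded (neither case nor control)
#' with exactly one event, and a control otherwise.
#'
#' @param code_events data.frame with `individual_id` and `code`, one row
#'   per event.
#' @param code_map data.frame with `code` and `phecode` columns.
#' @param individuals Ids of the full cohort (controls are individuals
#'   with no qualifying events, so the universe must be supplied).
#' @return Individuals x Phecodes character matrix with entries "case",
#'   "control", "excluded"; unmapped code events are counted in the
#'   `unmapped` attribute.
#' @export
map_phecodes <- function(code_events, code_map, individuals) {
  m <- match(code_events$code, code_map$code)
  unmapped <- sum(is.na(m))
  ev <- code_events[!is.na(m), , drop = FALSE]
  phe <- code_map$phecode[m[!is.na(m)]]
  codes <- sort(unique(code_map$phecode))
  status <- matrix("control", length(individuals), length(codes),
                   dimnames = list(individuals, codes))
  if (nrow(ev) > 0) {
    counts <- table(factor(ev$individual_id, levels = individuals),
                    factor(phe, levels = codes))
    status[counts == 1L] <- "excluded"
    status[counts >= 2L] <- "case"
  }
  attr(status, "unmapped") <- unmapped
  status
}

#' Bonferroni alpha for the cluster-phenome test family
#'
#' The family comprises one test per cluster and phenotype:
#' `alpha = family_alpha / (K * (n_quant + n_binary))`.
#'
#' @param K Number of clusters.
#' @param n_quant,n_binary Numbers of quantitative and binary traits.
#' @param family_alpha Family-wise error target (default 0.05).
#' @return The per-test alpha.
#' @examples
#' compute_alpha(9, 988, 832)  # 3.05e-06, i.e. 3.1e-06 to 2 significant digits
#' @export
compute_alpha <- function(K, n_quant, n_binary, family_alpha = 0.05) {
  check_number(K, "K", lower = 0)
  check_number(n_quant, "n_quant", lower = 0)
  check_number(n_binary, "n_binary", lower = 0)
  denom <- K * (n_quant + n_binary)
  if (denom == 0) stop_param("K * (n_quant + n_binary) must be positive")
  family_alpha / denom
}

# One standardized regression; returns estimate on the coefficient scale
# (beta for linear, log-OR for logistic) plus Wald CI and p.
fit_one <- function(y, score, covars, binary) {
  zs <- (score - mean(score)) / stats::sd(score)
  if (is.null(covars) || ncol(covars) == 0L) covars <- NULL
  if (binary) {
    df <- if (is.null(covars)) data.frame(y = y, cpgs = zs) else
      data.frame(y = y, cpgs = zs, covars)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    converged <- fit$converged && !any(is.na(stats::coef(fit)["cpgs"]))
  } else {
    yz <- (y - mean(y)) / stats::sd(y)
    df <- if (is.null(covars)) data.frame(y = yz, cpgs = zs) else
      data.frame(y = yz, cpgs = zs, covars)
    fit <- stats::lm(y ~ ., data = df)
    converged <- !is.na(stats::coef(fit)["cpgs"])
  }
  sm <- summary(fit)$coefficients
  if (!("cpgs" %in% rownames(sm)) || !converged) {
    return(list(est = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_,
                converged = FALSE))
  }
  est <- sm["cpgs", 1]; se <- sm["cpgs", 2]
  p <- if (binary) 2 * stats::pnorm(-abs(est / se)) else sm["cpgs", 4]
  list(est = est, lo = est - stats::qnorm(0.975) * se,
       hi = est + stats::qnorm(0.975) * se, p = p, converged = converged)
}

#' Phenome-wide association of cluster polygenic scores
#'
#' For every (cluster, trait) pair, regresses the trait on that cluster's
#' standardized cPGS adjusting for the supplied covariates (typically sex,
#' age, and the first ten genetic principal components). Quantitative
#' traits use linear regression with both outcome and score z-scored on
#' the analysis sample, so the reported estimate is the standardized beta;
#' binary traits (Phecode status matrices from [map_phecodes()] or logical
#' columns) use logistic regression with the score z-scored, reported as
#' the odds ratio per 1 SD of cPGS. Wald 95% confidence intervals
#' throughout. Traits observed in fewer than `min_n` individuals are
#' skipped, as are binary traits with fewer than `min_cases` cases
#' (a logistic fit on a handful of cases is meaningless). Non-converged
#' logistic fits are flagged, not fatal.
#'
#' @param cpgs Individuals x clusters matrix of (raw or standardized)
#'   scores; each column is standardized within each fitted sample.
#' @param quantitative data.frame/matrix of quantitative traits (rownames
#'   = ids), `NA` for unmeasured; may be `NULL`.
#' @param binary Individuals x traits matrix with "case"/"control"/
#'   "excluded" entries (or logical), same rownames; may be `NULL`.
#' @param covariates data.frame of covariates, same rownames.
#' @param min_n Minimum non-missing sample size per trait (default 100).
#' @param min_cases Minimum case count for binary traits (default 20).
#' @param alpha Significance threshold; default computed from the result
#'   family by [compute_alpha()].
#' @param family_alpha Family-wise error target used when `alpha` is NULL.
#' @return data.frame of class `phewas_result` with one row per
#'   cluster x analysed trait: `cluster_id`, `trait`, `trait_type`,
#'   `estimate` (standardized beta, or OR for binary), `ci_low`, `ci_high`,
#'   `p`, `n`, `n_cases`, `converged`, `significant`; skipped traits are
#'   listed in the `skipped` attribute, and `alpha` is attached.
#' @export
run_phewas <- function(cpgs, quantitative = NULL, binary = NULL, covariates,
                       min_n = 100L, min_cases = 20L, alpha = NULL,
                       family_alpha = 0.05) {
  cpgs <- as.matrix(cpgs)
  ids <- rownames(cpgs)
  covariates <- as.data.frame(covariates)
  # align inputs on ids where rownames are available
  align <- function(x) {
    if (!is.null(x) && !is.null(ids) && !is.null(rownames(x)) &&
        all(ids %in% rownames(x))) {
      x[ids, , drop = FALSE]
    } else {
      x
    }
  }
  quantitative <- align(quantitative)
  binary <- align(binary)
  covariates <- align(covariates)
  rows <- list()
  skipped <- character(0)

  analyse <- function(trait, y, binaryp) {
    for (k in colnames(cpgs)) {
      ok <- !is.na(y)
      yk <- y[ok]
      f <- fit_one(yk, cpgs[ok, k], covariates[ok, , drop = FALSE], binaryp)
      rows[[length(rows) + 1L]] <<- data.frame(
        cluster_id = k, trait = trait,
        trait_type = if (binaryp) "binary" else "quantitative",
        estimate = if (binaryp) exp(f$est) else f$est,
        ci_low = if (binaryp) exp(f$lo) else f$lo,
        ci_high = if (binaryp) exp(f$hi) else f$hi,
        p = f$p, n = length(yk),
        n_cases = if (binaryp) sum(yk == 1L) else NA_integer_,
        converged = f$converged, stringsAsFactors = FALSE)
    }
  }

  if (!is.null(quantitative)) {
    qt <- as.data.frame(quantitative)
    for (trait in colnames(qt)) {
      y <- qt[[trait]]
      if (sum(!is.na(y)) < min_n || stats::sd(y, na.rm = TRUE) == 0) {
        skipped <- c(skipped, trait)
        next
      }
      analyse(trait, y, FALSE)
    }
  }
  if (!is.null(binary)) {
    bn <- as.matrix(binary)
    for (trait in colnames(bn)) {
      col <- bn[, trait]
      y <- if (is.logical(col)) ifelse(col, 1L, 0L) else {
        ifelse(col == "case", 1L, ifelse(col == "control", 0L, NA_integer_))
      }
      if (sum(!is.na(y)) < min_n || sum(y == 1L, na.rm = TRUE) < min_cases) {
        skipped <- c(skipped, trait)
        next
      }
      analyse(trait, y, TRUE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), trait = character(0))
  if (is.null(alpha)) {
    n_quant <- length(unique(res$trait[res$trait_type == "quantitative"]))
    n_binary <- length(unique(res$trait[res$trait_type == "binary"]))
    alpha <- if (nrow(res)) {
      compute_alpha(ncol(cpgs), n_quant, n_binary, family_alpha)
    } else {
      family_alpha
    }
  }
  res$significant <- !is.na(res$p) & res$p < alpha
  attr(res, "alpha") <- alpha
  attr(res, "skipped") <- unique(skipped)
  class(res) <- c("phewas_result", "data.frame")
  res
}

#' Validate a cluster's top traits against PheWAS results
#'
#' A cluster top trait is validated when its matched PheWAS association is
#' Bonferroni-significant and the sign of the standardized estimate
#' (log odds ratio for binary traits) agrees with the trait's direction in
#' the cluster (the "+"/"-" of its association-matrix feature).
#'
#' @param phewas A [run_phewas()] result.
#' @param top_traits data.frame with `cluster_id`, `trait`, `direction`
#'   ("+"/"-" or +1/-1), optional `weight` and `rank`.
#' @param synonym_map Optional data.frame with `trait` and `phewas_trait`
#'   translating matrix trait names to PheWAS trait names.
#' @return data.frame: the top traits with `phewas_trait`, `estimate`, `p`,
#'   `validated`, `matched`; per-cluster validated counts in the `summary`
#'   attribute; unmatched trait names in the `unmatched` attribute.
#' @export
validate_top_traits <- function(phewas, top_traits, synonym_map = NULL) {
  tt <- top_traits
  tt$phewas_trait <- tt$trait
  if (!is.null(synonym_map)) {
    m <- match(tt$trait, synonym_map$trait)
    tt$phewas_trait[!is.na(m)] <- synonym_map$phewas_trait[m[!is.na(m)]]
  }
  dirnum <- function(d) {
    if (is.numeric(d)) sign(d) else ifelse(d %in% c("+", "+1"), 1, -1)
  }
  tt$direction_num <- dirnum(tt$direction)
  key <- paste(phewas$cluster_id, phewas$trait, sep = "\r")
  m <- match(paste(tt$cluster_id, tt$phewas_trait, sep = "\r"), key)
  tt$matched <- !is.na(m)
  est <- phewas$estimate[m]
  est_sign <- ifelse(phewas$trait_type[m] == "binary", sign(log(est)), sign(est))
  tt$estimate <- est
  tt$p <- phewas$p[m]
  tt$validated <- tt$matched & !is.na(phewas$significant[m]) &
    phewas$significant[m] & est_sign == tt$direction_num
  summ <- stats::aggregate(validated ~ cluster_id, data = tt, FUN = sum)
  attr(tt, "summary") <- summ
  attr(tt, "unmatched") <- unique(tt$trait[!tt$matched])
  tt
}
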