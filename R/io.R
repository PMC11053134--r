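#' Read pipeline input tables
#'
#' Thin readers for the tab/comma separated inputs: association records
#' (`proxy_rsid`, `trait`, `B`, `SE`, `p`, `n`, `gender_specific`,
#' `study_id`), proxy-LD links (`lead_rsid`, `proxy_rsid`, `r2`),
#' lead-variant tables (1-based positions), and dosage matrices
#' (individuals in rows, rsid columns).
#'
#' @param path File path.
#' @return A data.frame (`read_dosages` returns a numeric matrix).
#' @name readers
NULL

#' @rdname readers
#' @export
read_associations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readers
#' @export
read_proxies <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readers
#' @export
read_variants <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readers
#' @export
read_dosages <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read genotype dosages from a VCF with GT fields
#'
#' Converts diploid GT calls (e.g. `0/1`, `1|1`, `./.`) to alternate-allele
#' dosages 0/1/2 with `NA` for missing, using the vcfR parser.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return Individuals x variants dosage matrix.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_param("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (any(al == "." | is.na(al))) return(NA_real_)
      sum(al != "0")
    }, numeric(1))
  }
  d <- apply(gt, 2, count)
  d <- t(d)
  colnames(d) <- rownames(gt)
  d
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member genes. Uses the fgsea
#' parser when available.
#'
#' @param path Path to the .gmt file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[[`, character(1), 1))
}

#' Write an association matrix with its filter provenance
#'
#' @param x An `assoc_matrix` from [build_matrix()].
#' @param path Output TSV path (a sibling `.provenance.json` is written
#'   when provenance is present).
#' @export
write_assoc_matrix <- function(x, path) {
  stopifnot(inherits(x, "assoc_matrix"))
  df <- data.frame(feature = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$provenance)) {
    jsonlite::write_json(as.list(x$provenance),
                         sub("\\.tsv$", ".provenance.json", path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write all synthetic pipeline inputs to a directory
#'
#' Materializes one planted dataset in the same file formats the pipeline
#' reads: `associations.tsv`, `proxies.tsv`, `variants.tsv`,
#' `dosages.tsv`, `genotypes.vcf` (GT-only minimal VCF),
#' `phenotypes.csv`, `code_events.csv`, `phecode_map.csv`, and
#' `truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @param K,n_traits,n_variants,n_individuals,sparsity Generator settings.
#' @param noise_sd,n_decoys,h2,prevalence Generator settings.
#' @param seed Integer seed controlling every stage.
#' @return Invisibly, the list of generated objects.
#' @export
write_synthetic_dataset <- function(dir, K = 4L, n_traits = 60L,
                                    n_variants = 120L, n_individuals = 500L,
                                    sparsity = 0, noise_sd = 0.05,
                                    n_decoys = 10L, h2 = 0.3,
                                    prevalence = 0.1, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(K, n_traits, n_variants, sparsity, seed = seed)
  rec <- generate_association_records(truth, noise_sd = noise_sd,
                                      n_decoys = n_decoys, seed = seed + 1L)
  geno <- generate_genotypes(n_individuals, n_variants, seed = seed + 2L)
  phen <- generate_phenotypes(geno$dosages, truth, h2 = h2,
                              prevalence = prevalence, seed = seed + 3L)

  tsv <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                            quote = FALSE, row.names = FALSE)
  csv <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                          quote = FALSE, row.names = FALSE)
  tsv(rec, "associations.tsv")
  tsv(synthetic_proxy_table(truth), "proxies.tsv")
  tsv(synthetic_variant_table(truth), "variants.tsv")
  tsv(data.frame(individual_id = rownames(geno$dosages), geno$dosages,
                 check.names = FALSE), "dosages.tsv")
  write_minimal_vcf(geno$dosages, synthetic_variant_table(truth),
                    file.path(dir, "genotypes.vcf"))
  csv(phen$phenotypes, "phenotypes.csv")
  csv(phen$code_events, "code_events.csv")
  csv(phen$code_map, "phecode_map.csv")
  jsonlite::write_json(
    list(K_true = truth$K_true, seed = truth$seed,
         W_true = truth$W_true, H_true = truth$H_true,
         effect_sign = as.list(truth$effect_sign),
         trait_cluster = as.list(truth$trait_cluster),
         variant_cluster = as.list(truth$variant_cluster)),
    file.path(dir, "truth.json"), digits = NA)
  invisible(list(truth = truth, records = rec, genotypes = geno,
                 phenotypes = phen))
}

# Minimal VCF with GT-only genotype fields, one sample column per
# individual; dosage d becomes 0/0, 0/1 or 1/1.
write_minimal_vcf <- function(dosages, variants, path) {
  gt <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(dosages)), collapse = "\t"))
  m <- match(colnames(dosages), variants$rsid)
  body <- vapply(seq_len(ncol(dosages)), function(j) {
    calls <- ifelse(is.na(dosages[, j]), "./.", gt[dosages[, j] + 1L])
    paste(c(variants$chrom[m[j]], variants$pos[m[j]], colnames(dosages)[j],
            variants$other_allele[m[j]], variants$effect_allele[m[j]],
            ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
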