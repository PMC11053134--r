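records_fixture <- function() {
  data.frame(
    proxy_rsid = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    trait = "Serum urate",
    B = c(0.5, -0.4, 0.3, 0.2, 0.6, 0.7),
    SE = 0.05,
    p = 1e-20,
    n = c(5000, 99, 5000, 5000, 5000, 5000),
    gender_specific = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    study_id = "GCST1",
    stringsAsFactors = FALSE
  )
}

test_that("filter rules fire in order and are logged", {
  r <- records_fixture()
  out <- filter_associations(r, min_variants_per_trait = 1)
  expect_equal(out$log[["low_n"]], 1)          # the n = 99 record
  expect_equal(out$log[["gender_specific"]], 1)
  expect_equal(out$log[["kept"]], 4)
  expect_false("rs2" %in% out$records$proxy_rsid)
  expect_false("rs3" %in% out$records$proxy_rsid)

  # trait pattern and p threshold
  r2 <- records_fixture()
  r2$trait[1] <- "Chronic kidney disease stage 3"
  r2$p[4] <- 1e-6  # boundary: p >= threshold is removed
  out2 <- filter_associations(r2, min_variants_per_trait = 1)
  expect_equal(out2$log[["excluded_trait"]], 1)
  expect_equal(out2$log[["p_threshold"]], 1)

  # trait-level support counted after the record-level rules: 4 variants left
  out3 <- filter_associations(records_fixture(), min_variants_per_trait = 4)
  expect_equal(out3$log[["few_variants"]], 0)
  expect_error(filter_associations(records_fixture(),
                                   min_variants_per_trait = 5),
               "no data after filtering")
})

test_that("filtering an empty set returns empty output with zero counts", {
  out <- filter_associations(records_fixture()[0, ])
  expect_equal(nrow(out$records), 0)
  expect_true(all(out$log == 0))
})

test_that("filtering is idempotent", {
  tr <- generate_truth(3, 18, 36, seed = 6)
  rec <- generate_association_records(tr, n_decoys = 7, seed = 6)
  once <- filter_associations(rec)
  twice <- filter_associations(once$records)
  expect_equal(twice$records, once$records)
  expect_equal(twice$log[["kept"]], once$log[["kept"]])
  expect_true(all(twice$log[names(twice$log) != "kept"] == 0))
})

test_that("standardize_effects divides B by SE and preserves sign", {
  r <- data.frame(proxy_rsid = "rs1", trait = "t",
                  B = c(0.1, 0, -1.2), SE = c(0.05, 1, 0.4))
  s <- standardize_effects(r)
  expect_equal(s$beta_std, c(2, 0, -3))
  r$SE[2] <- 0
  expect_error(standardize_effects(r), "record")
})

test_that("align_to_lead applies the r2 cutoff, sign flips and the max rule", {
  variants <- data.frame(rsid = "rs_lead", chrom = "1", pos = 100,
                         effect_allele = "A", other_allele = "G",
                         kidney_decreasing_allele = "A")
  proxies <- data.frame(lead_rsid = "rs_lead",
                        proxy_rsid = c("rs_lead", "rs_p1", "rs_p2"),
                        r2 = c(1, 0.59, 0.8))
  rec <- standardize_effects(data.frame(
    proxy_rsid = c("rs_lead", "rs_p1", "rs_p2"),
    trait = "t", B = c(0.21, 0.5, 0.34), SE = 0.1, p = c(1e-9, 1e-30, 1e-12),
    effect_allele = "A", stringsAsFactors = FALSE))

  al <- align_to_lead(rec, proxies, variants)
  # r2 = 0.59 proxy dropped; among |beta| 2.1 and 3.4 the 3.4 record wins
  expect_equal(nrow(al), 1)
  expect_equal(al$proxy_rsid, "rs_p2")
  expect_equal(al$beta_std, 3.4)

  # identity proxy, effect allele == kidney-decreasing allele: sign unchanged
  one <- align_to_lead(rec[1, ], proxies, variants)
  expect_equal(one$beta_std, 2.1)

  # record reported on the other allele is flipped
  flip <- rec[1, ]
  flip$effect_allele <- "G"
  expect_equal(align_to_lead(flip, proxies, variants)$beta_std, -2.1)

  # neither allele matches -> skipped with log entry
  bad <- rec[1, ]
  bad$effect_allele <- "T"
  aligned <- align_to_lead(bad, proxies, variants)
  expect_equal(nrow(aligned), 0)
  expect_equal(attr(aligned, "alignment")[["allele_unresolvable"]], 1)

  # proxy pointing at an unknown lead warns and skips
  p2 <- data.frame(lead_rsid = "rs_missing", proxy_rsid = "rs_p2", r2 = 0.9)
  expect_warning(align_to_lead(rec, rbind(proxies, p2), variants),
                 "unknown lead")
})

test_that("build_matrix splits traits by direction and stays non-negative", {
  rec <- data.frame(lead_rsid = c("rs1", "rs2"), trait = "t",
                    beta_std = c(2, -3))
  X <- build_matrix(rec)
  expect_equal(unname(X$values["t|+", ]), c(2, 0))
  expect_equal(unname(X$values["t|-", ]), c(0, 3))

  rec_pos <- data.frame(lead_rsid = c("rs1", "rs2"), trait = "t",
                        beta_std = c(2, 3))
  X2 <- build_matrix(rec_pos)
  expect_equal(rownames(X2$values), "t|+")
  expect_true(min(X2$values) >= 0)
})

test_that("noiseless all-positive records reproduce W_true * H_true", {
  tr <- generate_truth(3, 15, 30, seed = 12)
  tr$effect_sign[] <- 1
  rec <- generate_association_records(tr, noise_sd = 0, seed = 12)
  al <- align_to_lead(standardize_effects(rec), synthetic_proxy_table(tr),
                      synthetic_variant_table(tr))
  X <- build_matrix(al)
  S <- tr$W_true %*% tr$H_true
  expect_equal(X$values[paste0(rownames(S), "|+"), colnames(S)], S,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("trait feature rows preserve the total absolute effect", {
  tr <- generate_truth(3, 15, 30, seed = 13)
  rec <- filter_associations(
    generate_association_records(tr, noise_sd = 0.2, seed = 13))$records
  al <- align_to_lead(standardize_effects(rec), synthetic_proxy_table(tr),
                      synthetic_variant_table(tr))
  X <- build_matrix(al)
  for (trait in unique(al$trait)) {
    rows <- X$feature_labels$feature[X$feature_labels$trait == trait]
    expect_equal(sum(X$values[rows, , drop = FALSE]),
                 sum(abs(al$beta_std[al$trait == trait])))
  }
})
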