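test_that("generate_truth plants the requested structure deterministically", {
  t1 <- generate_truth(K = 1, n_traits = 3, n_variants = 3, sparsity = 0,
                       seed = 1)
  expect_equal(qr(t1$W_true %*% t1$H_true)$rank, 1)

  t4 <- generate_truth(K = 4, n_traits = 40, n_variants = 80, sparsity = 0.5,
                       seed = 7)
  expect_equal(mean(t4$W_true == 0), 0.5, tolerance = 0.01)
  expect_equal(mean(t4$H_true == 0), 0.5, tolerance = 0.01)
  expect_equal(qr(t4$W_true %*% t4$H_true)$rank, 4)
  expect_true(all(t4$W_true >= 0) && all(t4$H_true >= 0))

  expect_identical(t4, generate_truth(K = 4, n_traits = 40, n_variants = 80,
                                      sparsity = 0.5, seed = 7))
  expect_error(generate_truth(K = 5, n_traits = 3, n_variants = 10),
               "n_traits")
})

test_that("association records encode the planted signal and B = beta * SE", {
  tr <- generate_truth(3, 12, 24, seed = 2)
  tr$effect_sign[] <- 1
  rec <- generate_association_records(tr, noise_sd = 0, seed = 3)
  S <- tr$W_true %*% tr$H_true
  expect_equal(rec$B / rec$SE,
               S[cbind(match(rec$trait, rownames(S)),
                       match(rec$proxy_rsid, colnames(S)))],
               tolerance = 1e-12)
  expect_equal(rec$p, 2 * pnorm(-abs(rec$B / rec$SE)))
  expect_true(all(rec$SE > 0))
})

test_that("decoy records fail the filter and genuine records survive", {
  tr <- generate_truth(3, 18, 36, seed = 4)
  rec <- generate_association_records(tr, noise_sd = 0.05, n_decoys = 5,
                                      seed = 4)
  expect_equal(sum(!is.na(rec$decoy_rule)), 5)
  out <- filter_associations(rec)
  expect_true(all(is.na(out$records$decoy_rule)))
  expect_equal(nrow(out$records), sum(is.na(rec$decoy_rule)))
  planted <- table(factor(rec$decoy_rule,
                          levels = setdiff(names(out$log), "kept")))
  expect_equal(out$log[names(planted)], as.vector(planted),
               ignore_attr = TRUE)
})

test_that("genotypes follow Hardy-Weinberg proportions within groups", {
  g <- generate_genotypes(4000, 50,
                          groups = list(list(label = "P", fraction = 1,
                                             maf_range = c(0.5, 0.5))),
                          seed = 9)
  expect_equal(mean(g$dosages), 1, tolerance = 0.02)
  props <- table(g$dosages) / length(g$dosages)
  expect_equal(as.vector(props), c(0.25, 0.5, 0.25), tolerance = 0.02)

  # maf -> 0 limit: dosages almost surely all zero
  g0 <- generate_genotypes(50, 20,
                           groups = list(list(label = "P", fraction = 1,
                                              maf_range = c(1e-9, 1e-9))),
                           seed = 9)
  expect_true(all(g0$dosages == 0))
  expect_error(generate_genotypes(10, 5,
                                  groups = list(list(label = "P",
                                                     fraction = 0.5,
                                                     maf_range = c(0.1, 0.2)))),
               "sum to 1")
})

test_that("two groups with disjoint allele frequencies separate on PCA", {
  g <- generate_genotypes(1000, 500, groups = list(
    list(label = "A", fraction = 0.5, maf_range = c(0.05, 0.15)),
    list(label = "B", fraction = 0.5, maf_range = c(0.35, 0.5))), seed = 11)
  pc <- dosage_pca(g$dosages)
  sc <- pc$scores[, 1]
  cent <- tapply(sc, g$group, mean)
  pred <- names(cent)[max.col(-abs(outer(sc, cent, "-")))]
  expect_gt(mean(pred == g$group), 0.95)
})

test_that("phenotypes hit the liability prevalence and the h2 -> 1 limit", {
  tr <- generate_truth(2, 8, 16, seed = 5)
  g <- generate_genotypes(5000, 16, seed = 5)
  ph <- generate_phenotypes(g$dosages, tr, h2 = 0.999, prevalence = 0.2,
                            seed = 5)
  z <- scale(ph$true_scores)
  eff <- tr$pheno_effects
  gval <- as.vector(z %*% eff[, "quant_1"])
  expect_gt(cor(ph$phenotypes$quant_1, gval), 0.99)

  frac <- colMeans(ph$case_status)
  ci <- 2.576 * sqrt(0.2 * 0.8 / 5000)
  expect_true(all(abs(frac - 0.2) < ci + 0.01))

  # cases carry >= 2 code events; some non-cases carry exactly 1
  counts <- table(ph$code_events$individual_id, ph$code_events$code)
  expect_true(any(counts == 1))
  case_ids <- rownames(ph$case_status)[ph$case_status[, "bin_1"]]
  expect_true(all(counts[intersect(case_ids, rownames(counts)), "ICD_01"] >= 2))
})

test_that("generators are pure functions of their seed", {
  tr <- generate_truth(3, 12, 24, seed = 8)
  expect_identical(generate_association_records(tr, seed = 2),
                   generate_association_records(tr, seed = 2))
  expect_identical(generate_genotypes(50, 30, seed = 2),
                   generate_genotypes(50, 30, seed = 2))
  g <- generate_genotypes(50, 24, seed = 2)
  expect_identical(generate_phenotypes(g$dosages, tr, seed = 3),
                   generate_phenotypes(g$dosages, tr, seed = 3))
})
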