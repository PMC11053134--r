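test_that("the Phecode rule needs two events, one event excludes", {
  ev <- data.frame(individual_id = c("a", "a", "b", "d", "d", "d"),
                   code = c("ICD_01", "ICD_01", "ICD_01", "ICD_01",
                            "ICD_02", "ICD_02"))
  map <- data.frame(code = c("ICD_01", "ICD_02"),
                    phecode = c("PHE_01", "PHE_02"))
  st <- map_phecodes(ev, map, individuals = c("a", "b", "c", "d"))
  expect_equal(st["a", "PHE_01"], "case")
  expect_equal(st["b", "PHE_01"], "excluded")
  expect_equal(st["c", "PHE_01"], "control")
  expect_equal(st["d", "PHE_02"], "case")
  expect_equal(st["d", "PHE_01"], "excluded")

  ev2 <- rbind(ev, data.frame(individual_id = "a", code = "UNKNOWN"))
  st2 <- map_phecodes(ev2, map, individuals = c("a", "b", "c", "d"))
  expect_equal(attr(st2, "unmapped"), 1)
})

test_that("the Bonferroni alpha follows the family size", {
  expect_equal(signif(compute_alpha(9, 988, 832, 0.05), 2), 3.1e-06)
  expect_equal(compute_alpha(1, 1, 0, 0.05), 0.05)
  expect_equal(compute_alpha(2, 5, 5, 0.05), 2.5e-03)
  expect_error(compute_alpha(0, 0, 0), "positive")
})

make_phewas_cohort <- function(n = 1500, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("i%04d", 1:n), "c1"))
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 20, 80),
                    row.names = rownames(z))
  list(z = z, cov = cov)
}

test_that("planted quantitative effects are recovered on the standardized scale", {
  ch <- make_phewas_cohort(5000, seed = 3)
  y <- 0.3 * ch$z[, 1] + rnorm(5000, 0, sqrt(0.91))
  qt <- data.frame(planted = y, row.names = rownames(ch$z))
  res <- run_phewas(ch$z, quantitative = qt, covariates = ch$cov,
                    alpha = 1e-4)
  expect_equal(res$estimate, 0.3, tolerance = 0.2)
  expect_true(res$estimate > 0.25 && res$estimate < 0.35)
  expect_true(res$significant)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("covariate-free standardized beta equals the Pearson correlation", {
  ch <- make_phewas_cohort(400, seed = 5)
  y <- 0.4 * ch$z[, 1] + rnorm(400)
  qt <- data.frame(y = y, row.names = rownames(ch$z))
  res <- run_phewas(ch$z, quantitative = qt,
                    covariates = data.frame(row.names = rownames(ch$z)),
                    min_n = 100, alpha = 0.05)
  expect_equal(res$estimate, cor(y, ch$z[, 1]), tolerance = 1e-8)
})

test_that("logistic OR matches the contingency-table odds ratio", {
  set.seed(11)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  pr <- plogis(-1 + 0.8 * x)
  y <- rbinom(n, 1, pr)
  ids <- sprintf("i%04d", 1:n)
  # a binary exposure fed in as the "score": OR must equal ad/bc after
  # undoing the score standardization
  zx <- matrix(x, n, 1, dimnames = list(ids, "c1"))
  bn <- matrix(ifelse(y == 1, "case", "control"), n, 1,
               dimnames = list(ids, "d1"))
  res <- run_phewas(zx, binary = bn,
                    covariates = data.frame(row.names = ids),
                    min_n = 100, alpha = 0.05)
  tab <- table(x, y)
  or_tab <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
  # reported OR is per 1 SD of the exposure
  expect_equal(res$estimate^(1 / sd(x)), or_tab, tolerance = 1e-6)
})

test_that("thin traits are skipped and alpha is recomputed from the family", {
  ch <- make_phewas_cohort(300, seed = 7)
  qt <- data.frame(ok = rnorm(300),
                   thin = c(rnorm(99), rep(NA, 201)),
                   row.names = rownames(ch$z))
  bn <- matrix("control", 300, 1, dimnames = list(rownames(ch$z), "rare"))
  bn[1:10, 1] <- "case"  # 10 cases < min_cases
  res <- run_phewas(ch$z, quantitative = qt, binary = bn,
                    covariates = ch$cov, min_n = 100)
  expect_equal(sort(attr(res, "skipped")), c("rare", "thin"))
  expect_equal(unique(res$trait), "ok")
  expect_equal(attr(res, "alpha"), compute_alpha(1, 1, 0, 0.05))
})

test_that("type-I error is nominal under the null", {
  ch <- make_phewas_cohort(500, seed = 9)
  set.seed(10)
  qt <- as.data.frame(matrix(rnorm(500 * 200), 500, 200))
  rownames(qt) <- rownames(ch$z)
  res <- run_phewas(ch$z, quantitative = qt, covariates = ch$cov,
                    min_n = 100, alpha = 0.05)
  rate <- mean(res$p < 0.05)
  ci <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), ci)
})

test_that("top-trait validation requires significance and sign agreement", {
  pw <- data.frame(cluster_id = "c1",
                   trait = c("tA", "tB", "tC"),
                   trait_type = c("quantitative", "quantitative", "binary"),
                   estimate = c(0.1, 0.1, 0.8), p = c(1e-9, 0.5, 1e-9),
                   significant = c(TRUE, FALSE, TRUE))
  top <- data.frame(cluster_id = "c1",
                    trait = c("tA", "tB", "matrixC"),
                    direction = c("+", "+", "+"))
  syn <- data.frame(trait = "matrixC", phewas_trait = "tC")
  v <- validate_top_traits(pw, top, synonym_map = syn)
  expect_true(v$validated[1])    # significant, sign agrees
  expect_false(v$validated[2])   # not significant
  expect_false(v$validated[3])   # OR 0.8 -> negative log-OR vs "+"
  expect_equal(attr(v, "summary")$validated, 1)
})

test_that("planted cluster-phenotype links validate end to end", {
  tr <- generate_truth(3, 12, 30, seed = 19)
  g <- generate_genotypes(2500, 30, seed = 19)
  ph <- generate_phenotypes(g$dosages, tr, h2 = 0.3, prevalence = 0.15,
                            seed = 19)
  z <- standardize_cpgs(compute_cpgs(g$dosages, tr$H_true))
  qt <- ph$phenotypes[, grep("^q", names(ph$phenotypes))]
  rownames(qt) <- ph$phenotypes$individual_id
  cov <- ph$phenotypes[, c("sex", "age")]
  rownames(cov) <- ph$phenotypes$individual_id
  res <- run_phewas(z, quantitative = qt, covariates = cov, min_n = 100)
  top <- data.frame(cluster_id = rep(rownames(tr$H_true), 2),
                    trait = c(sprintf("quant_%d", 1:3),
                              sprintf("qnull_%d", 1:3)),
                    direction = "+")
  v <- validate_top_traits(res, top)
  expect_true(all(v$validated[1:3]))   # planted links confirmed
  expect_false(any(v$validated[4:6]))  # null phenotypes do not validate
})
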