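test_that("monomorphic or infeasible variant specs are rejected", {
  expect_error(simulate_genotypes(10, data.frame(maf = 0)), "monomorphic")
  # r2 = 1 is unattainable for unequal MAFs
  expect_error(simulate_genotypes(10, data.frame(
    maf = c(0.1, 0.4), ld_partner = c(NA, 1), ld_r2 = c(NA, 1))),
    "infeasible")
  expect_error(simulate_genotypes(10, data.frame(
    maf = c(0.3, 0.3), ld_partner = c(2, NA), ld_r2 = c(0.5, NA))),
    "earlier")
})

test_that("large-sample genotypes match HWE proportions and the target MAF", {
  gm <- simulate_genotypes(50000, data.frame(maf = 0.3), seed = 101)
  g <- gm$dosages[, 1]
  expect_lt(abs(mean(g) / 2 - 0.3), 0.005)
  counts <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- mean(g) / 2
  expected <- 50000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expected)^2 / expected)
  expect_gt(pchisq(chi2, df = 1, lower.tail = FALSE), 0.001)
})

test_that("perfect LD with equal MAFs duplicates the dosage column", {
  gm <- simulate_genotypes(2000, data.frame(
    maf = c(0.25, 0.25), ld_partner = c(NA, 1), ld_r2 = c(NA, 1)),
    seed = 5)
  expect_identical(gm$dosages[, 1], gm$dosages[, 2])
})

test_that("simulated LD pairs hit the target r-squared in expectation", {
  gm <- simulate_genotypes(50000, data.frame(
    maf = c(0.3, 0.3), ld_partner = c(NA, 1), ld_r2 = c(NA, 0.5)),
    seed = 7)
  r2 <- ld_r2(gm$dosages[, 1], gm$dosages[, 2])
  expect_lt(abs(as.numeric(r2) - 0.5), 0.03)
  # independent variants have near-zero r2
  gm0 <- simulate_genotypes(50000, data.frame(maf = c(0.3, 0.2)), seed = 8)
  expect_lt(as.numeric(ld_r2(gm0$dosages[, 1], gm0$dosages[, 2])), 0.01)
})

test_that("identical seeds reproduce identical cohorts", {
  vs <- data.frame(maf = c(0.1, 0.3), missing_rate = c(0.02, 0))
  a <- simulate_genotypes(500, vs, seed = 42)
  b <- simulate_genotypes(500, vs, seed = 42)
  expect_identical(a, b)
  ca <- simulate_covariates(200, seed = 9)
  cb <- simulate_covariates(200, seed = 9)
  expect_identical(ca, cb)
})

test_that("null penetrance model reproduces the baseline prevalence", {
  gm <- simulate_genotypes(50000, data.frame(maf = c(0.3, 0.2)), seed = 12)
  spec <- penetrance_spec(c("SNP1", "SNP2"), baseline_logit = qlogis(0.03))
  ph <- simulate_gdm(gm, spec, seed = 13)
  expect_lt(abs(mean(ph$gdm_status) - 0.03), 0.005)
})

test_that("a planted per-allele OR of 1.5 is recovered by logistic regression", {
  gm <- simulate_genotypes(100000, data.frame(maf = 0.3), seed = 21)
  spec <- penetrance_spec("SNP1", baseline_logit = qlogis(0.05),
                          per_allele_logits = c(SNP1 = log(1.5)))
  ph <- simulate_gdm(gm, spec, seed = 22)
  fit <- single_snp_logistic(gm$dosages[, 1], ph$gdm_status)
  expect_gt(fit$or_value, 1.4)
  expect_lt(fit$or_value, 1.6)
})

test_that("pure epistasis leaves marginal ORs near 1 but separates cells", {
  gm <- simulate_genotypes(60000, data.frame(maf = c(0.5, 0.5)), seed = 31)
  spec <- penetrance_spec(
    c("SNP1", "SNP2"), baseline_logit = qlogis(0.05),
    epistasis_terms = data.frame(snp_i = "SNP1", snp_j = "SNP2", logit = 2))
  ph <- simulate_gdm(gm, spec, seed = 32)
  for (j in 1:2) {
    fit <- single_snp_logistic(gm$dosages[, j], ph$gdm_status)
    expect_gt(fit$or_value, 0.9)
    expect_lt(fit$or_value, 1.1)
  }
  # analytic penetrance differs across two-locus cells as planted
  cellmeans <- tapply(ph$gdm_status,
                      list(gm$dosages[, 1], gm$dosages[, 2]), mean)
  expect_gt(cellmeans["0", "0"], 2 * cellmeans["1", "1"])
  expect_gt(cellmeans["2", "2"], 2 * cellmeans["1", "1"])
  expect_lt(cellmeans["0", "2"], cellmeans["1", "1"])
})

test_that("null lifestyle spec makes T2DM independent of the PRS", {
  set.seed(41)
  prs <- rbinom(30000, 10, 0.3)
  lifestyle <- data.frame(diet_high = rbinom(30000, 1, 0.3),
                          breastfeeding_years = rexp(30000, 1))
  y <- simulate_t2dm(prs, lifestyle, lifestyle_effect_spec(), seed = 42)
  expect_lt(abs(mean(y) - 0.076), 0.01)
  cat3 <- categorize_prs(prs)
  res <- prs_association(cat3, y)
  expect_gt(res$or_value[res$category == "High"], 0.85)
  expect_lt(res$or_value[res$category == "High"], 1.15)
})

test_that("a protective breastfeeding effect is recovered in direction", {
  set.seed(51)
  n <- 40000
  prs <- rbinom(n, 10, 0.3)
  lifestyle <- data.frame(breastfeeding_years = round(rexp(n, 1), 1))
  spec <- lifestyle_effect_spec(breastfeeding_logit = log(0.887))
  y <- simulate_t2dm(prs, lifestyle, spec, seed = 52)
  long <- as.integer(lifestyle$breastfeeding_years >= 1)
  fit <- glm(y ~ long, family = binomial())
  expect_lt(exp(coef(fit)["long"]), 1)
})

test_that("ffq intakes are non-negative and reproduce planted structure", {
  L <- matrix(0, 29, 1)
  L[1:10, 1] <- 1.5
  x <- simulate_ffq(500, L, noise_sd = 0.5, seed = 61)
  expect_true(all(x >= 0))
  expect_identical(dim(x), c(500L, 29L))
  # noiseless-limit check: one factor explains nearly all variance
  x2 <- simulate_ffq(500, L, noise_sd = 1e-4, seed = 62)
  ev <- eigen(cor(x2[, 1:10]))$values
  expect_gt(ev[1] / sum(ev), 0.99)
})
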