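test_that("intercept-only score residuals follow the closed form", {
  y <- c(rep(1, 30), rep(0, 70))
  s <- compute_score_residuals(y)
  expect_equal(unique(s[y == 1]), 0.7)
  expect_equal(unique(s[y == 0]), -0.3)
  expect_equal(sum(s), 0, tolerance = 1e-10)
})

test_that("covariate-adjusted scores sum to zero and match strata", {
  set.seed(7)
  x <- rbinom(200, 1, 0.5)
  y <- rbinom(200, 1, plogis(-1 + 0.8 * x))
  s <- compute_score_residuals(y, data.frame(x = factor(x)))
  expect_equal(sum(s), 0, tolerance = 1e-6)
  # single binary covariate: fitted p equals the stratum prevalence
  for (v in 0:1) {
    expect_equal(unique(round(y[x == v] - s[x == v], 10)),
                 round(mean(y[x == v]), 10))
  }
})

test_that("a perfectly separating single SNP yields training BA 1", {
  dos <- matrix(c(rep(2L, 10), rep(0L, 10)), ncol = 1)
  gm <- genotype_matrix(dos, data.frame(
    id = "S", chrom = "1", pos = 1L, minor_allele = "A", major_allele = "G"))
  y <- c(rep(1, 10), rep(0, 10))
  s <- compute_score_residuals(y)
  r <- evaluate_model("S", s, y, gm, train_idx = 1:20, test_idx = integer(0))
  expect_equal(r$train_ba, 1.0)
  expect_identical(r$cell_labels$label[r$cell_labels$S == 2], "high")
  expect_identical(r$cell_labels$label[r$cell_labels$S == 0], "low")
})

test_that("a 12-subject two-SNP instance matches exhaustive cell enumeration", {
  dos <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L,
                  0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L, 0L, 1L, 2L),
                ncol = 2)
  gm <- genotype_matrix(dos, data.frame(
    id = c("A", "B"), chrom = "1", pos = c(1L, 2L),
    minor_allele = "A", major_allele = "G"))
  y <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 1, 0)
  s <- compute_score_residuals(y)
  tr <- 1:8
  te <- 9:12
  mine <- evaluate_model(c("A", "B"), s, y, gm, tr, te)
  oracle <- oracle_gmdr_ba(dos, s, y, tr, te)
  expect_equal(mine$train_ba, oracle$train_ba, tolerance = 1e-12)
  expect_equal(mine$test_ba, oracle$test_ba, tolerance = 1e-12)
})

test_that("permuted outcomes give test balanced accuracy near one half", {
  set.seed(55)
  gm <- simulate_genotypes(2000, data.frame(maf = c(0.3, 0.4)), seed = 56)
  y <- rbinom(2000, 1, 0.3)
  s <- compute_score_residuals(y)
  tr <- 1:1500
  te <- 1501:2000
  bas <- replicate(100, {
    yp <- sample(y)
    sp <- compute_score_residuals(yp)
    evaluate_model(c("SNP1", "SNP2"), sp, yp, gm, tr, te)$test_ba
  })
  expect_lt(abs(mean(bas) - 0.5), 0.05)
})

test_that("sign test reproduces the binomial upper tail", {
  expect_equal(sign_test(10, 10), 1 / 1024, tolerance = 1e-12)
  expect_equal(sign_test(0, 10), 1, tolerance = 1e-12)
  # monotone decreasing in the statistic
  p <- vapply(0:10, sign_test, numeric(1), n_folds = 10)
  expect_true(all(diff(p) < 0))
})

test_that("search is deterministic under a fixed seed and optimism is monotone", {
  gm <- simulate_genotypes(1000, data.frame(maf = rep(0.3, 5)), seed = 66)
  y <- rbinom(1000, 1, 0.15)
  s <- compute_score_residuals(y)
  a <- run_gmdr_search(gm$variants$id, s, y, gm, k_range = 1:3,
                       n_folds = 5, seed = 99)
  b <- run_gmdr_search(gm$variants$id, s, y, gm, k_range = 1:3,
                       n_folds = 5, seed = 99)
  expect_identical(a, b)
  # best-of-size training BA can only improve with model size
  expect_true(all(diff(a$trba) >= -1e-12))
})

test_that("oversized models are rejected", {
  gm <- simulate_genotypes(100, data.frame(maf = c(0.3, 0.3)), seed = 3)
  y <- rbinom(100, 1, 0.4)
  s <- compute_score_residuals(y)
  expect_error(run_gmdr_search(gm$variants$id, s, y, gm, k_range = 1:3),
               "exceeds")
})

test_that("a strong planted pair is found with full consistency", {
  gm <- simulate_genotypes(4000, data.frame(maf = rep(0.5, 4)), seed = 71)
  spec <- penetrance_spec(
    c("SNP1", "SNP2"), baseline_logit = qlogis(0.05),
    epistasis_terms = data.frame(snp_i = "SNP1", snp_j = "SNP2", logit = 3))
  ph <- simulate_gdm(gm, spec, seed = 72)
  s <- compute_score_residuals(ph$gdm_status)
  res <- run_gmdr_search(gm$variants$id, s, ph$gdm_status, gm,
                         k_range = 2, n_folds = 10, seed = 73)
  expect_setequal(strsplit(res$snp_ids, ",")[[1]], c("SNP1", "SNP2"))
  expect_identical(res$cvc, 10L)
  expect_lte(res$sign_p, sign_test(9, 10))
})
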