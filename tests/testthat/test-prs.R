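test_that("risk-allele counting follows the TT/GT/GG = 0/1/2 convention", {
  expect_identical(count_risk_alleles("TT", "G"), 0L)
  expect_identical(count_risk_alleles("GT", "G"), 1L)
  expect_identical(count_risk_alleles("GG", "G"), 2L)
  expect_identical(count_risk_alleles(c("T", "G"), "G"), 1L)
  expect_identical(count_risk_alleles(NA_character_, "G"), NA_integer_)
})

make_gm5 <- function(dosages) {
  genotype_matrix(dosages, data.frame(
    id = paste0("rs", 1:5), chrom = as.character(1:5),
    pos = 1:5 * 100L, minor_allele = "G", major_allele = "T"))
}

test_that("PRS sums risk alleles and respects orientation", {
  dos <- rbind(c(0L, 0L, 0L, 0L, 0L),
               c(2L, 2L, 2L, 2L, 2L),
               c(2L, 1L, 0L, 1L, 2L))
  gm <- make_gm5(dos)
  model <- data.frame(id = paste0("rs", 1:5), risk_allele = "G")
  prs <- compute_prs(gm, model)
  expect_identical(prs$prs, c(0L, 10L, 6L))
  # a risk allele on the major side counts 2 - dosage
  model_major <- data.frame(id = "rs1", risk_allele = "T")
  expect_identical(compute_prs(gm, model_major)$prs, c(2L, 0L, 0L))
  # invariant to the order of the model list
  prs_rev <- compute_prs(gm, model[5:1, ])
  expect_identical(prs_rev$prs, prs$prs)
  # all-minor risk alleles reduce to the dosage row sum
  expect_identical(prs$prs, as.integer(rowSums(dos)))
  expect_error(compute_prs(gm, data.frame(id = "rs1", risk_allele = "C")),
               "not an allele")
})

test_that("missing-genotype policies behave as documented", {
  dos <- rbind(c(2L, NA, 0L, 1L, 2L),
               c(1L, 1L, 1L, 1L, 1L))
  gm <- make_gm5(dos)
  model <- data.frame(id = paste0("rs", 1:5), risk_allele = "G")
  excl <- compute_prs(gm, model, missing_policy = "exclude")
  expect_true(is.na(excl$prs[1]))
  expect_identical(excl$prs[2], 5L)
  imp <- compute_prs(gm, model, missing_policy = "mean_impute")
  expect_equal(imp$prs[1], 2 + 1 + 0 + 1 + 2)  # column mean of rs2 is 1
})

test_that("PRS categories partition 0..10 with the fixed cutoffs", {
  cats <- categorize_prs(0:10)
  expect_identical(as.character(cats[c(4, 6, 7)]),  # prs 3, 5, 6
                   c("Low", "Medium", "High"))
  expect_false(anyNA(cats))
  expect_identical(sum(table(cats)), 11L)
  expect_error(categorize_prs(0:10, cutoffs = c(5, 3)), "increasing")
  # tertile mode splits at the empirical thirds
  tert <- categorize_prs(c(rep(0, 30), rep(2, 30), rep(5, 30)),
                         mode = "tertile")
  expect_identical(as.character(unique(tert)), c("Low", "Medium", "High"))
})

test_that("unadjusted category OR equals the contingency cross-product", {
  set.seed(91)
  cats <- factor(sample(c("Low", "High"), 2000, TRUE),
                 levels = c("Low", "Medium", "High"))
  y <- rbinom(2000, 1, ifelse(cats == "High", 0.15, 0.08))
  expect_warning(res <- prs_association(cats, y), "Medium")
  tab <- unname(table(droplevels(cats), y))  # rows Low, High; cols 0, 1
  cpr <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_equal(res$or_value[res$category == "High"], cpr, tolerance = 1e-6)
})

test_that("category association is calibrated under the null", {
  set.seed(93)
  inrange <- 0
  for (i in 1:20) {
    cats <- categorize_prs(rbinom(20000, 10, 0.45))
    y <- rbinom(20000, 1, 0.08)
    res <- prs_association(cats, y)
    or_h <- res$or_value[res$category == "High"]
    if (or_h > 0.9 && or_h < 1.1) inrange <- inrange + 1
  }
  expect_gte(inrange, 16)
})
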