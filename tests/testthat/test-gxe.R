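test_that("a single-stratum analysis reproduces the pooled PRS association", {
  set.seed(101)
  cats <- categorize_prs(rbinom(5000, 10, 0.45))
  y <- rbinom(5000, 1, plogis(-2.4 + 0.1 * as.integer(cats)))
  pooled <- prs_association(cats, y)
  strat <- stratified_association(cats, y, rep("all", 5000))
  expect_equal(strat$or_value, pooled$or_value, tolerance = 1e-10)
  expect_equal(strat$p, pooled$p, tolerance = 1e-10)
})

test_that("an effect planted in one stratum appears only there", {
  set.seed(103)
  n <- 40000
  prs <- rbinom(n, 10, 0.45)
  cats <- categorize_prs(prs)
  strat <- rbinom(n, 1, 0.5)
  beta <- ifelse(strat == 1, 0.35, 0)
  y <- rbinom(n, 1, plogis(-2.6 + beta * (prs - mean(prs))))
  res <- stratified_association(cats, y, strat)
  hi0 <- res$or_value[res$stratum == "0" & res$category == "High"]
  hi1 <- res$or_value[res$stratum == "1" & res$category == "High"]
  expect_gt(hi1, 1.5)
  expect_lt(abs(hi0 - 1), 0.25)
})

test_that("continuous interaction test equals the explicit extra-SS F test", {
  set.seed(107)
  n <- 300
  g <- rbinom(n, 10, 0.4)
  e <- rbinom(n, 1, 0.4)
  x <- rnorm(n)
  y <- 90 + 0.5 * g + 2 * e + 0.4 * g * e + x + rnorm(n, sd = 4)
  p <- interaction_test(y, g, e, covariates = data.frame(x = x),
                        outcome_type = "continuous")
  # normal-equations oracle on explicit design matrices
  ef <- as.numeric(e)
  X0 <- cbind(1, g, ef, x)
  X1 <- cbind(X0, g * ef)
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  f <- ((rss(X0) - rss(X1)) / 1) / (rss(X1) / (n - ncol(X1)))
  expect_equal(attr(p, "statistic"), f, tolerance = 1e-8)
  expect_equal(as.numeric(p), pf(f, 1, n - ncol(X1), lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("binary interaction LRT is calibrated and detects planted effects", {
  set.seed(109)
  rej <- 0
  n_reps <- 200
  for (i in seq_len(n_reps)) {
    n <- 1500
    g <- rbinom(n, 10, 0.4)
    e <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-2 + 0.05 * g + 0.2 * e))
    p <- tryCatch(as.numeric(interaction_test(y, g, e)), error = function(x) NA)
    if (!is.na(p) && p < 0.05) rej <- rej + 1
  }
  # binomial(200, 0.05): central 99.9% range is about 2..20
  expect_gte(rej, 2)
  expect_lte(rej, 21)
  # planted interaction is detected at moderate size
  n <- 20000
  g <- rbinom(n, 10, 0.4)
  e <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-2.5 + log(1.3) * (g - mean(g)) * e))
  expect_lt(as.numeric(interaction_test(y, g, e)), 0.01)
})

test_that("aliased interaction columns are reported as errors", {
  set.seed(111)
  g <- rbinom(200, 1, 0.5)
  e <- g  # stratifier identical to the PRS term
  y <- rbinom(200, 1, 0.3)
  expect_error(interaction_test(y, g, e), "alias")
})

test_that("adjusted means equal raw means under a balanced design", {
  set.seed(113)
  grp <- rep(c("a", "b", "c"), each = 40)
  x <- rep(rnorm(40), 3)  # identical covariate distribution per group
  y <- rnorm(120, mean = c(a = 1, b = 2, c = 3)[grp] + 0.5 * x)
  res <- adjusted_group_means(y, grp, data.frame(x = x))
  raw <- tapply(y, grp, mean)
  expect_equal(res$means$emmean,
               as.numeric(raw[as.character(res$means$group)]),
               tolerance = 1e-8)
})

test_that("identical groups give Tukey p near 1 and planted order is recovered", {
  set.seed(115)
  y1 <- rnorm(200)
  res <- adjusted_group_means(c(y1, y1), rep(c("g1", "g2"), each = 200))
  expect_gt(res$tukey$p.value[1], 0.99)
  # planted ordered means
  grp <- rep(c("lo", "mid", "hi"), each = 3000)
  y <- rnorm(9000, mean = c(lo = 90, mid = 93, hi = 96)[grp], sd = 5)
  res2 <- adjusted_group_means(y, grp)
  m <- setNames(res2$means$emmean, as.character(res2$means$group))
  expect_equal(unname(m[c("lo", "mid", "hi")]), c(90, 93, 96),
               tolerance = 0.5)
  expect_true(all(res2$tukey$p.value < 0.001))
})

test_that("Tukey p-values are invariant to group relabeling", {
  set.seed(117)
  y <- rnorm(300, rep(c(0, 0.3, 0.8), each = 100))
  grp <- rep(c("a", "b", "c"), each = 100)
  res1 <- adjusted_group_means(y, grp)
  relab <- c(a = "z", b = "y", c = "x")[grp]
  res2 <- adjusted_group_means(y, relab)
  expect_equal(sort(res1$tukey$p.value), sort(res2$tukey$p.value),
               tolerance = 1e-10)
})

test_that("crude tests match closed-form chi-square and reject 1 x k tables", {
  p <- crude_group_tests(factor(rep(c("x", "y"), times = c(20, 20))),
                         rep(c("g1", "g2"), 20))
  expect_equal(attr(p, "statistic"), 0)  # balanced 2x2 table
  expect_equal(as.numeric(p), 1)
  v <- rep(c("x", "y"), times = c(40, 40))
  g <- c(rep("g1", 30), rep("g2", 10), rep("g1", 10), rep("g2", 30))
  p2 <- crude_group_tests(factor(v), g)
  expect_equal(attr(p2, "statistic"), 20, tolerance = 1e-12)  # sum (O-E)^2/E
  expect_equal(as.numeric(p2), pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(crude_group_tests(factor(rep("x", 40)),
                                 rep(c("g1", "g2"), 20)), "1 x k")
})

test_that("crude chi-square p-values are uniform under independence", {
  set.seed(119)
  pvals <- replicate(2000, {
    v <- factor(rbinom(200, 1, 0.5))
    g <- rbinom(200, 1, 0.5)
    as.numeric(crude_group_tests(v, g))
  })
  grid <- seq(0.05, 0.95, by = 0.05)
  dev <- max(abs(vapply(grid, function(x) mean(pvals <= x) - x, numeric(1))))
  expect_lt(dev, sqrt(log(2 / 0.001) / (2 * 2000)))
})
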