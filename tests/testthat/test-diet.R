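test_that("food-group aggregation sums member items", {
  mapping <- data.frame(item = c("i1", "i2", "i3", "j1"),
                        group = c("g1", "g1", "g1", "g2"))
  x <- rbind(c(1.0, 2.0, 0.5, 4.0))
  colnames(x) <- c("i1", "i2", "i3", "j1")
  agg <- aggregate_food_groups(x, mapping)
  expect_equal(unname(agg[1, "g1"]), 3.5)
  expect_equal(unname(agg[1, "g2"]), 4.0)
  # zero intakes stay zero; identity mapping is a no-op
  expect_true(all(aggregate_food_groups(x * 0, mapping) == 0))
  ident <- data.frame(item = c("i1", "i2"), group = c("i1", "i2"))
  expect_equal(unname(aggregate_food_groups(x[, 1:2, drop = FALSE], ident)),
               unname(x[, 1:2, drop = FALSE]))
  expect_error(aggregate_food_groups(x, mapping[1:3, ]), "unmapped")
})

test_that("the shipped default mapping covers 106 items in 29 groups", {
  map <- default_food_groups()
  expect_identical(nrow(map), 106L)
  expect_identical(length(unique(map$group)), 29L)
  expect_false(anyDuplicated(map$item) > 0)
})

test_that("planted orthogonal factors are recovered after rotation", {
  L <- matrix(0, 29, 3)
  L[1:9, 1] <- 1.2
  L[10:18, 2] <- 1.2
  L[19:27, 3] <- 1.2
  x <- simulate_ffq(3000, L, noise_sd = 1, seed = 121)
  res <- extract_patterns(x)
  expect_identical(res$n_retained, 3L)
  cong <- match_congruence(res$loadings, L)
  expect_true(all(cong > 0.9))
  # labelling picks out the planted blocks
  lab1 <- res$labels[[which.max(vapply(seq_len(3), function(j)
    tucker_congruence(res$loadings[, j], L[, 1]), numeric(1)))]]
  expect_true(all(lab1 %in% colnames(x)[1:9]))
})

test_that("pure noise intake retains no component at the 1.5 rule", {
  x <- simulate_ffq(4000, matrix(0, 29, 0), noise_sd = 1, seed = 123)
  res <- extract_patterns(x)
  expect_identical(res$n_retained, 0L)
  expect_lt(max(res$all_eigenvalues), 1.5)
})

test_that("varimax of a single retained component is the identity up to sign", {
  L <- matrix(0, 29, 1)
  L[1:12, 1] <- 1.5
  x <- simulate_ffq(2000, L, noise_sd = 1, seed = 125)
  res <- extract_patterns(x)
  expect_identical(res$n_retained, 1L)
  ev <- eigen(cor(x), symmetric = TRUE)
  raw <- ev$vectors[, 1] * sqrt(ev$values[1])
  expect_equal(abs(as.numeric(res$loadings)), abs(raw), tolerance = 1e-8)
})

test_that("rotation preserves communalities and total retained variance", {
  L <- matrix(0, 29, 3)
  L[1:10, 1] <- 1.0
  L[11:20, 2] <- 1.3
  L[21:29, 3] <- 0.9
  x <- simulate_ffq(3000, L, noise_sd = 1, seed = 127)
  res <- extract_patterns(x)
  ev <- eigen(cor(x), symmetric = TRUE)
  k <- res$n_retained
  raw <- ev$vectors[, 1:k] %*% diag(sqrt(ev$values[1:k]))
  expect_equal(unname(rowSums(res$loadings^2)), unname(rowSums(raw^2)),
               tolerance = 1e-8)
  expect_equal(sum(res$loadings^2), sum(ev$values[1:k]), tolerance = 1e-8)
  # rotation matrix is orthonormal
  expect_equal(crossprod(res$rotation), diag(k), tolerance = 1e-8)
})

test_that("score dichotomization follows the interpolated 70th percentile", {
  flags <- dichotomize_scores(1:100)
  expect_identical(which(flags), 71:100)
  expect_identical(sum(dichotomize_scores(rnorm(10))), 3L)
  # rank invariance under strictly increasing transforms
  s <- rnorm(50)
  expect_identical(dichotomize_scores(s), dichotomize_scores(exp(s)))
  expect_warning(f0 <- dichotomize_scores(rep(1, 10)), "constant")
  expect_false(any(f0))
})

test_that("high-intake flags mark about 30 percent of subjects", {
  L <- matrix(0, 29, 2)
  L[1:10, 1] <- 1.2
  L[11:20, 2] <- 1.2
  x <- simulate_ffq(1000, L, noise_sd = 1, seed = 129)
  res <- extract_patterns(x)
  frac <- colMeans(res$high_flags)
  expect_true(all(abs(frac - 0.3) < 0.01))
})

test_that("zero-variance groups are dropped with a warning", {
  x <- simulate_ffq(500, matrix(0, 29, 0), noise_sd = 1, seed = 131)
  x[, 5] <- 7
  expect_warning(res <- extract_patterns(x), "zero-variance")
  expect_identical(nrow(res$loadings), 28L)
})
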