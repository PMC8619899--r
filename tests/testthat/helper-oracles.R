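# Independent oracles used to cross-check the package implementations.
# These deliberately take different computational routes from the package.

# Brute-force GMDR balanced accuracy: dictionary of multilocus cells keyed
# by pasted genotype strings, score sums via tapply.
oracle_gmdr_ba <- function(dosage_subset, scores, outcome, train_idx,
                           test_idx, threshold = 0) {
  dosage_subset <- as.matrix(dosage_subset)
  key <- apply(dosage_subset, 1, paste, collapse = "-")
  complete <- !apply(is.na(dosage_subset), 1, any)
  tr <- intersect(train_idx, which(complete))
  te <- intersect(test_idx, which(complete))
  sums <- tapply(scores[tr], key[tr], sum)
  high <- names(sums)[sums > threshold]
  ba <- function(ix) {
    y <- outcome[ix]
    if (length(unique(y)) < 2) return(NA_real_)
    pred <- key[ix] %in% high
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    (sens + spec) / 2
  }
  list(train_ba = ba(tr), test_ba = ba(te))
}

# Exact HWE p by full enumeration of genotype triples with the observed
# allele counts: P(nAa = h) proportional to n! / (aa! h! bb!) * 2^h.
oracle_hwe_exact <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logw <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  probs <- w / sum(w)
  obs <- probs[match(n_Aa, hets)]
  sum(probs[probs <= obs * (1 + 1e-10)])
}

# Textbook IRLS for logistic regression on an explicit design matrix.
oracle_irls <- function(X, y, tol = 1e-12, max_iter = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  drop(beta)
}

# Tucker congruence between two loading vectors (sign-free).
tucker_congruence <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# Best column-matching congruence of recovered loadings vs planted ones.
match_congruence <- function(recovered, planted) {
  vapply(seq_len(ncol(planted)), function(j) {
    max(vapply(seq_len(ncol(recovered)), function(i) {
      tucker_congruence(recovered[, i], planted[, j])
    }, numeric(1)))
  }, numeric(1))
}

# Small random case-control dataset with genotypes for GMDR checks.
random_gmdr_instance <- function(n, k, seed) {
  set.seed(seed)
  gm <- simulate_genotypes(
    n, data.frame(maf = runif(k + 2, 0.2, 0.5)), seed = seed)
  outcome <- rbinom(n, 1, 0.4)
  if (length(unique(outcome)) < 2) outcome[1:2] <- c(0, 1)
  list(gm = gm, outcome = outcome,
       scores = outcome - mean(outcome))
}
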