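#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' `chi2` is the 1-df goodness-of-fit test against the expected counts
#' n(p^2, 2pq, q^2) with allele frequencies taken from the sample. `exact`
#' is the conditional exact test: with the allele counts fixed, the p-value
#' sums the probabilities of all heterozygote counts no more probable than
#' the observed one. `auto` (default) uses the exact test when the smallest
#' expected genotype count is below 5 and chi-square otherwise.
#'
#' A monomorphic sample admits no test; p = 1 is returned with a
#' `monomorphic` attribute.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (AA = minor homozygote).
#' @param method `"auto"`, `"chi2"` or `"exact"`.
#' @return The p-value, with attribute `statistic` (chi-square only).
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("auto", "chi2", "exact")) {
  method <- match.arg(method)
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes", call. = FALSE)
  n_minor <- 2 * n_AA + n_Aa
  if (n_minor == 0 || n_minor == 2 * n) {
    return(structure(1, monomorphic = TRUE))
  }
  p <- n_minor / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (method == "auto") {
    method <- if (min(expected) < 5) "exact" else "chi2"
  }
  if (method == "chi2") {
    stat <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
    structure(stats::pchisq(stat, df = 1, lower.tail = FALSE),
              statistic = stat)
  } else {
    hwe_exact_p(n_AA, n_Aa, n_aa)
  }
}

# Conditional exact HWE p-value: probabilities over all heterozygote counts
# compatible with the fixed allele totals, via the standard ratio
# recurrence; p sums those no more probable than the observed count.
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- 2 * n_AA + n_Aa
  n_minor <- min(n_minor, 2 * n - n_minor)  # work with the rarer allele
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # unnormalized log-probabilities P(n_Aa = h | allele counts)
  logp <- vapply(hets, function(h) {
    aa <- (n_minor - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(n_minor + 1) -
                      lgamma(2 * n - n_minor + 1))
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

#' Apply per-variant genotype quality-control filters
#'
#' A variant passes when its missing call rate is below
#' `thresholds$missing_rate`, its observed heterozygote fraction is below
#' `thresholds$het_rate`, and its HWE p-value exceeds `thresholds$hwe_p`.
#' Defaults are 4% missingness, 30% heterozygosity, and HWE p > 0.05.
#'
#' @param genotypes A [genotype_matrix()].
#' @param thresholds Named list overriding any of `missing_rate`,
#'   `het_rate`, `hwe_p`; omitted entries keep the defaults.
#' @param hwe_method Passed to [hwe_test()].
#' @return List with `genotypes` (passing variants only) and `report`
#'   (per-variant data frame: missing_rate, het_rate, hwe_p, maf, pass,
#'   reason), plus the thresholds used as an attribute of the report.
#' @export
apply_qc_filters <- function(genotypes, thresholds = list(),
                             hwe_method = "auto") {
  th <- utils::modifyList(
    list(missing_rate = 0.04, het_rate = 0.30, hwe_p = 0.05), thresholds)
  stopifnot(th$missing_rate > 0, th$missing_rate < 1,
            th$het_rate > 0, th$het_rate < 1,
            th$hwe_p > 0, th$hwe_p < 1)
  d <- genotypes$dosages
  missing_rate <- colMeans(is.na(d))
  het_rate <- colMeans(d == 1L, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    as.numeric(hwe_test(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                        sum(g == 0L, na.rm = TRUE), method = hwe_method))
  }, numeric(1))
  reason <- rep(NA_character_, ncol(d))
  reason[hwe_p <= th$hwe_p] <- "hwe_p"
  reason[het_rate >= th$het_rate] <- "het_rate"
  reason[missing_rate >= th$missing_rate] <- "missing_rate"
  pass <- is.na(reason)
  report <- data.frame(
    id = genotypes$variants$id, chrom = genotypes$variants$chrom,
    missing_rate = missing_rate, het_rate = het_rate, hwe_p = hwe_p,
    maf = genotypes$variants$maf, pass = pass, reason = reason,
    stringsAsFactors = FALSE)
  attr(report, "thresholds") <- th
  if (!any(pass)) {
    stop("all variants excluded by QC; nothing to analyse", call. = FALSE)
  }
  list(genotypes = subset_variants(genotypes, which(pass)), report = report)
}
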