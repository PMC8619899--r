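#' Count risk-allele copies in one genotype call
#'
#' The conventional unweighted coding: with G the risk allele, TT, GT and
#' GG score 0, 1 and 2.
#'
#' @param genotype Unordered allele pair: a 2-character string (`"GT"`) or
#'   a length-2 character vector. `NA` propagates.
#' @param risk_allele Single-character risk allele.
#' @return Integer 0, 1 or 2 (NA for a missing call).
#' @export
count_risk_alleles <- function(genotype, risk_allele) {
  if (length(genotype) == 1 && (is.na(genotype) || nchar(genotype) == 2)) {
    if (is.na(genotype)) return(NA_integer_)
    genotype <- strsplit(genotype, "")[[1]]
  }
  stopifnot(length(genotype) == 2, nchar(risk_allele) == 1)
  if (anyNA(genotype)) return(NA_integer_)
  sum(genotype == risk_allele)
}

#' Choose each variant's risk allele from association results
#'
#' The risk allele is the allele with OR > 1 in the minor-allele-dosage
#' association: the minor allele when `or_value > 1`, otherwise the major
#' allele. Orientation is recorded for audit.
#'
#' @param assoc Data frame from [assoc_scan()] (columns `id`, `or_value`).
#' @param genotypes A [genotype_matrix()].
#' @return Data frame `id`, `risk_allele`, `risk_is_minor`, `or_value`.
#' @export
risk_alleles_from_assoc <- function(assoc, genotypes) {
  v <- genotypes$variants[match(assoc$id, genotypes$variants$id), ]
  if (anyNA(v$id)) stop("association results reference unknown variants",
                        call. = FALSE)
  risk_is_minor <- assoc$or_value > 1
  data.frame(id = assoc$id,
             risk_allele = ifelse(risk_is_minor, v$minor_allele,
                                  v$major_allele),
             risk_is_minor = risk_is_minor,
             or_value = assoc$or_value,
             stringsAsFactors = FALSE)
}

#' Unweighted risk-allele polygenic risk score
#'
#' Sums risk-allele copies over the model SNPs; a risk allele that is the
#' major allele contributes `2 - dosage`. Under the default
#' `missing_policy = "exclude"` a subject missing any model genotype gets
#' `NA`; `"mean_impute"` substitutes the cohort mean risk-allele count for
#' the missing SNP (the score is then non-integer).
#'
#' @param genotypes A [genotype_matrix()].
#' @param model_snps Data frame with columns `id` and `risk_allele`, e.g.
#'   from [risk_alleles_from_assoc()] restricted to the best GMDR model.
#' @param missing_policy `"exclude"` or `"mean_impute"`.
#' @return Data frame `subject_id`, `prs` (integer 0..2k under exclude).
#' @export
compute_prs <- function(genotypes, model_snps,
                        missing_policy = c("exclude", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  model_snps <- as.data.frame(model_snps)
  idx <- match(model_snps$id, genotypes$variants$id)
  if (anyNA(idx)) {
    stop("model SNP(s) absent from genotypes: ",
         paste(model_snps$id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  v <- genotypes$variants[idx, ]
  counts <- sapply(seq_along(idx), function(j) {
    d <- genotypes$dosages[, idx[j]]
    ra <- model_snps$risk_allele[j]
    if (ra == v$minor_allele[j]) d
    else if (ra == v$major_allele[j]) 2L - d
    else stop("risk allele '", ra, "' is not an allele of ", v$id[j],
              call. = FALSE)
  })
  counts <- matrix(counts, nrow = nrow(genotypes$dosages))
  if (missing_policy == "mean_impute") {
    for (j in seq_len(ncol(counts))) {
      nas <- is.na(counts[, j])
      if (any(nas)) counts[nas, j] <- mean(counts[, j], na.rm = TRUE)
    }
    prs <- rowSums(counts)
  } else {
    prs <- as.integer(rowSums(counts))  # NA when any genotype is missing
  }
  data.frame(subject_id = rownames(genotypes$dosages), prs = prs,
             stringsAsFactors = FALSE)
}

#' Categorize a PRS into Low / Medium / High groups
#'
#' Default fixed cutoffs follow the 5-SNP convention: <= 3 risk alleles is
#' Low, 4-5 Medium, >= 6 High. `mode = "tertile"` instead splits at the
#' empirical 1/3 and 2/3 quantiles.
#'
#' @param prs Numeric risk-allele counts (NA allowed).
#' @param cutoffs Length-2 increasing numeric `c(low_max, medium_max)`:
#'   Low is `prs <= low_max`, Medium `low_max < prs <= medium_max`, High
#'   above. Ignored for tertile mode.
#' @param mode `"fixed"` or `"tertile"`.
#' @return Factor with levels Low, Medium, High.
#' @export
categorize_prs <- function(prs, cutoffs = c(3, 5), mode = c("fixed", "tertile")) {
  mode <- match.arg(mode)
  if (mode == "tertile") {
    cutoffs <- stats::quantile(prs, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
  }
  if (length(cutoffs) != 2 || !is.numeric(cutoffs) ||
      cutoffs[1] >= cutoffs[2]) {
    stop("cutoffs must be two increasing numbers (low_max, medium_max); ",
         "overlapping or gapped category bounds are not a partition",
         call. = FALSE)
  }
  cut(prs, breaks = c(-Inf, cutoffs, Inf),
      labels = c("Low", "Medium", "High"), right = TRUE)
}

#' PRS-category association with a binary outcome
#'
#' Logistic regression of the outcome on PRS category dummies (Low is the
#' reference) plus covariates; per-category OR with Wald 95% CI.
#'
#' @param categories Factor from [categorize_prs()].
#' @param outcome Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @return Data frame with rows for Medium and High (when present):
#'   `category`, `or_value`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
prs_association <- function(categories, outcome, covariates = NULL) {
  keep <- !is.na(categories) & !is.na(outcome)
  cat_f <- droplevels(factor(categories[keep], levels = c("Low", "Medium", "High")))
  if (!"Low" %in% levels(cat_f) || sum(cat_f == "Low") == 0) {
    stop("Low-PRS reference category is empty", call. = FALSE)
  }
  dropped <- setdiff(c("Medium", "High"), levels(cat_f))
  if (length(dropped)) {
    warning("empty PRS categor(ies) dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  if (nlevels(cat_f) < 2) {
    stop("no non-reference PRS category is populated", call. = FALSE)
  }
  df <- data.frame(.y = outcome[keep], .cat = cat_f)
  if (!is.null(covariates)) {
    df <- cbind(df, as.data.frame(covariates)[keep, , drop = FALSE])
  }
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  cf <- summary(fit)$coefficients
  lev <- setdiff(levels(cat_f), "Low")
  rows <- lapply(lev, function(l) {
    nm <- paste0(".cat", l)
    b <- cf[nm, "Estimate"]
    se <- cf[nm, "Std. Error"]
    data.frame(category = l, or_value = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               p = cf[nm, "Pr(>|z|)"], n = sum(cat_f == l),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
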