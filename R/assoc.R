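#' Covariate-adjusted single-SNP logistic association
#'
#' Fits a maximum-likelihood logistic regression of a binary outcome on the
#' allele dosage (additive 1-df trend coding) plus covariates, by IRLS to
#' convergence tolerance 1e-8. Subjects with a missing dosage are excluded
#' from that variant's fit. The 95% CI is the Wald interval
#' exp(beta +/- 1.96 SE).
#'
#' Complete separation is flagged (infinite CI, `separation = TRUE`) rather
#' than raised as an error.
#'
#' @param dosages Numeric 0/1/2 vector (NA allowed).
#' @param outcome Binary 0/1 vector.
#' @param covariates Optional data frame of covariate columns (numeric or
#'   factor); aliased columns are dropped by the fitter.
#' @param id Variant id used in messages and the result row.
#' @return One-row data frame: `id`, `beta`, `se`, `or_value`, `ci_low`,
#'   `ci_high`, `p_adjusted_model`, `n_used`, `separation`.
#' @export
single_snp_logistic <- function(dosages, outcome, covariates = NULL,
                                id = "variant") {
  keep <- !is.na(dosages) & !is.na(outcome)
  df <- data.frame(.y = outcome[keep], .g = as.numeric(dosages[keep]))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)[keep, , drop = FALSE]
    df <- cbind(df, cv)
  }
  if (length(unique(df$.y)) < 2) {
    stop("outcome has a single class for variant ", id, call. = FALSE)
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("logistic fit did not converge for variant ", id, call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  if (!".g" %in% rownames(cf)) {
    stop("dosage term aliased in the design for variant ", id, call. = FALSE)
  }
  beta <- cf[".g", "Estimate"]
  se <- cf[".g", "Std. Error"]
  if (sep || se > 100) {
    sep <- TRUE
    ci <- c(0, Inf)
  } else {
    ci <- exp(beta + c(-1, 1) * 1.96 * se)
  }
  data.frame(id = id, beta = beta, se = se, or_value = exp(beta),
             ci_low = ci[1], ci_high = ci[2],
             p_adjusted_model = cf[".g", "Pr(>|z|)"],
             n_used = nrow(df), separation = sep,
             stringsAsFactors = FALSE)
}

#' Association scan over all variants of a genotype matrix
#'
#' @param genotypes A [genotype_matrix()].
#' @param outcome Binary 0/1 vector, one per subject.
#' @param covariates Optional covariate data frame.
#' @return Data frame of [single_snp_logistic()] rows, one per variant, in
#'   variant order.
#' @export
assoc_scan <- function(genotypes, outcome, covariates = NULL) {
  rows <- lapply(seq_len(ncol(genotypes$dosages)), function(j) {
    single_snp_logistic(genotypes$dosages[, j], outcome, covariates,
                        id = genotypes$variants$id[j])
  })
  out <- do.call(rbind, rows)
  out$chrom <- genotypes$variants$chrom
  out$pos <- genotypes$variants$pos
  out
}

#' Select candidate variants by association p-value
#'
#' Keeps variants with adjusted p strictly below the threshold, sorted by
#' ascending p (ties by position).
#'
#' @param results Data frame from [assoc_scan()].
#' @param p_threshold Selection threshold (default 1e-4).
#' @return The selected rows, sorted; zero rows (with a warning) when
#'   nothing passes.
#' @export
select_candidates <- function(results, p_threshold = 1e-4) {
  stopifnot(nrow(results) > 0)
  sel <- results[results$p_adjusted_model < p_threshold, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning("no variants pass p < ", p_threshold, call. = FALSE)
    return(sel)
  }
  ord <- order(sel$p_adjusted_model,
               if (!is.null(sel$pos)) sel$pos else seq_len(nrow(sel)))
  sel[ord, , drop = FALSE]
}
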