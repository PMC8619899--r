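#' Stratified PRS-category odds ratios
#'
#' Fits [prs_association()] independently in each stratum of a lifestyle
#' or outcome-history variable, with a common covariate set, yielding the
#' per-stratum Medium- and High- vs Low-PRS odds ratios. A stratum where
#' the fit is degenerate (single outcome class or empty reference) is
#' reported with absent estimates and a warning.
#'
#' @param categories PRS category factor (Low/Medium/High).
#' @param outcome Binary 0/1 vector.
#' @param stratifier Binary or categorical vector defining the strata.
#' @param covariates Optional covariate data frame.
#' @return Data frame: `stratum`, `category`, `or_value`, `ci_low`,
#'   `ci_high`, `p`, `n`.
#' @export
stratified_association <- function(categories, outcome, stratifier,
                                   covariates = NULL) {
  strat <- factor(stratifier)
  rows <- lapply(levels(strat), function(s) {
    ix <- which(strat == s)
    res <- tryCatch(
      prs_association(categories[ix], outcome[ix],
                      if (is.null(covariates)) NULL
                      else as.data.frame(covariates)[ix, , drop = FALSE]),
      error = function(e) {
        warning("stratum '", s, "' degenerate: ", conditionMessage(e),
                call. = FALSE)
        data.frame(category = c("Medium", "High"), or_value = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                   n = NA_integer_, stringsAsFactors = FALSE)
      })
    cbind(stratum = s, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Test a PRS-by-environment interaction term
#'
#' Binary outcomes: logistic model with both main effects, their product
#' term(s) and covariates; the interaction p-value is a likelihood-ratio
#' test of the product term(s) by default (`test = "Wald"` gives the
#' single-coefficient Wald z test and requires a numeric PRS term).
#' Continuous outcomes (glucose, HbA1c): linear model, extra-sum-of-squares
#' F test of the product term(s) (two-way ANCOVA).
#'
#' @param outcome Binary 0/1 or continuous vector.
#' @param prs_term Numeric PRS (risk-allele count) or PRS category factor.
#' @param stratifier Binary/categorical environment variable.
#' @param covariates Optional covariate data frame.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param test `"LRT"` (default) or `"Wald"` for binary outcomes.
#' @return The interaction p-value, with attribute `statistic`.
#' @export
interaction_test <- function(outcome, prs_term, stratifier, covariates = NULL,
                             outcome_type = c("binary", "continuous"),
                             test = c("LRT", "Wald")) {
  outcome_type <- match.arg(outcome_type)
  test <- match.arg(test)
  if (length(unique(stats::na.omit(prs_term))) < 2 ||
      length(unique(stats::na.omit(stratifier))) < 2) {
    stop("both main effects must vary", call. = FALSE)
  }
  df <- data.frame(.y = outcome, .g = prs_term, .e = factor(stratifier))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  full_fml <- .y ~ . + .g:.e
  red_fml <- .y ~ .
  if (outcome_type == "binary") {
    ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
    full <- suppressWarnings(stats::glm(full_fml, data = df,
                                        family = stats::binomial(),
                                        control = ctrl))
    check_interaction_alias(full)
    if (test == "Wald") {
      if (!is.numeric(df$.g)) {
        stop("Wald test requires a numeric PRS term", call. = FALSE)
      }
      cf <- summary(full)$coefficients
      nm <- grep("^\\.g:", rownames(cf), value = TRUE)
      return(structure(cf[nm, "Pr(>|z|)"], statistic = cf[nm, "z value"]))
    }
    red <- suppressWarnings(stats::glm(red_fml, data = df,
                                       family = stats::binomial(),
                                       control = ctrl))
    an <- stats::anova(red, full, test = "LRT")
    structure(an$`Pr(>Chi)`[2], statistic = an$Deviance[2])
  } else {
    full <- stats::lm(full_fml, data = df)
    check_interaction_alias(full)
    red <- stats::lm(red_fml, data = df)
    an <- stats::anova(red, full)
    structure(an$`Pr(>F)`[2], statistic = an$F[2])
  }
}

# Aliased interaction columns make the test meaningless; name them.
check_interaction_alias <- function(fit) {
  cf <- stats::coef(fit)
  inter <- grep("\\.g:\\.e|\\.e.*:\\.g", names(cf))
  if (any(is.na(cf[inter]))) {
    stop("interaction column(s) aliased (collinear with main effects/",
         "covariates): ", paste(names(cf)[inter][is.na(cf[inter])],
                                collapse = ", "), call. = FALSE)
  }
}

#' Covariate-adjusted group means with Tukey pairwise comparisons
#'
#' Least-squares (adjusted) means of a continuous trait per group,
#' evaluated at the covariate grand means, with standard errors and
#' Tukey-HSD pairwise p-values from the studentized-range distribution.
#'
#' @param outcome Continuous vector (e.g. fasting glucose in mg/dL,
#'   HbA1c in percent).
#' @param groups Factor (or interaction of factors) defining the groups.
#' @param covariates Optional covariate data frame.
#' @return List with `means` (group, emmean, se, df) and `tukey`
#'   (contrast, estimate, p).
#' @export
adjusted_group_means <- function(outcome, groups, covariates = NULL) {
  g <- factor(groups)
  small <- names(which(table(g) < 2))
  if (length(small)) {
    warning("group(s) with < 2 subjects excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(g %in% small)
    outcome <- outcome[keep]
    g <- droplevels(g[keep])
    if (!is.null(covariates)) {
      covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
    }
  }
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  df <- data.frame(.y = outcome, .grp = g)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- stats::lm(.y ~ ., data = df)
  emm <- emmeans::emmeans(fit, ".grp")
  means <- as.data.frame(emm)
  names(means)[names(means) == ".grp"] <- "group"
  names(means)[names(means) == "SE"] <- "se"
  pairs_df <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                              adjust = "tukey"))
  list(means = means[, c("group", "emmean", "se", "df")],
       tukey = pairs_df[, c("contrast", "estimate", "p.value")])
}

#' Crude between-group tests for descriptive tables
#'
#' Categorical values: Pearson chi-square test on the group-by-level
#' contingency table. Continuous values: one-way ANOVA F test.
#'
#' @param values Categorical (factor/character) or numeric vector.
#' @param groups Grouping vector.
#' @return The p-value, with attribute `statistic`.
#' @export
crude_group_tests <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.numeric(values)) {
    an <- summary(stats::aov(values ~ g))[[1]]
    structure(an$`Pr(>F)`[1], statistic = an$`F value`[1])
  } else {
    tab <- table(factor(values), g)
    if (nrow(tab) < 2) {
      stop("contingency table has a single value level (1 x k)", call. = FALSE)
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (any(ct$expected <= 0)) {
      stop("expected cell count of zero; chi-square undefined", call. = FALSE)
    }
    structure(unname(ct$p.value), statistic = unname(ct$statistic))
  }
}
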