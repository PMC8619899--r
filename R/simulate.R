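#' Simulate genotypes under Hardy-Weinberg equilibrium with optional LD
#'
#' Independent variants are drawn from the HWE genotype proportions
#' (p^2, 2pq, q^2). A variant with an LD partner is drawn at the haplotype
#' level: two-locus haplotype frequencies are solved from the two MAFs and
#' the target r-squared (D = r * sqrt(pA qA pB qB), positive root), and each
#' of the subject's two haplotypes at the new locus is drawn conditionally
#' on the allele it carries at the partner locus, so the pair hits the
#' target r-squared in expectation.
#'
#' @param n_subjects Number of subjects.
#' @param variant_specs Data frame with one row per variant: `maf`
#'   (required, in (0, 0.5]), and optionally `id`, `chrom`, `pos`,
#'   `ld_partner` (index of an *earlier* variant, NA for independent),
#'   `ld_r2` (target r-squared in [0, 1]), `missing_rate` (fraction of
#'   calls set missing, default 0).
#' @param seed Integer seed; the draw is a pure function of
#'   (`n_subjects`, `variant_specs`, `seed`).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_subjects, variant_specs, seed = 1L) {
  vs <- as.data.frame(variant_specs)
  if (!"maf" %in% names(vs)) stop("variant_specs needs a 'maf' column", call. = FALSE)
  m <- nrow(vs)
  if (!"id" %in% names(vs)) vs$id <- sprintf("SNP%d", seq_len(m))
  if (!"chrom" %in% names(vs)) vs$chrom <- "1"
  if (!"pos" %in% names(vs)) vs$pos <- seq_len(m) * 1000000L
  if (!"ld_partner" %in% names(vs)) vs$ld_partner <- NA_integer_
  if (!"ld_r2" %in% names(vs)) vs$ld_r2 <- NA_real_
  if (!"missing_rate" %in% names(vs)) vs$missing_rate <- 0
  if (any(vs$maf <= 0 | vs$maf > 0.5)) {
    stop("maf must lie in (0, 0.5]; monomorphic variants are not allowed",
         call. = FALSE)
  }
  for (j in which(!is.na(vs$ld_partner))) {
    k <- vs$ld_partner[j]
    if (k >= j) stop("ld_partner must reference an earlier variant", call. = FALSE)
    r2 <- vs$ld_r2[j]
    if (is.na(r2) || r2 < 0 || r2 > 1) {
      stop("ld_r2 must be in [0, 1] for variant ", vs$id[j], call. = FALSE)
    }
    r2max <- max_r2(vs$maf[j], vs$maf[k])
    if (r2 > r2max + 1e-12) {
      stop(sprintf(
        "target r2 %.3f infeasible for MAFs (%.3f, %.3f); maximum is %.3f",
        r2, vs$maf[j], vs$maf[k], r2max), call. = FALSE)
    }
  }
  set.seed(seed)
  # haplotypes carried at each locus: two 0/1 columns per variant
  hap1 <- matrix(0L, n_subjects, m)
  hap2 <- matrix(0L, n_subjects, m)
  for (j in seq_len(m)) {
    p <- vs$maf[j]
    if (is.na(vs$ld_partner[j])) {
      hap1[, j] <- stats::rbinom(n_subjects, 1L, p)
      hap2[, j] <- stats::rbinom(n_subjects, 1L, p)
    } else {
      k <- vs$ld_partner[j]
      q <- vs$maf[k]
      D <- sqrt(vs$ld_r2[j]) * sqrt(p * (1 - p) * q * (1 - q))
      # P(minor at j | partner allele), from haplotype table
      p_given_minor <- (q * p + D) / q
      p_given_major <- ((1 - q) * p - D) / (1 - q)
      p_given_minor <- min(max(p_given_minor, 0), 1)
      p_given_major <- min(max(p_given_major, 0), 1)
      hap1[, j] <- stats::rbinom(n_subjects, 1L,
                                 ifelse(hap1[, k] == 1L, p_given_minor, p_given_major))
      hap2[, j] <- stats::rbinom(n_subjects, 1L,
                                 ifelse(hap2[, k] == 1L, p_given_minor, p_given_major))
    }
  }
  dosages <- hap1 + hap2
  for (j in which(vs$missing_rate > 0)) {
    drop <- stats::runif(n_subjects) < vs$missing_rate[j]
    dosages[drop, j] <- NA_integer_
  }
  rownames(dosages) <- sprintf("S%d", seq_len(n_subjects))
  genotype_matrix(dosages, data.frame(
    id = vs$id, chrom = as.character(vs$chrom), pos = vs$pos,
    minor_allele = if ("minor_allele" %in% names(vs)) vs$minor_allele else "A",
    major_allele = if ("major_allele" %in% names(vs)) vs$major_allele else "G",
    stringsAsFactors = FALSE))
}

# Maximum attainable r^2 between two loci given their MAFs (positive D).
max_r2 <- function(pA, pB) {
  Dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  Dmax^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Planted penetrance model for a binary outcome
#'
#' Describes P(case) on the logit scale: a baseline, additive per-minor-
#' allele effects, SNP-SNP interaction terms, and covariate effects.
#' Interaction terms act on *mean-centered* dosages (g - 2 MAF), so a pure
#' interaction (zero main-effect logits) leaves each SNP's marginal odds
#' ratio at ~1 while the joint penetrance differs across two-locus cells.
#'
#' @param model_snps Character vector of variant ids carrying effects.
#' @param baseline_logit Intercept on the logit scale (e.g. `qlogis(0.03)`
#'   for ~3% prevalence when all effects are centered).
#' @param per_allele_logits Named numeric, log-OR per minor allele; names
#'   must be in `model_snps`. Defaults to all zero.
#' @param epistasis_terms Data frame with columns `snp_i`, `snp_j`, `logit`.
#' @param covariate_logits Named numeric, log-OR per unit of the
#'   (mean-centered) numeric covariate column of the covariate table.
#' @return An object of class `penetrance_spec`.
#' @export
penetrance_spec <- function(model_snps, baseline_logit,
                            per_allele_logits = NULL,
                            epistasis_terms = NULL,
                            covariate_logits = NULL) {
  if (is.null(per_allele_logits)) {
    per_allele_logits <- stats::setNames(rep(0, length(model_snps)), model_snps)
  }
  if (!all(names(per_allele_logits) %in% model_snps)) {
    stop("per_allele_logits names must be in model_snps", call. = FALSE)
  }
  if (!is.null(epistasis_terms)) {
    epistasis_terms <- as.data.frame(epistasis_terms)
    stopifnot(all(c("snp_i", "snp_j", "logit") %in% names(epistasis_terms)))
    snps <- c(epistasis_terms$snp_i, epistasis_terms$snp_j)
    if (!all(snps %in% model_snps)) {
      stop("epistasis_terms reference SNPs outside model_snps", call. = FALSE)
    }
  }
  stopifnot(is.finite(baseline_logit), all(is.finite(per_allele_logits)))
  structure(list(model_snps = model_snps, baseline_logit = baseline_logit,
                 per_allele_logits = per_allele_logits,
                 epistasis_terms = epistasis_terms,
                 covariate_logits = covariate_logits),
            class = "penetrance_spec")
}

#' Simulate covariate and lifestyle variables for a women-only cohort
#'
#' Parametric families with defaults matching a middle-aged hospital-based
#' cohort: age ~ N(53, 5) truncated at 40, age at first pregnancy
#' ~ N(25.2, 3), BMI at age 20 ~ N(20.3, 2.2), education 20/23/57%,
#' income 11/44/45%, ~52% regular exercise, mostly never-smokers, and a
#' right-skewed breastfeeding duration. Fasting glucose and HbA1c are drawn
#' in the non-diabetic range as baseline traits.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return Data frame keyed by `subject_id`.
#' @export
simulate_covariates <- function(n_subjects, seed = 1L) {
  set.seed(seed)
  n <- n_subjects
  data.frame(
    subject_id = sprintf("S%d", seq_len(n)),
    age = pmax(stats::rnorm(n, 53, 5), 40),
    age_first_pregnancy = stats::rnorm(n, 25.2, 3),
    bmi_at_20 = stats::rnorm(n, 20.3, 2.2),
    residence_area = sample(c("urban", "rural"), n, TRUE, c(0.6, 0.4)),
    childbirth = stats::rbinom(n, 1, 0.97),
    education = sample(c("less_than_high_school", "high_school",
                         "college_or_more"), n, TRUE, c(0.20, 0.23, 0.57)),
    income = sample(c("low", "medium", "high"), n, TRUE, c(0.11, 0.44, 0.45)),
    energy_intake = stats::rnorm(n, 99, 8),
    alcohol = sample(c("none", "mild", "moderate"), n, TRUE, c(0.6, 0.3, 0.1)),
    smoking = sample(c("never", "past", "current"), n, TRUE,
                     c(0.97, 0.02, 0.01)),
    exercise = stats::rbinom(n, 1, 0.52),
    breastfeeding_years = round(pmax(stats::rnorm(n, 1.0, 1.1), 0), 2),
    fasting_glucose = stats::rnorm(n, 91, 8),
    hba1c = stats::rnorm(n, 5.6, 0.3),
    stringsAsFactors = FALSE)
}

# Shared penetrance machinery: linear predictor for a penetrance_spec.
penetrance_lp <- function(genotypes, spec, covariates = NULL) {
  stopifnot(inherits(spec, "penetrance_spec"))
  miss <- setdiff(spec$model_snps, genotypes$variants$id)
  if (length(miss)) {
    stop("penetrance_spec references unknown SNP(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lp <- rep(spec$baseline_logit, nrow(genotypes$dosages))
  mafs <- stats::setNames(genotypes$variants$maf, genotypes$variants$id)
  dose <- function(id) {
    d <- variant_dosage(genotypes, id)
    d[is.na(d)] <- 2 * mafs[[id]]   # mean-impute rare missing calls
    d
  }
  for (id in names(spec$per_allele_logits)) {
    b <- spec$per_allele_logits[[id]]
    if (b != 0) lp <- lp + b * dose(id)
  }
  if (!is.null(spec$epistasis_terms)) {
    for (r in seq_len(nrow(spec$epistasis_terms))) {
      ei <- spec$epistasis_terms[r, ]
      ci <- dose(ei$snp_i) - 2 * mafs[[ei$snp_i]]
      cj <- dose(ei$snp_j) - 2 * mafs[[ei$snp_j]]
      lp <- lp + ei$logit * ci * cj
    }
  }
  if (!is.null(spec$covariate_logits)) {
    for (nm in names(spec$covariate_logits)) {
      x <- covariates[[nm]]
      if (is.null(x)) stop("covariate '", nm, "' not in covariate table",
                           call. = FALSE)
      lp <- lp + spec$covariate_logits[[nm]] * (x - mean(x))
    }
  }
  lp
}

#' Simulate gestational diabetes status from a planted penetrance model
#'
#' P(GDM) is the inverse logit of baseline + additive SNP terms +
#' centered-dosage interaction terms + centered covariate terms; the
#' default covariate effects are positive for age at first pregnancy and
#' BMI at age 20.
#'
#' @param genotypes A [genotype_matrix()].
#' @param spec A [penetrance_spec()].
#' @param covariates Covariate table from [simulate_covariates()] (or
#'   compatible); required when `spec$covariate_logits` is non-empty.
#' @param seed Integer seed.
#' @return `covariates` with a `gdm_status` column appended (a new table
#'   when `covariates` is NULL).
#' @export
simulate_gdm <- function(genotypes, spec, covariates = NULL, seed = 1L) {
  n <- nrow(genotypes$dosages)
  if (is.null(covariates)) {
    covariates <- data.frame(subject_id = rownames(genotypes$dosages),
                             stringsAsFactors = FALSE)
  }
  stopifnot(nrow(covariates) == n)
  p <- stats::plogis(penetrance_lp(genotypes, spec, covariates))
  set.seed(seed)
  covariates$gdm_status <- stats::rbinom(n, 1L, p)
  covariates
}

#' Planted PRS-by-lifestyle effect on type 2 diabetes
#'
#' @param baseline_logit Intercept on the logit scale (default ~7.6%
#'   prevalence, the control-group T2DM rate the cohort emulates).
#' @param prs_logit_per_allele Log-OR per risk allele (centered PRS).
#' @param diet_main_logit Log-OR for high dietary-pattern intake.
#' @param prs_by_diet_logit Interaction log-OR: extra per-allele effect in
#'   the high-intake stratum.
#' @param breastfeeding_logit Log-OR for breastfeeding >= 1 year.
#' @return An object of class `lifestyle_effect_spec`.
#' @export
lifestyle_effect_spec <- function(baseline_logit = stats::qlogis(0.076),
                                  prs_logit_per_allele = 0,
                                  diet_main_logit = 0,
                                  prs_by_diet_logit = 0,
                                  breastfeeding_logit = 0) {
  vals <- c(baseline_logit, prs_logit_per_allele, diet_main_logit,
            prs_by_diet_logit, breastfeeding_logit)
  stopifnot(all(is.finite(vals)))
  structure(list(baseline_logit = baseline_logit,
                 prs_logit_per_allele = prs_logit_per_allele,
                 diet_main_logit = diet_main_logit,
                 prs_by_diet_logit = prs_by_diet_logit,
                 breastfeeding_logit = breastfeeding_logit),
            class = "lifestyle_effect_spec")
}

#' Simulate type 2 diabetes status with a PRS-by-lifestyle interaction
#'
#' P(T2DM) is the inverse logit of baseline + PRS term + diet term +
#' PRS-by-diet term + breastfeeding term. The PRS enters centered at its
#' cohort mean so the baseline logit pins the overall prevalence.
#'
#' @param prs Integer risk-allele counts per subject (e.g.
#'   `compute_prs()$prs`).
#' @param lifestyle Data frame aligned with `prs`, with columns
#'   `diet_high` (0/1) and/or `breastfeeding_years` as the spec requires.
#' @param spec A [lifestyle_effect_spec()].
#' @param seed Integer seed.
#' @return Integer 0/1 vector of T2DM status.
#' @export
simulate_t2dm <- function(prs, lifestyle, spec, seed = 1L) {
  stopifnot(inherits(spec, "lifestyle_effect_spec"))
  n <- length(prs)
  stopifnot(nrow(lifestyle) == n)
  lp <- rep(spec$baseline_logit, n)
  prs_c <- prs - mean(prs)
  lp <- lp + spec$prs_logit_per_allele * prs_c
  if (spec$diet_main_logit != 0 || spec$prs_by_diet_logit != 0) {
    if (is.null(lifestyle$diet_high)) {
      stop("lifestyle table needs a 'diet_high' column", call. = FALSE)
    }
    lp <- lp + spec$diet_main_logit * lifestyle$diet_high +
      spec$prs_by_diet_logit * prs_c * lifestyle$diet_high
  }
  if (spec$breastfeeding_logit != 0) {
    if (is.null(lifestyle$breastfeeding_years)) {
      stop("lifestyle table needs a 'breastfeeding_years' column", call. = FALSE)
    }
    lp <- lp + spec$breastfeeding_logit * (lifestyle$breastfeeding_years >= 1)
  }
  set.seed(seed)
  stats::rbinom(n, 1L, stats::plogis(lp))
}

#' Simulate food-frequency intakes from a latent-factor model
#'
#' Each subject's group intakes are `loadings %*% factors + noise`, with
#' standard-normal latent factors and iid Gaussian noise, then shifted per
#' group so all intakes are non-negative.
#'
#' @param n_subjects Number of subjects.
#' @param factor_loadings Groups x factors numeric matrix (29 x k for the
#'   default food grouping). A zero-column matrix yields pure noise.
#' @param noise_sd Noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return Subjects x groups intake matrix; column names from the loading
#'   matrix row names (defaults `group01`..).
#' @export
simulate_ffq <- function(n_subjects, factor_loadings, noise_sd = 1, seed = 1L) {
  L <- as.matrix(factor_loadings)
  stopifnot(all(is.finite(L)), noise_sd > 0)
  set.seed(seed)
  k <- ncol(L)
  g <- nrow(L)
  f <- matrix(stats::rnorm(n_subjects * k), n_subjects, k)
  x <- (if (k > 0) f %*% t(L) else matrix(0, n_subjects, g)) +
    matrix(stats::rnorm(n_subjects * g, sd = noise_sd), n_subjects, g)
  x <- sweep(x, 2, apply(x, 2, min))   # shift to non-negative
  colnames(x) <- if (!is.null(rownames(L))) rownames(L) else
    sprintf("group%02d", seq_len(g))
  rownames(x) <- sprintf("S%d", seq_len(n_subjects))
  x
}
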