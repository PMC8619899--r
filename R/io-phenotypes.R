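#' Read a phenotype / covariate / lifestyle table
#'
#' Reads a CSV or TSV (delimiter inferred from the extension) and validates
#' it against the cohort schema: binary outcomes (`gdm_status`,
#' `t2dm_status`), continuous glycemic traits (`fasting_glucose` in mg/dL,
#' `hba1c` in percent), covariates (age, age at first pregnancy, BMI at age
#' 20, residence area, childbirth experience, education, income, energy
#' intake, alcohol, smoking, exercise, breastfeeding years).
#'
#' When `derive_t2dm = TRUE` the type 2 diabetes status is derived as
#' fasting glucose > 126 mg/dL, or HbA1c >= 6.5%, or use of hypoglycemic
#' agents (column `hypoglycemic_agent`, optional, treated as 0 if absent).
#'
#' A numeric `income` column (monthly USD) is mapped onto the three-level
#' scale low (< $2000), medium ($2000-4000), high (> $4000).
#'
#' @param path CSV/TSV file with a header row.
#' @param derive_t2dm Derive `t2dm_status` from glucose/HbA1c/medication
#'   instead of requiring it as a column.
#' @param levels Named list overriding the allowed category levels for
#'   `education`, `income`, `smoking`, `alcohol`.
#' @return A data frame with validated columns; categorical columns are
#'   factors with the schema's level sets.
#' @export
read_phenotypes <- function(path, derive_t2dm = FALSE, levels = list()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  ph <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_phenotypes(ph, derive_t2dm = derive_t2dm, levels = levels)
}

#' @rdname read_phenotypes
#' @param ph A data frame already in memory (e.g. from the simulator).
#' @export
validate_phenotypes <- function(ph, derive_t2dm = FALSE, levels = list()) {
  lv <- utils::modifyList(list(
    education = c("less_than_high_school", "high_school", "college_or_more"),
    income    = c("low", "medium", "high"),
    smoking   = c("never", "past", "current"),
    alcohol   = c("none", "mild", "moderate")
  ), levels)
  if (!"subject_id" %in% names(ph)) {
    ph$subject_id <- paste0("S", seq_len(nrow(ph)))
  }
  if (is.numeric(ph$income)) ph$income <- categorize_income(ph$income)
  for (col in names(lv)) {
    if (!col %in% names(ph)) next
    bad <- !is.na(ph[[col]]) & !(ph[[col]] %in% lv[[col]])
    if (any(bad)) {
      stop(sprintf("column '%s' has unknown level(s) %s in row(s) %s",
                   col, paste(unique(ph[[col]][bad]), collapse = ", "),
                   paste(utils::head(which(bad), 10), collapse = ", ")),
           call. = FALSE)
    }
    ph[[col]] <- factor(ph[[col]], levels = lv[[col]])
  }
  if (derive_t2dm) {
    ph$t2dm_status <- derive_t2dm_status(ph)
  }
  for (col in c("gdm_status", "t2dm_status", "childbirth", "exercise")) {
    if (col %in% names(ph) && !all(ph[[col]] %in% c(0, 1, NA))) {
      stop("column '", col, "' must be binary 0/1", call. = FALSE)
    }
  }
  if (all(c("gdm_status", "pre_pregnancy_diabetes") %in% names(ph))) {
    both <- ph$gdm_status == 1 & ph$pre_pregnancy_diabetes == 1
    if (any(both, na.rm = TRUE)) {
      stop("subjects flagged both GDM-case and pre-pregnancy diabetic: rows ",
           paste(utils::head(which(both), 10), collapse = ", "), call. = FALSE)
    }
  }
  ph
}

#' Derive type 2 diabetes status from glycemic traits and medication
#'
#' T2DM is positive when fasting glucose exceeds 126 mg/dL (strict), HbA1c
#' is at least 6.5%, or the subject takes hypoglycemic agents.
#'
#' @param ph Data frame with `fasting_glucose`, `hba1c` and optionally
#'   `hypoglycemic_agent` (0/1).
#' @return Integer 0/1 vector.
#' @export
derive_t2dm_status <- function(ph) {
  need <- setdiff(c("fasting_glucose", "hba1c"), names(ph))
  if (length(need)) {
    stop("cannot derive t2dm_status without column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  med <- if ("hypoglycemic_agent" %in% names(ph)) ph$hypoglycemic_agent else 0
  as.integer(ph$fasting_glucose > 126 | ph$hba1c >= 6.5 | med == 1)
}

#' Map monthly household income in USD onto the three-level scale
#'
#' @param usd Numeric monthly income.
#' @return Factor with levels `low` (< $2000), `medium` ($2000-4000),
#'   `high` (> $4000).
#' @export
categorize_income <- function(usd) {
  out <- ifelse(usd < 2000, "low", ifelse(usd <= 4000, "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Read genotypes in PLINK or VCF format
#'
#' Thin dispatcher over [read_plink()] and [read_vcf()].
#'
#' @param path PLINK stem (no extension) or VCF path.
#' @param format `"plink"` or `"vcf"`; guessed from the path when `NULL`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink"
  }
  format <- match.arg(format, c("plink", "vcf"))
  if (format == "vcf") read_vcf(path) else read_plink(sub("\\.bed$", "", path))
}
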