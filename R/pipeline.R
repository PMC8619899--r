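#' Named covariate presets for adjusted models
#'
#' Two presets exist in two printed variants each, reflecting the two
#' covariate lists in circulation for this design; select by name.
#' `model1_text`/`model2_text`: age at first pregnancy, BMI at age 20,
#' residence area (+ childbirth experience, education for model 2).
#' `model1_fig`/`model2_fig`: age, BMI at age 20, residence area,
#' education, income (+ energy intake, alcohol, smoking, exercise).
#' `table5`: the lifestyle-interaction covariate set (age, education,
#' income, energy intake, residence area, alcohol, smoking, exercise).
#'
#' @param name Preset name, or `"custom"` with `columns` supplied.
#' @param columns Character vector of phenotype columns for `"custom"`.
#' @return Character vector of phenotype column names.
#' @export
covariate_preset <- function(name, columns = NULL) {
  presets <- list(
    model1_text = c("age_first_pregnancy", "bmi_at_20", "residence_area"),
    model2_text = c("age_first_pregnancy", "bmi_at_20", "residence_area",
                    "childbirth", "education"),
    model1_fig = c("age", "bmi_at_20", "residence_area", "education",
                   "income"),
    model2_fig = c("age", "bmi_at_20", "residence_area", "education",
                   "income", "energy_intake", "alcohol", "smoking",
                   "exercise"),
    table5 = c("age", "education", "income", "energy_intake",
               "residence_area", "alcohol", "smoking", "exercise"))
  if (name == "custom") {
    if (is.null(columns)) stop("custom preset needs 'columns'", call. = FALSE)
    return(columns)
  }
  if (!name %in% names(presets)) {
    stop("unknown covariate preset '", name, "'; one of: ",
         paste(c(names(presets), "custom"), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' Default pipeline configuration
#'
#' All stage thresholds are config keys with the standard defaults: QC at
#' 4% missingness / 30% heterozygosity / HWE p > 0.05, candidate selection
#' at p < 1e-4, LD pruning at r-squared 0.3, 10-fold GMDR, PRS cutoffs
#' (<=3 / 4-5 / >=6), and a simulation block describing a women-only
#' cohort with ~3% GDM prevalence, ~7.6% control-group T2DM prevalence,
#' a planted two-SNP effect among null SNPs, and a three-factor
#' food-frequency structure.
#'
#' @return Nested config list; override any entry via the `config`
#'   argument of [run_pipeline()] or a YAML file with the same structure.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = c("qc", "assoc", "prune", "gmdr", "prs", "interact", "diet"),
    input = list(genotypes = NULL, format = NULL, phenotypes = NULL,
                 ffq = NULL, derive_t2dm = FALSE),
    simulate = list(
      n_subjects = 10000L,
      null_snps = 8L,
      null_maf_range = c(0.05, 0.15),
      planted_snps = c("SNPA", "SNPB"),
      planted_maf = c(0.15, 0.15),
      planted_per_allele_logit = log(1.8),
      planted_epistasis_logit = 1.0,
      gdm_baseline_logit = stats::qlogis(0.03),
      covariate_logits = c(age_first_pregnancy = 0.05, bmi_at_20 = 0.10),
      t2dm = list(baseline_logit = stats::qlogis(0.076),
                  prs_logit_per_allele = log(1.2),
                  diet_main_logit = log(0.9),
                  prs_by_diet_logit = log(1.15),
                  breastfeeding_logit = log(0.887)),
      ffq_factors = 3L,
      ffq_loading = 1.5,
      ffq_noise_sd = 1),
    thresholds = list(missing_rate = 0.04, het_rate = 0.30, hwe_p = 0.05,
                      assoc_p = 1e-4, ld_r2 = 0.3),
    top_n = 10L,
    covariates = list(assoc = "model2_text", gmdr = "model2_text",
                      prs = "model2_text", interact = "table5"),
    gmdr = list(k_range = c(1L, 2L), n_folds = 10L, threshold = 0),
    prs = list(cutoffs = c(3, 5), mode = "fixed",
               missing_policy = "exclude", model_size = NULL),
    diet = list(eigen_threshold = 1.5, loading_threshold = 0.40,
                percentile = 70))
}

# Recursive merge of a user config (list or YAML path) over the defaults.
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  utils::modifyList(default_config(), config)
}

# Phenotype columns (numeric stay numeric, categories become factors)
# for a covariate preset applied to a phenotype table.
covariate_frame <- function(ph, preset) {
  cols <- covariate_preset(preset)
  missing <- setdiff(cols, names(ph))
  if (length(missing)) {
    stop("phenotype table lacks covariate column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- ph[, cols, drop = FALSE]
  for (nm in names(out)) {
    if (is.character(out[[nm]])) out[[nm]] <- factor(out[[nm]])
  }
  out
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order, the stages named in `config$stages`: genotype QC,
#' covariate-adjusted association scan with candidate selection, LD
#' pruning (then top-N by p), exhaustive GMDR search, PRS construction and
#' association, PRS-by-lifestyle interaction analysis, and dietary-pattern
#' extraction. Inputs come either from `config$input` paths (PLINK/VCF
#' genotypes, phenotype CSV/TSV, FFQ CSV) or, when those are NULL, from
#' the simulation block. Counts entering and leaving each stage are logged
#' to stderr and returned; a stage that empties the candidate set raises a
#' "no candidates" error. With a fixed seed the run is deterministic.
#'
#' @param config A config list (see [default_config()]), a YAML file path,
#'   or NULL for the defaults.
#' @return A result bundle (list of per-stage tables plus a `log` data
#'   frame); also written as TSV/JSON under `config$out_dir` when set.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_config(config)
  stages <- cfg$stages
  bundle <- list(config = cfg)
  log <- data.frame(stage = character(0), n_in = integer(0),
                    n_out = integer(0), stringsAsFactors = FALSE)
  note <- function(stage, n_in, n_out) {
    message(sprintf("[epiprs] %-8s %d -> %d", stage, n_in, n_out))
    log <<- rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out))
  }

  ## ---- inputs ----
  simulated <- is.null(cfg$input$genotypes)
  if (simulated) {
    sim <- cfg$simulate
    n_planted <- length(sim$planted_snps)
    set.seed(cfg$seed)
    null_mafs <- stats::runif(sim$null_snps, sim$null_maf_range[1],
                              sim$null_maf_range[2])
    vs <- data.frame(
      id = c(sim$planted_snps, sprintf("NULL%d", seq_len(sim$null_snps))),
      maf = c(sim$planted_maf, null_mafs),
      chrom = as.character(seq_len(n_planted + sim$null_snps)))
    gm <- simulate_genotypes(sim$n_subjects, vs, seed = cfg$seed + 1L)
    ph <- simulate_covariates(sim$n_subjects, seed = cfg$seed + 2L)
    pen <- penetrance_spec(
      model_snps = sim$planted_snps,
      baseline_logit = sim$gdm_baseline_logit,
      per_allele_logits = stats::setNames(
        rep(sim$planted_per_allele_logit, n_planted), sim$planted_snps),
      epistasis_terms = if (n_planted >= 2) data.frame(
        snp_i = sim$planted_snps[1], snp_j = sim$planted_snps[2],
        logit = sim$planted_epistasis_logit) else NULL,
      covariate_logits = as.list(sim$covariate_logits))
    ph <- simulate_gdm(gm, pen, ph, seed = cfg$seed + 3L)
    # latent high-diet flag used by the outcome generator (the diet stage
    # re-derives patterns from intakes independently of this flag)
    L <- matrix(0, 29, sim$ffq_factors)
    for (j in seq_len(sim$ffq_factors)) {
      L[((j - 1) * 9 + 1):(j * 9), j] <- sim$ffq_loading
    }
    rownames(L) <- sort(unique(default_food_groups()$group))
    ffq <- simulate_ffq(sim$n_subjects, L, noise_sd = sim$ffq_noise_sd,
                        seed = cfg$seed + 4L)
    latent1 <- scale(ffq[, 1:9]) %*% rep(1, 9)  # proxy of factor 1
    ph$diet_high <- as.integer(dichotomize_scores(as.numeric(latent1),
                                                  cfg$diet$percentile))
    bundle$ffq <- ffq
  } else {
    gm <- read_genotypes(cfg$input$genotypes, cfg$input$format)
    ph <- read_phenotypes(cfg$input$phenotypes,
                          derive_t2dm = cfg$input$derive_t2dm)
    if (!is.null(cfg$input$ffq)) {
      bundle$ffq <- as.matrix(utils::read.csv(cfg$input$ffq, row.names = 1))
    }
  }
  bundle$phenotypes <- ph

  ## ---- qc ----
  current <- gm
  if ("qc" %in% stages) {
    n_in <- ncol(current$dosages)
    qc <- apply_qc_filters(current, cfg$thresholds)
    bundle$qc_report <- qc$report
    current <- qc$genotypes
    note("qc", n_in, ncol(current$dosages))
  }

  ## ---- association + candidate selection ----
  candidates <- NULL
  if ("assoc" %in% stages) {
    cov <- covariate_frame(ph, cfg$covariates$assoc)
    bundle$assoc <- assoc_scan(current, ph$gdm_status, cov)
    candidates <- select_candidates(bundle$assoc, cfg$thresholds$assoc_p)
    bundle$candidates <- candidates
    note("assoc", nrow(bundle$assoc), nrow(candidates))
    if (nrow(candidates) == 0) {
      stop("no candidates: association filter left no variants", call. = FALSE)
    }
  }

  ## ---- LD pruning + top-N ----
  if ("prune" %in% stages && !is.null(candidates)) {
    n_in <- nrow(candidates)
    candidates <- ld_prune(candidates, current, cfg$thresholds$ld_r2)
    candidates <- utils::head(candidates, cfg$top_n)
    bundle$pruned <- candidates
    note("prune", n_in, nrow(candidates))
    if (nrow(candidates) == 0) {
      stop("no candidates: LD pruning left no variants", call. = FALSE)
    }
  }

  ## ---- GMDR ----
  best_model <- NULL
  if ("gmdr" %in% stages && !is.null(candidates)) {
    cov <- covariate_frame(ph, cfg$covariates$gmdr)
    scores <- compute_score_residuals(ph$gdm_status, cov)
    k_range <- cfg$gmdr$k_range[cfg$gmdr$k_range <= nrow(candidates)]
    if (length(k_range) == 0) {
      stop("no candidates: fewer variants than the smallest GMDR model size",
           call. = FALSE)
    }
    bundle$gmdr <- run_gmdr_search(candidates$id, scores, ph$gdm_status,
                                   current, k_range = k_range,
                                   n_folds = cfg$gmdr$n_folds,
                                   seed = cfg$seed + 5L,
                                   threshold = cfg$gmdr$threshold)
    note("gmdr", nrow(candidates), nrow(bundle$gmdr))
    g <- bundle$gmdr
    # model choice: among sizes whose sign test is significant, take the
    # highest testing balanced accuracy (ties: higher CVC, then smaller k)
    pick <- if (!is.null(cfg$prs$model_size)) {
      which(g$k == cfg$prs$model_size)
    } else {
      sig <- g[g$sign_p < 0.05, , drop = FALSE]
      if (nrow(sig) == 0) sig <- g
      which(g$k == sig$k[order(-sig$teba, -sig$cvc, sig$k)][1])
    }
    best_model <- strsplit(g$snp_ids[pick], ",")[[1]]
    bundle$best_model <- best_model
  }

  ## ---- PRS ----
  prs_tab <- NULL
  if ("prs" %in% stages && !is.null(best_model)) {
    risk <- risk_alleles_from_assoc(
      bundle$assoc[bundle$assoc$id %in% best_model, , drop = FALSE], current)
    prs_tab <- compute_prs(current, risk, cfg$prs$missing_policy)
    prs_tab$category <- categorize_prs(prs_tab$prs, cfg$prs$cutoffs,
                                       cfg$prs$mode)
    if (cfg$prs$mode == "fixed" &&
        any(table(prs_tab$category) == 0)) {
      # small models cannot reach the fixed cutoffs; regroup on the
      # observed score distribution (tertiles, else observed values)
      u <- sort(unique(stats::na.omit(prs_tab$prs)))
      regrouped <- tryCatch(categorize_prs(prs_tab$prs, mode = "tertile"),
                            error = function(e) NULL)
      if (is.null(regrouped) && length(u) >= 3) {
        regrouped <- categorize_prs(prs_tab$prs, cutoffs = u[1:2])
      }
      if (!is.null(regrouped)) {
        message("[epiprs] fixed PRS cutoffs leave empty categor(ies) for ",
                "the ", length(best_model), "-SNP model; regrouping")
        prs_tab$category <- regrouped
      }
    }
    bundle$risk_alleles <- risk
    bundle$prs <- prs_tab
    cov <- covariate_frame(ph, cfg$covariates$prs)
    bundle$prs_assoc <- prs_association(prs_tab$category, ph$gdm_status, cov)
    note("prs", nrow(prs_tab), sum(!is.na(prs_tab$prs)))
  }

  ## ---- T2DM outcome (simulation mode plants the PRS-lifestyle effects) ----
  if (simulated && !is.null(prs_tab)) {
    t2 <- cfg$simulate$t2dm
    spec <- lifestyle_effect_spec(
      baseline_logit = t2$baseline_logit,
      prs_logit_per_allele = t2$prs_logit_per_allele,
      diet_main_logit = t2$diet_main_logit,
      prs_by_diet_logit = t2$prs_by_diet_logit,
      breastfeeding_logit = t2$breastfeeding_logit)
    ph$t2dm_status <- simulate_t2dm(prs_tab$prs, ph, spec,
                                    seed = cfg$seed + 6L)
    bundle$phenotypes <- ph
  }

  ## ---- PRS x lifestyle interaction ----
  if ("interact" %in% stages && !is.null(prs_tab) &&
      "t2dm_status" %in% names(ph)) {
    cov <- covariate_frame(ph, cfg$covariates$interact)
    strat_defs <- list()
    if ("gdm_status" %in% names(ph)) {
      strat_defs$gdm <- factor(ph$gdm_status, c(0, 1), c("non-GDM", "GDM"))
    }
    if ("breastfeeding_years" %in% names(ph)) {
      strat_defs$breastfeeding <- factor(ph$breastfeeding_years >= 1,
                                         c(FALSE, TRUE),
                                         c("<1 year", ">=1 year"))
    }
    if ("diet_high" %in% names(ph)) {
      strat_defs$diet <- factor(ph$diet_high, c(0, 1), c("low", "high"))
    }
    rows <- list()
    for (nm in names(strat_defs)) {
      st <- stratified_association(prs_tab$category, ph$t2dm_status,
                                   strat_defs[[nm]], cov)
      p_int <- tryCatch(
        as.numeric(interaction_test(ph$t2dm_status, prs_tab$prs,
                                    strat_defs[[nm]], cov)),
        error = function(e) NA_real_)
      st$stratifier <- nm
      st$interaction_p <- p_int
      rows[[nm]] <- st
    }
    bundle$interaction <- do.call(rbind, rows)
    note("interact", length(strat_defs), nrow(bundle$interaction))
  }

  ## ---- dietary patterns ----
  if ("diet" %in% stages && !is.null(bundle$ffq)) {
    dp <- extract_patterns(bundle$ffq,
                           eigen_threshold = cfg$diet$eigen_threshold,
                           loading_threshold = cfg$diet$loading_threshold,
                           percentile = cfg$diet$percentile)
    bundle$diet <- dp
    note("diet", ncol(bundle$ffq), dp$n_retained)
  }

  bundle$genotypes <- current
  bundle$log <- log
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

# Write the per-stage tables of a pipeline bundle as TSV/JSON.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in c("qc_report", "assoc", "candidates", "pruned", "gmdr",
               "prs", "prs_assoc", "interaction", "log")) {
    if (!is.null(bundle[[nm]])) wt(bundle[[nm]], nm)
  }
  if (!is.null(bundle$gmdr)) {
    jsonlite::write_json(attr(bundle$gmdr, "cell_labels"),
                         file.path(out_dir, "gmdr_cell_labels.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$diet) && bundle$diet$n_retained > 0) {
    wt(data.frame(group = rownames(bundle$diet$loadings),
                  bundle$diet$loadings, check.names = FALSE),
       "diet_loadings")
    wt(data.frame(subject_id = rownames(bundle$diet$scores),
                  bundle$diet$scores, check.names = FALSE), "diet_scores")
  }
  invisible(out_dir)
}
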