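#' Covariate-adjusted score residuals for GMDR
#'
#' The GMDR score statistic for a binary trait: the residual
#' `y - p-hat` from the covariate-only logistic null model (intercept-only
#' when no covariates are given, so scores are `1 - prevalence` for cases
#' and `-prevalence` for controls). With an intercept in the null model the
#' scores sum to zero.
#'
#' @param outcome Binary 0/1 vector.
#' @param covariates Optional data frame of covariates.
#' @return Numeric score vector, one per subject.
#' @export
compute_score_residuals <- function(outcome, covariates = NULL) {
  if (length(unique(stats::na.omit(outcome))) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(outcome - mean(outcome))
  }
  df <- cbind(data.frame(.y = outcome), as.data.frame(covariates))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep) {
    stop("covariates perfectly separate the outcome; scores undefined",
         call. = FALSE)
  }
  outcome - stats::fitted(fit)
}

# Multilocus cell index (1..3^k) for a SNP subset; NA when any genotype
# in the subset is missing.
multilocus_cells <- function(genotypes, snp_ids) {
  k <- length(snp_ids)
  idx <- match(snp_ids, genotypes$variants$id)
  if (anyNA(idx)) {
    stop("unknown SNP id(s): ", paste(snp_ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  d <- genotypes$dosages[, idx, drop = FALSE]
  cell <- rep(1L, nrow(d))
  for (j in seq_len(k)) cell <- cell + d[, j] * 3L^(j - 1L)
  cell  # NA propagates from missing dosages
}

# Core evaluation on a precomputed cell vector. Returns train/test balanced
# accuracy and the per-cell high/low labels from the training subjects.
gmdr_eval_cells <- function(cell, scores, outcome, train_idx, test_idx,
                            threshold = 0) {
  tr <- train_idx[!is.na(cell[train_idx])]
  te <- test_idx[!is.na(cell[test_idx])]
  sums <- rowsum(scores[tr], cell[tr])
  high_cells <- as.integer(rownames(sums))[sums[, 1] > threshold]
  ba <- function(ix) {
    y <- outcome[ix]
    if (length(unique(y)) < 2) return(NA_real_)
    pred <- cell[ix] %in% high_cells
    (mean(pred[y == 1]) + mean(!pred[y == 0])) / 2
  }
  list(train_ba = ba(tr), test_ba = ba(te), high_cells = high_cells)
}

#' Evaluate one SNP subset as a GMDR classifier on a train/test split
#'
#' Subjects are mapped to the 3^k multilocus genotype cells of the subset
#' (those missing any subset genotype are excluded). A cell is labeled
#' high-risk iff the sum of *training* score residuals in it exceeds the
#' threshold (default 0; empty, tied, or unseen-in-training cells are
#' low-risk). Subjects are predicted case iff their cell is high-risk, and
#' balanced accuracy = (sensitivity + specificity) / 2 against the true
#' outcome on each index set.
#'
#' @param snp_ids Character vector of 1-10 SNP ids.
#' @param scores Score residuals from [compute_score_residuals()].
#' @param outcome Binary 0/1 vector (the true case/control labels).
#' @param genotypes A [genotype_matrix()].
#' @param train_idx,test_idx Disjoint subject index vectors.
#' @param threshold Cell-classification threshold on the score sum.
#' @return List with `train_ba`, `test_ba` (NA when an index set has a
#'   single outcome class), and `cell_labels` (data frame of cell index,
#'   per-SNP genotypes, and label).
#' @export
evaluate_model <- function(snp_ids, scores, outcome, genotypes,
                           train_idx, test_idx, threshold = 0) {
  k <- length(snp_ids)
  stopifnot(k >= 1, k <= 10)
  if (length(intersect(train_idx, test_idx)) > 0) {
    stop("train and test sets must be disjoint", call. = FALSE)
  }
  cell <- multilocus_cells(genotypes, snp_ids)
  res <- gmdr_eval_cells(cell, scores, outcome, train_idx, test_idx, threshold)
  grid <- as.matrix(expand.grid(rep(list(0:2), k)))
  colnames(grid) <- snp_ids
  cells <- as.integer(1 + grid %*% 3L^(seq_len(k) - 1L))
  labels <- data.frame(cell = cells, grid,
                       label = ifelse(cells %in% res$high_cells,
                                      "high", "low"),
                       check.names = FALSE)
  list(train_ba = res$train_ba, test_ba = res$test_ba, cell_labels = labels)
}

#' One-sided binomial sign test on cross-validation support
#'
#' The sign statistic counts the folds supporting the model; the p-value is
#' the upper Binomial(n_folds, 1/2) tail,
#' p = sum_{j >= s} C(n, j) / 2^n.
#'
#' @param sign_stat Integer in 0..n_folds.
#' @param n_folds Number of folds.
#' @return The p-value.
#' @export
sign_test <- function(sign_stat, n_folds) {
  stopifnot(sign_stat >= 0, sign_stat <= n_folds)
  stats::pbinom(sign_stat - 1, n_folds, 0.5, lower.tail = FALSE)
}

# Seeded case/control-stratified fold labels.
stratified_folds <- function(outcome, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(outcome))
  for (cls in unique(outcome)) {
    ix <- which(outcome == cls)
    fold[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
  }
  fold
}

#' Exhaustive cross-validated GMDR model search
#'
#' For each model size k, every size-k subset of the candidate SNPs is
#' evaluated in a seeded, case/control-stratified n-fold cross-validation.
#' Within each fold the subset maximizing *training* balanced accuracy is
#' the fold winner; the best model of size k is the subset winning the most
#' folds (cross-validation consistency, CVC), with ties broken by higher
#' mean testing balanced accuracy and then lexicographic SNP ids. TRBA and
#' TEBA are that subset's across-fold mean training and testing balanced
#' accuracies, and the sign statistic counts folds with testing balanced
#' accuracy strictly above 0.5 (ties count against the model), tested
#' against the Binomial(n_folds, 1/2) upper tail.
#'
#' @param candidates Character vector of candidate SNP ids (or a data frame
#'   with an `id` column, e.g. from [ld_prune()]).
#' @param scores Score residuals from [compute_score_residuals()].
#' @param outcome Binary 0/1 vector.
#' @param genotypes A [genotype_matrix()].
#' @param k_range Model sizes to search (each <= number of candidates).
#' @param n_folds Number of CV folds (>= 2; default 10).
#' @param seed Seed for the fold assignment.
#' @param threshold Cell-classification threshold (default 0).
#' @return Data frame with one row per model size: `k`, `snp_ids`
#'   (comma-separated), `trba`, `teba`, `sign_stat`, `sign_p`, `cvc`,
#'   `n_folds`; the per-size best models' full-data cell labels are in
#'   attribute `cell_labels`.
#' @export
run_gmdr_search <- function(candidates, scores, outcome, genotypes,
                            k_range = 1:3, n_folds = 10, seed = 1L,
                            threshold = 0) {
  if (is.data.frame(candidates)) candidates <- candidates$id
  candidates <- as.character(candidates)
  stopifnot(n_folds >= 2)
  if (max(k_range) > length(candidates)) {
    stop("k exceeds the number of candidate SNPs", call. = FALSE)
  }
  fold <- stratified_folds(outcome, n_folds, seed)
  all_idx <- seq_along(outcome)
  out <- list()
  labels <- list()
  for (k in k_range) {
    subsets <- utils::combn(candidates, k, simplify = FALSE)
    ns <- length(subsets)
    train_ba <- matrix(NA_real_, ns, n_folds)
    test_ba <- matrix(NA_real_, ns, n_folds)
    for (s in seq_len(ns)) {
      cell <- multilocus_cells(genotypes, subsets[[s]])
      for (f in seq_len(n_folds)) {
        te <- which(fold == f)
        tr <- which(fold != f)
        r <- gmdr_eval_cells(cell, scores, outcome, tr, te, threshold)
        train_ba[s, f] <- r$train_ba
        test_ba[s, f] <- r$test_ba
      }
    }
    bad_fold <- apply(train_ba, 2, function(x) all(is.na(x)))
    if (any(bad_fold)) {
      warning(sum(bad_fold), " fold(s) had a single outcome class; excluded",
              call. = FALSE)
    }
    use <- which(!bad_fold)
    winner <- vapply(use, function(f) which.max(train_ba[, f]), integer(1))
    cvc_all <- tabulate(winner, nbins = ns)
    teba_all <- rowMeans(test_ba[, use, drop = FALSE], na.rm = TRUE)
    key <- vapply(subsets, function(s) paste(sort(s), collapse = ","),
                  character(1))
    best <- order(-cvc_all, -teba_all, key)[1]
    sign_stat <- sum(test_ba[best, use] > 0.5, na.rm = TRUE)
    out[[length(out) + 1]] <- data.frame(
      k = k, snp_ids = paste(subsets[[best]], collapse = ","),
      trba = mean(train_ba[best, use], na.rm = TRUE),
      teba = teba_all[best],
      sign_stat = sign_stat, sign_p = sign_test(sign_stat, length(use)),
      cvc = cvc_all[best], n_folds = length(use),
      stringsAsFactors = FALSE)
    labels[[as.character(k)]] <- evaluate_model(
      subsets[[best]], scores, outcome, genotypes,
      train_idx = all_idx, test_idx = integer(0),
      threshold = threshold)$cell_labels
  }
  res <- do.call(rbind, out)
  attr(res, "cell_labels") <- labels
  res
}
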