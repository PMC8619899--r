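#' Default 106-item to 29-food-group mapping
#'
#' A synthetic default grouping shipped as an editable CSV
#' (`extdata/food_groups_synthetic.csv`): 106 generic food items assigned
#' to 29 named groups typical of a Korean semi-quantitative food-frequency
#' questionnaire (rice, kimchi, green vegetables, seaweeds, ...). It is a
#' stand-in written for this package, not a published instrument's
#' grouping; replace it with the study's own mapping for real data.
#'
#' @return Data frame with columns `item`, `group`.
#' @export
default_food_groups <- function() {
  path <- system.file("extdata", "food_groups_synthetic.csv",
                      package = "epiprs", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate item-level intakes to food groups
#'
#' @param item_intake Subjects x items numeric matrix/data frame with item
#'   column names.
#' @param mapping Data frame with columns `item`, `group`; every intake
#'   column must map to exactly one group.
#' @return Subjects x groups matrix of summed daily intakes.
#' @export
aggregate_food_groups <- function(item_intake, mapping = default_food_groups()) {
  x <- as.matrix(item_intake)
  mapping <- as.data.frame(mapping)
  if (anyDuplicated(mapping$item)) {
    stop("mapping assigns item(s) to more than one group: ",
         paste(unique(mapping$item[duplicated(mapping$item)]), collapse = ", "),
         call. = FALSE)
  }
  grp <- mapping$group[match(colnames(x), mapping$item)]
  if (anyNA(grp)) {
    stop("unmapped item(s): ",
         paste(colnames(x)[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  t(rowsum(t(x), grp))
}

#' Extract dietary patterns by PCA with varimax rotation
#'
#' Columns are standardized (correlation-matrix PCA); components with a
#' pre-rotation eigenvalue above `eigen_threshold` are retained and
#' varimax-rotated (Kaiser-normalized). Subject scores come from the
#' rotated solution, each component's sign is fixed so its
#' largest-magnitude loading is positive, and groups with |loading| at or
#' above `loading_threshold` label the pattern. Scores are dichotomized at
#' the 70th percentile into high/low intake flags.
#'
#' @param group_intake Subjects x groups numeric matrix (more subjects
#'   than groups).
#' @param eigen_threshold Retention threshold on eigenvalues (default 1.5).
#' @param loading_threshold Threshold on |rotated loading| for a group to
#'   label a pattern (default 0.40).
#' @param n_components Optional fixed number of components, overriding the
#'   eigenvalue rule.
#' @param percentile High-intake dichotomization percentile (default 70).
#' @return Object of class `diet_patterns`: `loadings` (rotated, groups x
#'   components), `eigenvalues` (pre-rotation, retained), `scores`
#'   (subjects x components), `labels` (list of labelling groups per
#'   component), `high_flags` (subjects x components logical), `rotation`
#'   (the orthonormal rotation matrix), `n_retained`. Zero retained
#'   components gives empty matrices.
#' @export
extract_patterns <- function(group_intake, eigen_threshold = 1.5,
                             loading_threshold = 0.40, n_components = NULL,
                             percentile = 70) {
  x <- as.matrix(group_intake)
  if (nrow(x) <= ncol(x)) {
    stop("need more subjects than food groups", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance group(s) dropped: ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  ev <- eigen(stats::cor(x), symmetric = TRUE)
  k <- if (!is.null(n_components)) n_components
  else sum(ev$values > eigen_threshold)
  if (k == 0) {
    return(structure(list(
      loadings = matrix(0, ncol(x), 0, dimnames = list(colnames(x), NULL)),
      eigenvalues = numeric(0),
      scores = matrix(0, nrow(x), 0), labels = list(),
      high_flags = matrix(FALSE, nrow(x), 0),
      rotation = matrix(0, 0, 0), n_retained = 0L,
      all_eigenvalues = ev$values), class = "diet_patterns"))
  }
  L <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(k)]), k)
  rownames(L) <- colnames(x)
  if (k >= 2) {
    vr <- stats::varimax(L, normalize = TRUE)
    Lr <- unclass(vr$loadings)
    rot <- vr$rotmat
  } else {
    Lr <- L
    rot <- diag(1)
  }
  # fix signs so each pattern's dominant group loads positively
  for (j in seq_len(k)) {
    if (Lr[which.max(abs(Lr[, j])), j] < 0) {
      Lr[, j] <- -Lr[, j]
      rot[, j] <- -rot[, j]
    }
  }
  colnames(Lr) <- sprintf("pattern%d", seq_len(k))
  # regression scores from the rotated solution
  scores <- z %*% Lr %*% solve(crossprod(Lr))
  colnames(scores) <- colnames(Lr)
  labels <- lapply(seq_len(k), function(j) {
    rownames(Lr)[abs(Lr[, j]) >= loading_threshold]
  })
  names(labels) <- colnames(Lr)
  high <- apply(scores, 2, dichotomize_scores, percentile = percentile)
  structure(list(loadings = Lr, eigenvalues = ev$values[seq_len(k)],
                 scores = scores, labels = labels, high_flags = high,
                 rotation = rot, n_retained = as.integer(k),
                 all_eigenvalues = ev$values),
            class = "diet_patterns")
}

#' @export
print.diet_patterns <- function(x, ...) {
  cat(sprintf("diet_patterns: %d component(s) retained\n", x$n_retained))
  if (x$n_retained > 0) {
    cat("  eigenvalues:", paste(sprintf("%.2f", x$eigenvalues),
                                collapse = ", "), "\n")
    for (nm in names(x$labels)) {
      cat(sprintf("  %s: %s\n", nm, paste(x$labels[[nm]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Dichotomize pattern scores at a percentile
#'
#' High iff the score is at or above the empirical percentile computed by
#' linear interpolation between order statistics (quantile type 7); tied
#' scores fall on the same side.
#'
#' @param scores Finite numeric vector.
#' @param percentile Cut percentile (default 70).
#' @return Logical vector (TRUE = high intake).
#' @export
dichotomize_scores <- function(scores, percentile = 70) {
  stopifnot(all(is.finite(scores)))
  if (stats::sd(scores) == 0) {
    warning("constant scores; all subjects flagged low", call. = FALSE)
    return(rep(FALSE, length(scores)))
  }
  scores >= stats::quantile(scores, percentile / 100, type = 7, names = FALSE)
}
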