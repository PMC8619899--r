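#' Genotype matrix container
#'
#' A `genotype_matrix` bundles a subjects x variants dosage matrix with its
#' variant metadata. Dosages count copies of the *minor* allele (0, 1, 2) and
#' use `NA` for missing calls; positions are 1-based as in `.bim` and VCF.
#'
#' @param dosages Integer matrix, subjects in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`. Row names (subject ids) and column
#'   names (variant ids) are kept if present.
#' @param variants Data frame with one row per variant and columns
#'   `id`, `chrom`, `pos`, `minor_allele`, `major_allele`. A `maf` column is
#'   recomputed from the dosages if absent.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (integer matrix) and `variants` (data frame with an added
#'   `maf` and `missing_rate` column).
#' @export
genotype_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (!all(dosages %in% c(0L, 1L, 2L, NA))) {
    stop("dosages must be 0, 1, 2 or NA (minor-allele copies)", call. = FALSE)
  }
  variants <- as.data.frame(variants)
  req <- c("id", "chrom", "pos", "minor_allele", "major_allele")
  miss <- setdiff(req, names(variants))
  if (length(miss)) {
    stop("variants is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("nrow(variants) must equal ncol(dosages)", call. = FALSE)
  }
  bad <- variants$minor_allele == variants$major_allele
  if (any(bad)) {
    stop("minor and major allele identical for variant(s): ",
         paste(variants$id[bad], collapse = ", "), call. = FALSE)
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  colnames(dosages) <- variants$id
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  }
  variants$maf <- observed_maf(dosages)
  variants$missing_rate <- colMeans(is.na(dosages))
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

# Observed minor-allele frequency from a 0/1/2 dosage matrix (NA-aware).
observed_maf <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = ", ")))
  cat(sprintf("  MAF range: %.3f - %.3f; mean missingness %.4f\n",
              min(x$variants$maf), max(x$variants$maf),
              mean(x$variants$missing_rate)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by variants and/or subjects
#'
#' @param gm A [genotype_matrix()].
#' @param variants Variant ids, or a logical/integer index over columns.
#' @param subjects Subject ids, or a logical/integer index over rows.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_variants <- function(gm, variants = NULL, subjects = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  vi <- if (is.null(variants)) seq_len(ncol(gm$dosages)) else {
    if (is.character(variants)) {
      idx <- match(variants, gm$variants$id)
      if (anyNA(idx)) {
        stop("unknown variant id(s): ",
             paste(variants[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      idx
    } else variants
  }
  si <- if (is.null(subjects)) seq_len(nrow(gm$dosages)) else {
    if (is.character(subjects)) match(subjects, rownames(gm$dosages)) else subjects
  }
  genotype_matrix(gm$dosages[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE])
}

# Internal: dosage vector for one variant id.
variant_dosage <- function(gm, id) {
  i <- match(id, gm$variants$id)
  if (is.na(i)) stop("unknown variant id: ", id, call. = FALSE)
  gm$dosages[, i]
}
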