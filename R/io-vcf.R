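#' Read genotypes from a VCF file
#'
#' Only the GT field is required. ALT-allele counts are computed from the
#' genotype calls and then oriented to the minor allele: when the observed
#' ALT frequency exceeds 0.5 the dosages are flipped (`2 - d`) and the REF
#' allele becomes the minor allele, so the returned dosages always count
#' minor-allele copies.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic site(s) not supported: ",
         paste(fix[multi, "ID"], collapse = ", "), call. = FALSE)
  }
  # ALT copies from GT strings such as 0/1, 1|1, ./.
  alt_count <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(a, function(x) {
      if (any(x == "." | is.na(x))) NA_integer_ else sum(x == "1")
    }, integer(1))
  }
  gt[is.na(gt)] <- "./."
  d <- apply(gt, 1, alt_count)          # subjects x variants
  if (is.null(dim(d))) d <- matrix(d, nrow = ncol(gt))
  rownames(d) <- colnames(gt)
  minor <- fix[, "ALT"]
  major <- fix[, "REF"]
  alt_freq <- colMeans(d, na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  if (any(flip)) {
    d[, flip] <- 2L - d[, flip]
    tmp <- minor[flip]; minor[flip] <- major[flip]; major[flip] <- tmp
  }
  genotype_matrix(d, data.frame(
    id = fix[, "ID"], chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    minor_allele = minor, major_allele = major, stringsAsFactors = FALSE))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a sites-plus-GT VCF (v4.2) with REF = major allele and
#' ALT = minor allele, so the minor-allele dosage maps onto the usual
#' 0/0, 0/1, 1/1 codes; missing calls become `./.`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  ids <- rownames(gm$dosages)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    d <- gm$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$major_allele[j],
            v$minor_allele[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
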