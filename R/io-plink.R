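#' Read genotypes from a PLINK bed/bim/fam file set
#'
#' Parses the binary PLINK 1 format directly: magic bytes `0x6c 0x1b`,
#' mode byte `0x01` (SNP-major), then 2-bit genotype codes packed four
#' subjects per byte, least-significant bits first. The `.bim` A1 allele is
#' taken as the minor allele (PLINK's default orientation), so dosages count
#' A1 copies: code `00` -> 2, `10` -> 1, `11` -> 0, `01` -> `NA`.
#'
#' @param stem Path without extension; `stem.bed`, `stem.bim` and `stem.fam`
#'   must all exist.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(stem) {
  paths <- paste0(stem, c(".bed", ".bim", ".fam"))
  ok <- file.exists(paths)
  if (!all(ok)) {
    stop("missing PLINK file(s): ", paste(paths[!ok], collapse = ", "),
         call. = FALSE)
  }
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1], call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files (mode byte 0x01) are supported",
         call. = FALSE)
  }
  bpv <- ceiling(n / 4)  # bytes per variant
  if (length(raw) - 3L != bpv * m) {
    stop(sprintf(".bed payload is %d bytes; expected %d for %d subjects x %d variants",
                 length(raw) - 3L, bpv * m, n, m), call. = FALSE)
  }
  # Decode all 2-bit codes at once: 4 codes per byte, LSB-first.
  payload <- as.integer(raw[-(1:3)])
  codes <- cbind(payload %% 4L, (payload %/% 4L) %% 4L,
                 (payload %/% 16L) %% 4L, payload %/% 64L)
  codes <- matrix(t(codes), nrow = 4L * bpv)   # codes per variant in order
  codes <- codes[seq_len(n), , drop = FALSE]   # drop padding
  # 00 -> 2 A1 copies, 10 -> 1, 11 -> 0, 01 -> missing
  lut <- c(2L, NA_integer_, 1L, 0L)
  dosages <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  rownames(dosages) <- as.character(fam[[2]])
  genotype_matrix(dosages,
                  data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                             minor_allele = bim$a1, major_allele = bim$a2,
                             stringsAsFactors = FALSE))
}

#' Write a genotype matrix as a PLINK bed/bim/fam file set
#'
#' @param gm A [genotype_matrix()].
#' @param stem Output path without extension.
#' @return `stem`, invisibly.
#' @export
write_plink <- function(gm, stem) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$dosages)
  v <- gm$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0L, v$pos, v$minor_allele, v$major_allele),
    paste0(stem, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  ids <- rownames(gm$dosages)
  utils::write.table(
    data.frame(ids, ids, 0L, 0L, 2L, -9L),  # women-only cohorts: sex code 2
    paste0(stem, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  # dosage (A1 copies) -> 2-bit code
  code_of <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 2L] <- 0L
    out[!is.na(d) & d == 1L] <- 2L
    out[!is.na(d) & d == 0L] <- 3L
    out
  }
  bpv <- ceiling(n / 4)
  con <- file(paste0(stem, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(ncol(gm$dosages))) {
    codes <- code_of(gm$dosages[, j])
    length(codes) <- 4L * bpv          # pad with 0 (counts as code 00)
    codes[is.na(codes)] <- 0L
    bytes <- colSums(matrix(codes * mult, nrow = 4L))
    writeBin(as.raw(bytes), con)
  }
  invisible(stem)
}
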