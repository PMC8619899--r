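#' Pairwise LD r-squared from unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by EM from the 3x3
#' genotype count table over jointly non-missing subjects (the double
#' heterozygote is the only ambiguous cell), and
#' r^2 = D^2 / (pA(1-pA) pB(1-pB)) with D the haplotype-frequency
#' covariance.
#'
#' @param dosages_a,dosages_b Numeric 0/1/2 vectors (NA allowed).
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param max_iter Maximum EM iterations.
#' @return r-squared in [0, 1], with attribute `D`.
#' @export
ld_r2 <- function(dosages_a, dosages_b, tol = 1e-12, max_iter = 1000) {
  keep <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[keep]
  b <- dosages_b[keep]
  n <- length(a)
  if (n == 0) stop("no jointly observed subjects", call. = FALSE)
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stop("r2 undefined: variant monomorphic among jointly observed subjects",
         call. = FALSE)
  }
  counts <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) counts[i + 1, j + 1] <- sum(a == i & b == j)
  pA <- mean(a) / 2
  pB <- mean(b) / 2
  # haplotypes: 11 = minor-minor, 10 = minor at A only, 01, 00
  h <- c(h11 = pA * pB, h10 = pA * (1 - pB), h01 = (1 - pA) * pB,
         h00 = (1 - pA) * (1 - pB))
  ndh <- counts[2, 2]  # double heterozygotes: phase-ambiguous
  # known haplotype contributions from unambiguous cells
  base <- c(
    h11 = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3],
    h10 = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    h01 = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
    h00 = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1])
  for (it in seq_len(max_iter)) {
    # E-step: split double hets between (11,00) and (10,01) phases
    w <- h["h11"] * h["h00"]
    v <- h["h10"] * h["h01"]
    frac <- if (w + v > 0) w / (w + v) else 0.5
    cnt <- base + ndh * c(frac, 1 - frac, 1 - frac, frac)
    h_new <- cnt / (2 * n)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  D <- unname(h["h11"] - pA * pB)
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(min(max(r2, 0), 1), D = D)
}

#' Greedy LD pruning of a p-sorted candidate list
#'
#' Scans candidates in ascending association-p order and keeps a variant
#' iff its r-squared with every already-kept variant *on the same
#' chromosome* is at or below the threshold; cross-chromosome pairs are
#' never tested. Ties in p are broken by ascending position (stable).
#'
#' @param candidates Data frame with columns `id`, `chrom`,
#'   `p_adjusted_model` (and optionally `pos`), e.g. from
#'   [select_candidates()].
#' @param genotypes A [genotype_matrix()] containing the candidates.
#' @param r2_threshold Exclusion threshold (default 0.3: variants in
#'   stronger LD than this with a kept variant are dropped).
#' @return The kept subset of `candidates`, in scan order, with a
#'   `pruned_for` column naming the kept variant that displaced each
#'   dropped one attached as attribute `dropped`.
#' @export
ld_prune <- function(candidates, genotypes, r2_threshold = 0.3) {
  if (nrow(candidates) == 0) return(candidates)
  ord <- order(candidates$p_adjusted_model,
               if (!is.null(candidates$pos)) candidates$pos
               else seq_len(nrow(candidates)))
  cand <- candidates[ord, , drop = FALSE]
  kept <- integer(0)
  dropped <- data.frame(id = character(0), blocked_by = character(0),
                        r2 = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (k in kept) {
      if (cand$chrom[k] != cand$chrom[i]) next
      r2 <- ld_r2(variant_dosage(genotypes, cand$id[k]),
                  variant_dosage(genotypes, cand$id[i]))
      if (r2 > r2_threshold) {
        ok <- FALSE
        dropped <- rbind(dropped, data.frame(
          id = cand$id[i], blocked_by = cand$id[k], r2 = as.numeric(r2),
          stringsAsFactors = FALSE))
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- cand[kept, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
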