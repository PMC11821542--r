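#' Diploid local-ancestry state probabilities from per-haplotype posteriors
#'
#' Combines two per-haplotype European-ancestry posteriors a, b under an
#' independence approximation into the four diploid states:
#' P_EE = ab, P_EA = a(1-b), P_AE = (1-a)b, P_AA = (1-a)(1-b). Inputs may be
#' scalars, vectors or matrices of matching shape.
#'
#' @param hap1_eu_prob,hap2_eu_prob European-ancestry posteriors in \[0, 1\].
#' @return list with components `EE`, `EA`, `AE`, `AA` (same shape as the
#'   inputs), summing to 1 elementwise.
#' @export
diploid_state_probs <- function(hap1_eu_prob, hap2_eu_prob) {
  a <- hap1_eu_prob; b <- hap2_eu_prob
  if (any(a < 0 | a > 1) || any(b < 0 | b > 1))
    stop("haplotype posteriors must lie in [0, 1]")
  structure(list(EE = a * b, EA = a * (1 - b),
                 AE = (1 - a) * b, AA = (1 - a) * (1 - b)),
            class = "diploid_probs")
}

#' Diploid state probabilities of a simulated cohort
#'
#' @param cohort an `admix_cohort`.
#' @return a `diploid_probs` list of n x M matrices.
#' @export
cohort_state_probs <- function(cohort) {
  post <- ancestry_posteriors(cohort)
  diploid_state_probs(post$a1, post$a2)
}

#' Expected ancestry-specific allele counts
#'
#' G_E = h1 a1 + h2 a2 and G_A = h1 (1-a1) + h2 (1-a2), the expected counts
#' of the counted allele carried on European / African background;
#' G_E + G_A equals the genotype exactly.
#'
#' @param hap1,hap2 allele matrices or vectors (0/1).
#' @param a1,a2 per-haplotype European posteriors in \[0, 1\].
#' @return list with matrices/vectors `GE`, `GA`.
#' @export
expected_ancestry_dosages <- function(hap1, hap2, a1, a2) {
  if (!all(hap1 %in% c(0, 1)) || !all(hap2 %in% c(0, 1)))
    stop("haplotype alleles must be 0/1")
  if (any(a1 < 0 | a1 > 1) || any(a2 < 0 | a2 > 1))
    stop("posteriors must lie in [0, 1]")
  list(GE = hap1 * a1 + hap2 * a2,
       GA = hap1 * (1 - a1) + hap2 * (1 - a2))
}

#' Mask uncertain or short local-ancestry segments
#'
#' A site is masked for an individual if the maximal diploid-state
#' posterior falls below `min_posterior`, or if it lies in a maximal run of
#' constant most-probable ancestry state spanning less than `min_length_bp`
#' (default 5 Mb) along the physical map. Masking is idempotent. Because
#' the phase of the two chromosomes is arbitrary, the EA and AE states are
#' collapsed into a single unphased heterozygous-ancestry class before
#' taking the maximum, so a confidently heterozygous site (EA = AE = 0.5)
#' is not treated as uncertain.
#'
#' @param probs a `diploid_probs` list of n x M matrices.
#' @param variants data frame with `chrom`, `pos` sorted by (chrom, pos).
#' @param min_length_bp minimal retained segment span in bp (default 5e6).
#' @param min_posterior minimal max-state posterior (default 0.9).
#' @return logical n x M matrix, TRUE where the site is masked.
#' @export
mask_segments <- function(probs, variants, min_length_bp = 5e6,
                          min_posterior = 0.9) {
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants))))
    stop("sites must be sorted by (chrom, pos)")
  EE <- as.matrix(probs$EE); EA <- as.matrix(probs$EA)
  AE <- as.matrix(probs$AE); AA <- as.matrix(probs$AA)
  n <- nrow(EE); M <- ncol(EE)
  stopifnot(M == nrow(variants))

  # most-probable unphased state (1=EE, 2=EA/AE, 3=AA) and its posterior
  HET <- EA + AE
  state <- matrix(1L, n, M); best <- EE
  for (k in 2:3) {
    Pk <- if (k == 2) HET else AA
    upd <- Pk > best
    state[upd] <- k
    best[upd] <- Pk[upd]
  }
  mask <- best < min_posterior

  chrom <- variants$chrom; pos <- variants$pos
  chrom_starts <- which(!duplicated(chrom))
  for (i in seq_len(n)) {
    for (ci in seq_along(chrom_starts)) {
      from <- chrom_starts[ci]
      to <- if (ci < length(chrom_starts)) chrom_starts[ci + 1] - 1 else M
      s <- state[i, from:to]
      r <- rle(s)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      span <- pos[from - 1 + ends] - pos[from - 1 + starts]
      short <- which(span < min_length_bp)
      for (k in short) {
        mask[i, (from - 1 + starts[k]):(from - 1 + ends[k])] <- TRUE
      }
    }
  }
  mask
}
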