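#' Greedy LD clumping of GWAS results
#'
#' Walks variants by ascending p-value (ties broken by genomic order). A
#' variant becomes an index SNP if its p-value is below `p1` and it is not
#' both within `window_kb` of an already-chosen index on the same
#' chromosome and in LD with it (r-squared above `r2`, computed as the
#' squared Pearson correlation of unphased dosage columns in the supplied
#' cohort). Index variants are returned with their GWAS effect estimates as
#' per-copy weights. Defaults mirror
#' `--clump-p1 0.05 --clump-p2 1 --clump-r1 0.1 --clump-kb 500`.
#'
#' @param results `gwas_result` data frame ([run_gwas()]).
#' @param G dosage matrix used for r-squared computation.
#' @param variants data frame with `chrom`, `pos` (and optionally `id`,
#'   `ref`, `alt`) aligned to the columns of `G`.
#' @param p1 index-SNP significance threshold (default 0.05; the strict
#'   alternative used at full scale is 1e-4).
#' @param r2 LD threshold (default 0.1).
#' @param window_kb physical clumping window in kb (default 500).
#' @return `pgs_weights` data frame: `variant`, `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight`, `p`.
#' @export
ld_clump <- function(results, G, variants, p1 = 0.05, r2 = 0.1,
                     window_kb = 500) {
  stopifnot(nrow(variants) == ncol(G))
  cand <- results[!is.na(results$p) & results$p < p1, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no variant passes the p1 threshold; empty weight set")
    return(empty_weights())
  }
  j <- cand$variant
  ord <- order(cand$p, variants$chrom[j], variants$pos[j])
  cand <- cand[ord, , drop = FALSE]

  Gs <- scale(G[, cand$variant, drop = FALSE])  # columns: candidates
  n1 <- nrow(Gs) - 1
  chrom <- variants$chrom[cand$variant]
  pos <- variants$pos[cand$variant]
  win <- window_kb * 1000

  keep <- integer(0)
  for (k in seq_len(nrow(cand))) {
    ok <- TRUE
    if (length(keep)) {
      near <- keep[chrom[keep] == chrom[k] & abs(pos[keep] - pos[k]) <= win]
      if (length(near)) {
        r <- drop(crossprod(Gs[, near, drop = FALSE], Gs[, k])) / n1
        if (any(r^2 > r2, na.rm = TRUE)) ok <- FALSE
      }
    }
    if (ok) keep <- c(keep, k)
  }
  idx <- cand$variant[keep]
  out <- data.frame(
    variant = idx,
    id = if ("id" %in% names(variants)) variants$id[idx]
         else paste0(variants$chrom[idx], ":", variants$pos[idx]),
    chrom = variants$chrom[idx], pos = variants$pos[idx],
    effect_allele = if ("alt" %in% names(variants)) variants$alt[idx] else "G",
    other_allele = if ("ref" %in% names(variants)) variants$ref[idx] else "A",
    weight = cand$beta[keep], p = cand$p[keep])
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pgs_weights", class(out))
  out
}

empty_weights <- function() {
  out <- data.frame(variant = integer(0), id = character(0),
                    chrom = integer(0), pos = integer(0),
                    effect_allele = character(0), other_allele = character(0),
                    weight = numeric(0), p = numeric(0))
  class(out) <- c("pgs_weights", class(out))
  out
}
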