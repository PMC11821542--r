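#' Estimate background-specific allele frequencies by per-site regression
#'
#' Fits, at every site j, the linear model
#' `G_ij = I_j + S_j x_ij + eps` with predictor
#' `x_ij = 2 P_EE + P_EA + P_AE` (the expected number of European-background
#' allele copies), and maps the fit to frequencies
#' `f_E = S_j + I_j / 2`, `f_A = I_j / 2`, clipped into \[0, 1\].
#' Sites whose predictor is (numerically) constant fall back to
#' `f_E = f_A = mean(G) / 2`. Missing genotypes and masked entries are
#' excluded pairwise.
#'
#' @param G n x M genotype (dosage) matrix.
#' @param probs `diploid_probs` list of n x M matrices.
#' @param mask optional logical n x M matrix (TRUE = excluded).
#' @param var_tol predictor-variance tolerance for the degenerate fallback.
#' @return `ancestral_freqs` data frame: `f_eu`, `f_af`, `slope`,
#'   `intercept`, `var_x`, `n_used`, `degenerate`, `clipped` (TRUE where a
#'   raw fitted frequency exited \[0, 1\]; clipping breaks the exact
#'   residual identity at such sites).
#' @export
fit_site_frequencies <- function(G, probs, mask = NULL, var_tol = 1e-8) {
  G <- as.matrix(G)
  xE <- 2 * as.matrix(probs$EE) + as.matrix(probs$EA) + as.matrix(probs$AE)
  if (!all(dim(G) == dim(xE))) stop("genotype / probability dimension mismatch")
  if (nrow(G) < 2) stop("need at least 2 individuals")
  w <- !is.na(G)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(G))) stop("mask dimension mismatch")
    w <- w & !mask
  }
  if (any(colSums(!is.na(G)) == 0)) stop("site with no usable genotypes")
  n_used <- colSums(w)
  # sites masked for every individual never feed centering: fall back to
  # the unmasked mean so the fit stays defined, and flag them degenerate
  all_masked <- n_used == 0
  if (any(all_masked)) w[, all_masked] <- !is.na(G[, all_masked])
  n_used <- colSums(w)
  Gw <- ifelse(w, G, 0)
  xw <- ifelse(w, xE, 0)
  Sx <- colSums(xw); Sg <- colSums(Gw)
  Sxx <- colSums(xw * xw); Sxg <- colSums(xw * Gw)
  mx <- Sx / n_used
  var_x <- Sxx / n_used - mx^2
  degenerate <- var_x < var_tol | n_used < 2
  denom <- n_used * Sxx - Sx^2
  slope <- ifelse(degenerate, 0, (n_used * Sxg - Sx * Sg) / denom)
  intercept <- ifelse(degenerate, Sg / n_used, (Sg - slope * Sx) / n_used)
  f_eu <- ifelse(degenerate, Sg / n_used / 2, slope + intercept / 2)
  f_af <- ifelse(degenerate, Sg / n_used / 2, intercept / 2)
  clipped <- f_eu < 0 | f_eu > 1 | f_af < 0 | f_af > 1
  out <- data.frame(f_eu = pmin(pmax(f_eu, 0), 1),
                    f_af = pmin(pmax(f_af, 0), 1),
                    slope = slope, intercept = intercept,
                    var_x = var_x, n_used = n_used,
                    degenerate = degenerate, clipped = clipped)
  class(out) <- c("ancestral_freqs", class(out))
  out
}

#' Mean-center ancestry-specific dosages
#'
#' Subtracts from each ancestry-specific expected allele count its
#' expectation conditional on the local-ancestry probabilities:
#' `Gbar_E = G_E - f_E (2 P_EE + P_EA + P_AE)` and
#' `Gbar_A = G_A - f_A (2 P_AA + P_EA + P_AE)`. Masked entries are set to 0
#' in both matrices. When the frequencies were fitted on the same cohort by
#' [fit_site_frequencies()] (same mask), `Gbar_E + Gbar_A` is the per-site
#' OLS residual and sums to zero over individuals.
#'
#' @param dosages list with matrices `GE`, `GA`
#'   (see [expected_ancestry_dosages()]).
#' @param probs `diploid_probs` list.
#' @param freqs data frame with columns `f_eu`, `f_af` (one row per site).
#' @param mask optional logical matrix, TRUE = masked.
#' @return list with centered matrices `GE`, `GA` and the `mask` used.
#' @export
mean_center_dosages <- function(dosages, probs, freqs, mask = NULL) {
  GE <- as.matrix(dosages$GE); GA <- as.matrix(dosages$GA)
  M <- ncol(GE)
  if (nrow(freqs) < M) stop("frequencies missing for some sites")
  fE <- freqs$f_eu[seq_len(M)]; fA <- freqs$f_af[seq_len(M)]
  xE <- 2 * as.matrix(probs$EE) + as.matrix(probs$EA) + as.matrix(probs$AE)
  xA <- 2 * as.matrix(probs$AA) + as.matrix(probs$EA) + as.matrix(probs$AE)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(GE), M)
  if (any(!is.finite(fE[colSums(!mask) > 0])) ||
      any(!is.finite(fA[colSums(!mask) > 0])))
    stop("missing frequency at an unmasked site")
  GEc <- GE - xE * rep(fE, each = nrow(GE))
  GAc <- GA - xA * rep(fA, each = nrow(GA))
  GEc[mask] <- 0
  GAc[mask] <- 0
  list(GE = GEc, GA = GAc, mask = mask)
}
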