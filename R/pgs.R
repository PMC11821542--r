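#' Compute a polygenic score
#'
#' `PGS_i = sum_j w_j G_ij`, an uncentered linear sum over the weight
#' table's variants (mean-centering genotypes within a population would
#' shift every score by a constant and leave slopes unchanged). Weights are
#' matched to cohort columns by the `variant` column when present,
#' otherwise by `id`; unmatched variants are skipped with a message.
#'
#' @param G n x M dosage matrix.
#' @param weights `pgs_weights` data frame.
#' @param variants optional variant table (needed for `id` matching).
#' @return numeric vector of per-individual scores.
#' @export
compute_pgs <- function(G, weights, variants = NULL) {
  if (nrow(weights) == 0) return(rep(0, nrow(G)))
  if (!is.null(weights$variant) && !anyNA(weights$variant)) {
    idx <- weights$variant
    keep <- idx >= 1 & idx <= ncol(G)
  } else {
    if (is.null(variants)) stop("need `variants` to match weights by id")
    idx <- match(weights$id, variants$id)
    keep <- !is.na(idx)
  }
  if (any(!keep))
    message(sum(!keep), " weight variants not found in cohort; skipped")
  if (!any(keep)) return(rep(0, nrow(G)))
  drop(G[, idx[keep], drop = FALSE] %*% weights$weight[keep])
}

#' Reference-population PGS slope and residual r-squared
#'
#' Fits `Y = I + beta PGS + covariates + eps` by OLS. `beta` estimates the
#' increase in mean phenotype per unit PGS; `delta_r2` is 1 minus the ratio
#' of residual phenotypic variance with the PGS in the model to the (larger)
#' residual variance with `beta = 0` — the variance explained by the PGS
#' beyond covariates. Uncertainty by percentile bootstrap over individuals.
#'
#' @param Y phenotype vector.
#' @param PGS score vector.
#' @param covariates optional covariate matrix (intercept always added).
#' @param n_boot bootstrap replicates (default 1000; 0 disables).
#' @param seed integer seed for the bootstrap.
#' @return `reference_slope` list: `beta`, `delta_r2`, `ci` (2.5/97.5
#'   percentiles of beta), `boot` (replicate betas), `n`.
#' @export
fit_reference_slope <- function(Y, PGS, covariates = NULL, n_boot = 1000,
                                seed = 1L) {
  n <- length(Y)
  stopifnot(length(PGS) == n)
  if (stats::var(PGS) < 1e-14 * max(1, stats::var(Y)))
    stop("zero-variance PGS")
  X0 <- cbind(rep(1, n), covariates)
  if (n <= ncol(X0) + 2) stop("too few individuals")
  est <- slope_dr2(Y, PGS, X0)
  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    boot <- vapply(seq_len(n_boot), function(b) {
      ii <- sample.int(n, n, replace = TRUE)
      slope_dr2(Y[ii], PGS[ii], X0[ii, , drop = FALSE])["beta"]
    }, numeric(1))
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  }
  structure(list(beta = unname(est["beta"]),
                 delta_r2 = unname(est["delta_r2"]),
                 ci = ci, boot = unname(boot), n = n),
            class = "reference_slope")
}

slope_dr2 <- function(Y, PGS, X0) {
  fit_full <- stats::lm.fit(cbind(X0, PGS), Y)
  fit_red <- stats::lm.fit(X0, Y)
  sse_full <- sum(fit_full$residuals^2)
  sse_red <- sum(fit_red$residuals^2)
  c(beta = unname(fit_full$coefficients[ncol(X0) + 1]),
    delta_r2 = 1 - sse_full / sse_red)
}

#' @export
print.reference_slope <- function(x, ...) {
  cat(sprintf("beta_Obs = %.4g (95%% CI %.4g, %.4g), delta_R2 = %.4f, n = %d\n",
              x$beta, x$ci[1], x$ci[2], x$delta_r2, x$n))
  invisible(x)
}

#' LDSC-style attenuation ratio
#'
#' `(max(intercept, 1) - 1) / (max(mean_chi2, 1) - 1)`; both inputs are
#' floored at 1 for non-negativity and 0/0 is reported as 0.
#'
#' @param intercept LD-score regression intercept.
#' @param mean_chi2 mean association chi-squared.
#' @return the attenuation ratio.
#' @export
attenuation_ratio <- function(intercept, mean_chi2) {
  stopifnot(is.finite(intercept), is.finite(mean_chi2))
  num <- max(intercept, 1) - 1
  den <- max(mean_chi2, 1) - 1
  if (num == 0) return(0)
  num / den
}
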