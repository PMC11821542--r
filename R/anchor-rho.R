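#' Estimate the cross-ancestry effect-size correlation rho
#'
#' `rho_hat = beta_Eu / beta_Obs.Eu`: the European-segment slope from the
#' admixed-cohort fit divided by the phenotype-per-PGS slope in the
#' European reference cohort. Also reports the projection to individuals of
#' 100% African ancestry, `beta_Eu (1 + omega) / beta_Obs.Eu`, and the
#' local-tagging ratio `beta_Af / beta_Obs.Eu` (expected below 1 whenever
#' the PGS tags rather than contains the causal variants). Confidence
#' intervals come from a joint bootstrap: replicate b of the admixed-cohort
#' fit is paired with replicate b of the reference slope, so both cohorts'
#' sampling noise propagates into the ratio.
#'
#' @param fit an `anchor_fit`, ideally from [bootstrap_fit()] (replicates
#'   are needed for CIs).
#' @param ref a `reference_slope` from [fit_reference_slope()].
#' @return `rho_estimate` list: `rho`, `rho_projected_af`, `local_ratio`,
#'   `ci` (per quantity), `unstable` (TRUE when the reference-slope CI
#'   covers 0), and the paired replicate table `boot`.
#' @export
estimate_rho <- function(fit, ref) {
  if (!is.finite(ref$beta) || ref$beta == 0)
    stop("reference slope beta_Obs.Eu is zero")
  rho <- fit$beta_eu / ref$beta
  omega <- ifelse(is.na(fit$omega), 0, fit$omega)
  out <- list(rho = rho,
              rho_projected_af = fit$beta_eu * (1 + omega) / ref$beta,
              local_ratio = fit$beta_af / ref$beta,
              beta_eu = fit$beta_eu, beta_af = fit$beta_af,
              beta_obs_eu = ref$beta,
              unstable = length(ref$ci) == 2 && all(is.finite(ref$ci)) &&
                ref$ci[1] <= 0 && ref$ci[2] >= 0)
  if (!is.null(fit$boot) && length(ref$boot) > 1) {
    B <- min(nrow(fit$boot), length(ref$boot))
    rb <- ref$boot[seq_len(B)]
    om <- fit$boot$omega[seq_len(B)]
    om[is.na(om)] <- 0
    boot <- data.frame(
      rho = fit$boot$beta_eu[seq_len(B)] / rb,
      rho_projected_af = fit$boot$beta_eu[seq_len(B)] * (1 + om) / rb,
      local_ratio = fit$boot$beta_af[seq_len(B)] / rb,
      beta_eu = fit$boot$beta_eu[seq_len(B)], beta_obs_eu = rb)
    out$boot <- boot
    out$ci <- lapply(boot[c("rho", "rho_projected_af", "local_ratio")],
                     function(v) stats::quantile(v, c(0.025, 0.975),
                                                 names = FALSE, na.rm = TRUE))
  }
  class(out) <- "rho_estimate"
  out
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("rho_hat = %.4f", x$rho))
  if (!is.null(x$ci))
    cat(sprintf(" (95%% CI %.4f, %.4f)", x$ci$rho[1], x$ci$rho[2]))
  cat(sprintf("; local ratio beta_Af/beta_Obs.Eu = %.4f\n", x$local_ratio))
  if (isTRUE(x$unstable))
    cat("  [unstable: reference-slope CI covers 0]\n")
  invisible(x)
}

#' Pool rho estimates across traits
#'
#' The pooled correlation is the ratio of (weighted) means,
#' `sum_t w_t beta_Eu_t / sum_t w_t beta_Obs.Eu_t`, with equal weights or
#' weights inversely proportional to the bootstrap variance of each trait's
#' ratio. The CI is a trait-paired joint bootstrap: the pooled ratio is
#' recomputed on each replicate b using every trait's b-th paired
#' replicates.
#'
#' @param estimates list of `rho_estimate` objects.
#' @param weighting `"equal"` or `"inverse_variance"` (default
#'   inverse bootstrap variance of the per-trait ratio).
#' @return list: `rho`, `ci`, `weights`, `n_traits`, `per_trait`.
#' @export
pool_traits <- function(estimates,
                        weighting = c("inverse_variance", "equal")) {
  weighting <- match.arg(weighting)
  if (length(estimates) < 1) stop("need at least one trait")
  be <- vapply(estimates, function(e) e$beta_eu, numeric(1))
  bo <- vapply(estimates, function(e) e$beta_obs_eu, numeric(1))
  if (weighting == "equal" || length(estimates) == 1) {
    w <- rep(1, length(estimates))
  } else {
    v <- vapply(estimates, function(e) {
      if (is.null(e$boot)) NA_real_ else stats::var(e$boot$rho, na.rm = TRUE)
    }, numeric(1))
    if (anyNA(v)) {
      warning("missing bootstrap replicates; falling back to equal weights")
      w <- rep(1, length(estimates))
    } else w <- 1 / v
  }
  w <- w / sum(w)
  den <- sum(w * bo)
  if (den == 0) stop("pooled reference slope is zero")
  pooled <- sum(w * be) / den

  ci <- NULL
  Bs <- vapply(estimates, function(e)
    if (is.null(e$boot)) 0L else nrow(e$boot), integer(1))
  if (all(Bs > 1)) {
    B <- min(Bs)
    reps <- vapply(seq_len(B), function(b) {
      num <- sum(w * vapply(estimates, function(e) e$boot$beta_eu[b],
                            numeric(1)))
      den_b <- sum(w * vapply(estimates, function(e) e$boot$beta_obs_eu[b],
                              numeric(1)))
      num / den_b
    }, numeric(1))
    ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  }
  list(rho = pooled, ci = ci, weights = w, n_traits = length(estimates),
       per_trait = data.frame(beta_eu = be, beta_obs_eu = bo,
                              rho = be / bo, weight = w))
}
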