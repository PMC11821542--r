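#' Simulate an additive phenotype with calibrated heritability
#'
#' Y_i = sum_j gamma_j g_ij + eps_i. The noise variance is calibrated to the
#' target heritability from the observed variance of the genetic term,
#' sigma_e^2 = ((1 - h2)/h2) sigma_g^2, so the realized heritability matches
#' `h2` up to sampling error.
#'
#' With `ancestry_specific = TRUE` the African-background effects enter the
#' genetic value. Two models are offered:
#' * `effect_model = "individual"` (default): every genotype of this cohort
#'   contributes `gamma_af`. This reproduces the efficient construction used
#'   in the cross-ancestry simulations — European-cohort phenotypes are
#'   generated with `gamma_eu`, the admixed cohort's with `gamma_af`
#'   (correlated rho with `gamma_eu`), capturing nonlocal (gene-gene /
#'   gene-environment) interactions that act on the whole genome of an
#'   individual. Only under this model does the decomposition's
#'   beta_Eu / beta_Obs.Eu estimate rho.
#' * `effect_model = "tract"`: each allele copy contributes `gamma_eu` or
#'   `gamma_af` according to the true ancestry of its haplotype tract — a
#'   strictly local interaction model, kept for contrast experiments.
#'
#' Because calibration uses the cohort's own genetic-value variance,
#' simulating an admixed cohort separately from a European cohort with the
#' same effects automatically adjusts the admixed group's noise so its
#' heritability stays at `h2`.
#'
#' @param cohort an `admix_cohort`.
#' @param effects data frame from [draw_effect_sizes()] (`index`,
#'   `gamma_eu`, `gamma_af`).
#' @param h2 target heritability in (0, 1]; `h2 = 1` gives a noiseless trait.
#' @param ancestry_specific use the African-background effects (see above).
#' @param effect_model `"individual"` or `"tract"`.
#' @param seed integer seed for the noise draw.
#' @return list with `y` (phenotype), `genetic` (true genetic values),
#'   `sigma_e2`, and `h2_realized` = var(genetic)/var(y).
#' @export
simulate_phenotype <- function(cohort, effects, h2, ancestry_specific = FALSE,
                               effect_model = c("individual", "tract"),
                               seed) {
  effect_model <- match.arg(effect_model)
  if (!(h2 > 0 && h2 <= 1)) stop("`h2` must lie in (0, 1]")
  j <- effects$index
  if (!ancestry_specific) {
    genetic <- drop(cohort$G[, j, drop = FALSE] %*% effects$gamma_eu)
  } else if (effect_model == "individual") {
    genetic <- drop(cohort$G[, j, drop = FALSE] %*% effects$gamma_af)
  } else {
    if (is.null(cohort$anc1)) {
      genetic <- drop(cohort$G[, j, drop = FALSE] %*% effects$gamma_eu)
    } else {
      h1 <- cohort$hap1[, j, drop = FALSE]; a1 <- cohort$anc1[, j, drop = FALSE]
      h2m <- cohort$hap2[, j, drop = FALSE]; a2 <- cohort$anc2[, j, drop = FALSE]
      ge <- h1 * a1 + h2m * a2              # European-tract allele count
      ga <- h1 * (1 - a1) + h2m * (1 - a2)  # African-tract allele count
      genetic <- drop(ge %*% effects$gamma_eu + ga %*% effects$gamma_af)
    }
  }
  sigma_g2 <- stats::var(genetic)
  if (!is.finite(sigma_g2) || sigma_g2 <= 0)
    stop("degenerate genetic variance: no polymorphic causal variant with nonzero effect; cannot calibrate heritability")
  sigma_e2 <- (1 - h2) / h2 * sigma_g2
  set.seed(as.integer(seed))
  y <- genetic + stats::rnorm(length(genetic), 0, sqrt(sigma_e2))
  list(y = y, genetic = genetic, sigma_e2 = sigma_e2,
       h2_realized = sigma_g2 / stats::var(y))
}
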