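#' Build a complete simulation study: cohorts, local ancestry, centering
#'
#' Simulates, from one set of Balding-Nichols ancestral frequencies and one
#' shared founder-haplotype pool, (i) a European GWAS training cohort,
#' (ii) a held-out European evaluation cohort for the reference slope
#' beta_Obs.Eu, and (iii) an admixed target cohort. For the admixed cohort
#' it precomputes the whole local-ancestry stack: diploid state
#' probabilities, the 5-Mb / 0.9-posterior mask, regression-estimated
#' background frequencies, and mean-centered ancestry-specific dosages.
#'
#' @param n_admixed,n_eu_train,n_eu_test cohort sizes.
#' @param n_variants number of variants M.
#' @param fst ancestral divergence (default 0.15).
#' @param h2 default trait heritability carried into per-trait configs.
#' @param seed master seed.
#' @param ... further arguments to [simulation_config()] (e.g.
#'   `admix_generations`, `n_founders`, `latent_ar`).
#' @return `anchor_study` list: `config`, `freqs`, `eu_train`, `eu_test`,
#'   `admixed`, `mask`, `freq_fit`, `centered`, `theta`.
#' @export
build_anchor_study <- function(n_admixed = 2000, n_eu_train = 5000,
                               n_eu_test = 2000, n_variants = 5000,
                               fst = 0.15, h2 = 0.6, seed, ...) {
  freqs <- draw_ancestral_frequencies(n_variants, fst, seed)
  base <- simulation_config(n_individuals = n_admixed,
                            n_variants = n_variants, fst = fst, h2 = h2,
                            seed = seed, ...)
  founders <- if (base$ld_blocks) draw_ld_founders(base, freqs) else NULL

  cfg_train <- base; cfg_train$n_individuals <- as.integer(n_eu_train)
  cfg_train$theta_distribution <- 0; cfg_train$seed <- base$seed + 101L
  cfg_test <- base; cfg_test$n_individuals <- as.integer(n_eu_test)
  cfg_test$theta_distribution <- 0; cfg_test$seed <- base$seed + 202L
  cfg_adm <- base; cfg_adm$seed <- base$seed + 303L

  eu_train <- simulate_admixed_genomes(cfg_train, freqs, founders)
  eu_test <- simulate_admixed_genomes(cfg_test, freqs, founders)
  admixed <- simulate_admixed_genomes(cfg_adm, freqs, founders)

  probs <- cohort_state_probs(admixed)
  mask <- mask_segments(probs, admixed$variants)
  freq_fit <- fit_site_frequencies(admixed$G, probs, mask)
  dosages <- expected_ancestry_dosages(
    admixed$hap1, admixed$hap2,
    ancestry_posteriors(admixed)$a1, ancestry_posteriors(admixed)$a2)
  centered <- mean_center_dosages(dosages, probs, freq_fit, mask)

  structure(list(config = base, freqs = freqs, eu_train = eu_train,
                 eu_test = eu_test, admixed = admixed, mask = mask,
                 freq_fit = freq_fit, centered = centered,
                 theta = admixed$theta, seed = seed),
            class = "anchor_study")
}

#' @export
print.anchor_study <- function(x, ...) {
  cat(sprintf("ANCHOR study: %d admixed, %d + %d European, %d variants, FST %g\n",
              nrow(x$admixed$G), nrow(x$eu_train$G), nrow(x$eu_test$G),
              x$config$n_variants, x$config$fst))
  invisible(x)
}

#' Run the full per-trait ANCHOR pipeline on a simulated study
#'
#' For one trait: draw causal variants and (possibly cross-ancestry
#' correlated) effect sizes, simulate phenotypes in all three cohorts, run
#' the GWAS in the European training cohort over the tag panel (causal
#' variants excluded by default, so the PGS tags rather than contains
#' them), LD-clump, score the held-out European cohort to obtain
#' beta_Obs.Eu, decompose the score over the admixed cohort's mean-centered
#' ancestry-specific dosages, fit the decomposition model (omega = 0) with
#' a joint bootstrap, and form the rho estimate.
#'
#' @param study an `anchor_study`.
#' @param trait_seed per-trait seed (controls causal set, effects, noise,
#'   bootstrap).
#' @param rho generating effect-size correlation.
#' @param h2 trait heritability.
#' @param n_causal,placement,effect_dist causal architecture.
#' @param n_boot bootstrap replicates (default 200 at desk scale).
#' @param p1,r2,window_kb clumping parameters.
#' @param exclude_causal drop causal variants from the GWAS/PGS panel.
#' @return list: `estimate` (`rho_estimate`), `fit`, `ref`, `weights`,
#'   `effects`, `causal`.
#' @export
run_trait <- function(study, trait_seed, rho = 1, h2 = 0.6,
                      n_causal = 100L,
                      placement = "uniform", effect_dist = "normal",
                      n_boot = 200L, p1 = 0.05, r2 = 0.1, window_kb = 500,
                      exclude_causal = TRUE) {
  cfg <- study$config
  cfg$n_causal <- as.integer(n_causal)
  cfg$placement <- placement
  cfg$seed <- as.integer(trait_seed)
  variants <- study$admixed$variants

  causal <- select_causal_variants(cfg, variants)
  effects <- draw_effect_sizes(causal, study$freqs, effect_dist, rho,
                               seed = trait_seed + 11L)

  y_train <- simulate_phenotype(study$eu_train, effects, h2,
                                seed = trait_seed + 21L)$y
  y_test <- simulate_phenotype(study$eu_test, effects, h2,
                               seed = trait_seed + 22L)$y
  y_adm <- simulate_phenotype(study$admixed, effects, h2,
                              ancestry_specific = TRUE,
                              seed = trait_seed + 23L)$y

  panel <- if (exclude_causal) setdiff(seq_len(ncol(study$eu_train$G)),
                                       causal)
           else seq_len(ncol(study$eu_train$G))
  gwas <- run_gwas(study$eu_train$G[, panel, drop = FALSE], y_train)
  weights <- ld_clump(gwas, study$eu_train$G[, panel, drop = FALSE],
                      variants[panel, , drop = FALSE],
                      p1 = p1, r2 = r2, window_kb = window_kb)
  weights$variant <- panel[weights$variant]   # back to cohort columns

  pgs_test <- compute_pgs(study$eu_test$G, weights)
  ref <- fit_reference_slope(y_test, pgs_test, n_boot = n_boot,
                             seed = trait_seed + 31L)

  scores <- decompose_pgs(study$centered, weights, theta = study$theta,
                          covariates = cbind(theta = study$theta))
  fit <- bootstrap_fit(y_adm, scores, "fixed_zero", n_boot = n_boot,
                       seed = trait_seed + 32L)
  est <- estimate_rho(fit, ref)
  list(estimate = est, fit = fit, ref = ref, weights = weights,
       effects = effects, causal = causal)
}

#' Run a multi-trait simulation study through the ANCHOR pipeline
#'
#' Repeats [run_trait()] for `n_traits` independent traits on one shared
#' study and summarizes the per-trait rho estimates, their 95% bootstrap
#' CIs, CI coverage of the generating value, and the local-tagging ratios.
#'
#' @inheritParams run_trait
#' @param n_traits number of traits to simulate.
#' @param seed base seed; trait t uses `seed + 1000 t`.
#' @return list: `summary` data frame (one row per trait: `rho`, `ci_lo`,
#'   `ci_hi`, `covered`, `local_ratio`, `beta_eu`, `beta_obs_eu`, `dr2`),
#'   `estimates` (list of `rho_estimate`), `pooled` ([pool_traits()]).
#' @export
run_trait_study <- function(study, n_traits = 50L, rho = 1, h2 = 0.6,
                            n_causal = 100L, placement = "uniform",
                            effect_dist = "normal", n_boot = 200L,
                            p1 = 0.05, r2 = 0.1, window_kb = 500,
                            seed = 1L) {
  rows <- vector("list", n_traits)
  ests <- vector("list", n_traits)
  for (t in seq_len(n_traits)) {
    tr <- run_trait(study, trait_seed = as.integer(seed + 1000 * t),
                    rho = rho, h2 = h2, n_causal = n_causal,
                    placement = placement, effect_dist = effect_dist,
                    n_boot = n_boot, p1 = p1, r2 = r2,
                    window_kb = window_kb)
    e <- tr$estimate
    ests[[t]] <- e
    rows[[t]] <- data.frame(
      trait = t, rho = e$rho,
      ci_lo = if (is.null(e$ci)) NA_real_ else e$ci$rho[1],
      ci_hi = if (is.null(e$ci)) NA_real_ else e$ci$rho[2],
      covered = if (is.null(e$ci)) NA else
        e$ci$rho[1] <= rho && rho <= e$ci$rho[2],
      local_ratio = e$local_ratio, beta_eu = e$beta_eu,
      beta_obs_eu = e$beta_obs_eu, dr2 = tr$ref$delta_r2,
      n_weights = nrow(tr$weights))
  }
  list(summary = do.call(rbind, rows), estimates = ests,
       pooled = pool_traits(ests))
}
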