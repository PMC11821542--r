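# Small in-code fixtures shared across test files.

# tiny admixed cohort with explicit truth tracks, fast to build
tiny_cohort <- function(n = 40, M = 60, seed = 7, theta = 0.5,
                        ld_blocks = FALSE, ...) {
  cfg <- simulation_config(n_individuals = n, n_variants = M,
                           n_causal = min(5L, M), theta_distribution = theta,
                           ld_blocks = ld_blocks, seed = seed, ...)
  freqs <- draw_ancestral_frequencies(M, cfg$fst, seed)
  list(config = cfg, freqs = freqs,
       cohort = simulate_admixed_genomes(cfg, freqs))
}

# deterministic scores object for the decomposition-model tests
toy_scores <- function(n = 200, seed = 1, theta = NULL) {
  set.seed(seed)
  structure(list(epgs = rnorm(n), apgs = rnorm(n),
                 theta = theta %||% runif(n), covariates = NULL),
            class = "decomposed_pgs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
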