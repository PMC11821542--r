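#' Simulation configuration for admixed cohorts
#'
#' Bundles every knob of the synthetic-cohort generator: cohort and marker
#' sizes, causal architecture, heritability, cross-ancestry effect-size
#' correlation, ancestral divergence, admixture history, and the genetic map.
#'
#' @param n_individuals number of diploid individuals to simulate.
#' @param n_variants number of biallelic variants.
#' @param n_causal number of causal variants J (defaults follow the
#'   simulation grid: 100, 1,000 or 10,000 at full scale).
#' @param placement `"uniform"` (J positions drawn without replacement) or
#'   `"clustered"` (half of the causal variants concentrated in J/10
#'   nonoverlapping 10-kb regions, the remainder uniform).
#' @param effect_dist `"normal"` (per-variant effect s.d. 1) or
#'   `"frequency_scaled"` (s.d. `[2 p (1-p)]^(-0.25)`, the LDAK-style
#'   convention giving rarer variants larger effects).
#' @param h2 narrow-sense heritability in (0, 1].
#' @param rho cross-ancestry correlation of causal effect sizes, in [-1, 1].
#' @param fst Balding-Nichols divergence between the two ancestral
#'   populations, in [0, 1). Default 0.15, typical of African-European
#'   differentiation.
#' @param admix_generations g, generations since admixture; ancestry tract
#'   breakpoints arise as a Poisson process at rate g per Morgan.
#' @param theta_distribution either a numeric vector of per-individual
#'   global African-ancestry fractions (recycled to `n_individuals`), or a
#'   list `list(edges=, probs=)` describing a mixture of uniforms over
#'   ancestry bins. The default mirrors the occupancy of the five ancestry
#'   bins of the admixed UK Biobank subset the method was developed on.
#' @param genetic_map optional data frame with columns `chrom`, `pos`
#'   (1-based bp) and `cm`; when `NULL` a map is laid out by
#'   [default_genetic_map()].
#' @param n_chrom,chrom_length_bp,cm_per_mb layout of the default map.
#' @param ld_blocks logical; simulate within-block linkage disequilibrium by
#'   founder-haplotype copying (needed for tag-SNP scoring to be
#'   meaningful). Blocks are `block_length_bp` wide.
#' @param block_length_bp haplotype-block length in bp (default 50 kb).
#' @param n_founders founder haplotypes per population per block.
#' @param latent_ar within-block latent AR(1) correlation between adjacent
#'   sites used when drawing founder haplotypes; controls tag r-squared.
#' @param ancestry_error rate at which truth-track local-ancestry posteriors
#'   are blurred toward 0.5 (0 = perfect truth tracks).
#' @param seed integer seed; mandatory so cohorts are reproducible.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_admixed_genomes()], [scenario_grid()]
#' @export
simulation_config <- function(n_individuals,
                              n_variants,
                              n_causal = 100L,
                              placement = c("uniform", "clustered"),
                              effect_dist = c("normal", "frequency_scaled"),
                              h2 = 0.6,
                              rho = 1,
                              fst = 0.15,
                              admix_generations = 6,
                              theta_distribution = default_theta_distribution(),
                              genetic_map = NULL,
                              n_chrom = 5L,
                              chrom_length_bp = NULL,
                              cm_per_mb = 1,
                              ld_blocks = TRUE,
                              block_length_bp = 5e4,
                              n_founders = 40L,
                              latent_ar = 0.85,
                              ancestry_error = 0,
                              seed) {
  placement <- match.arg(placement)
  effect_dist <- match.arg(effect_dist)
  if (missing(seed)) stop("`seed` is mandatory in a simulation config")
  stopifnot(n_individuals >= 1, n_variants >= 1)
  if (!(h2 > 0 && h2 <= 1)) stop("`h2` must lie in (0, 1]")
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1]")
  if (fst < 0 || fst >= 1) stop("`fst` must lie in [0, 1)")
  if (n_causal > n_variants) stop("`n_causal` exceeds `n_variants`")
  if (admix_generations <= 0) stop("`admix_generations` must be positive")
  if (is.numeric(theta_distribution)) {
    if (any(theta_distribution < 0 | theta_distribution > 1))
      stop("theta values must lie in [0, 1]")
  }

  if (is.null(genetic_map)) {
    genetic_map <- default_genetic_map(n_variants, n_chrom = n_chrom,
                                       chrom_length_bp = chrom_length_bp,
                                       cm_per_mb = cm_per_mb)
  } else {
    validate_genetic_map(genetic_map, n_variants)
  }

  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    n_causal = as.integer(n_causal),
    placement = placement,
    effect_dist = effect_dist,
    h2 = h2, rho = rho, fst = fst,
    admix_generations = admix_generations,
    theta_distribution = theta_distribution,
    genetic_map = genetic_map,
    ld_blocks = isTRUE(ld_blocks),
    block_length_bp = block_length_bp,
    n_founders = as.integer(n_founders),
    latent_ar = latent_ar,
    ancestry_error = ancestry_error,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Admixture simulation config:\n")
  cat(sprintf("  %d individuals x %d variants, J = %d (%s, %s effects)\n",
              x$n_individuals, x$n_variants, x$n_causal, x$placement,
              x$effect_dist))
  cat(sprintf("  h2 = %g, rho = %g, FST = %g, g = %g, seed = %d\n",
              x$h2, x$rho, x$fst, x$admix_generations, x$seed))
  invisible(x)
}

#' Default global-ancestry mixture
#'
#' African-ancestry fraction theta is drawn uniformly within one of five
#' ancestry bins, with bin probabilities matching the occupancies of the
#' admixed reference subset (373/560/475/2,556/4,039 of 8,003 individuals in
#' bins \[0.1,0.35\], (0.35,0.55\], (0.55,0.78\], (0.78,0.95\], (0.95,1\]).
#'
#' @return a list with `edges` (length 6) and `probs` (length 5).
#' @export
default_theta_distribution <- function() {
  list(edges = c(0.1, 0.35, 0.55, 0.78, 0.95, 1),
       probs = c(373, 560, 475, 2556, 4039) / 8003)
}

draw_theta <- function(theta_distribution, n) {
  if (is.numeric(theta_distribution)) {
    return(rep_len(theta_distribution, n))
  }
  edges <- theta_distribution$edges
  probs <- theta_distribution$probs
  stopifnot(length(edges) == length(probs) + 1)
  bin <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  stats::runif(n, min = edges[bin], max = edges[bin + 1])
}

#' Lay out an evenly spaced genetic map
#'
#' Variants are spread uniformly over `n_chrom` chromosomes with a constant
#' recombination rate of `cm_per_mb`.
#'
#' @inheritParams simulation_config
#' @param n_variants number of variants to place.
#' @return data frame with columns `chrom`, `pos`, `cm`.
#' @export
default_genetic_map <- function(n_variants, n_chrom = 5L,
                                chrom_length_bp = NULL, cm_per_mb = 1) {
  n_variants <- as.integer(n_variants)
  n_chrom <- as.integer(min(n_chrom, n_variants))
  per <- diff(round(seq(0, n_variants, length.out = n_chrom + 1)))
  if (is.null(chrom_length_bp)) {
    # 10 kb spacing gives ~5 variants per 50-kb LD block
    chrom_length_bp <- max(per) * 1e4
  }
  chrom <- rep(seq_len(n_chrom), per)
  pos <- unlist(lapply(per, function(k) {
    as.integer(round(seq(1e4, chrom_length_bp, length.out = k)))
  }), use.names = FALSE)
  data.frame(chrom = chrom, pos = pos, cm = pos / 1e6 * cm_per_mb)
}

validate_genetic_map <- function(map, n_variants) {
  if (nrow(map) == 0) stop("genetic map is empty")
  if (nrow(map) != n_variants)
    stop("genetic map must have one row per variant")
  if (!all(c("chrom", "pos", "cm") %in% names(map)))
    stop("genetic map needs columns chrom, pos, cm")
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map))))
    stop("genetic map must be sorted by (chrom, pos)")
  bad <- unlist(tapply(map$cm, map$chrom, function(x) any(diff(x) < 0)))
  if (any(bad)) stop("cM positions must be nondecreasing within chromosome")
  invisible(map)
}

#' Enumerate the factorial simulation scenario grid
#'
#' The full factorial of causal counts \{100, 1,000, 10,000\} x placement
#' \{uniform, clustered\} x effect distribution \{normal, frequency-scaled\}
#' x heritability \{0.3, 0.6\} — 24 scenarios in total.
#'
#' @param n_causal,placement,effect_dist,h2 factor levels to cross.
#' @return a data frame with one row per scenario and a `label` column of the
#'   form `#causal:1K(uniform)S:0 h2:0.6`.
#' @export
scenario_grid <- function(n_causal = c(100L, 1000L, 10000L),
                          placement = c("uniform", "clustered"),
                          effect_dist = c("normal", "frequency_scaled"),
                          h2 = c(0.3, 0.6)) {
  g <- expand.grid(n_causal = n_causal, placement = placement,
                   effect_dist = effect_dist, h2 = h2,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fmt_j <- function(j) ifelse(j >= 1000, paste0(j / 1000, "K"), as.character(j))
  g$label <- sprintf("#causal:%s(%s)S:%s h2:%g", fmt_j(g$n_causal),
                     g$placement,
                     ifelse(g$effect_dist == "normal", "0", "0.5"), g$h2)
  g
}
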