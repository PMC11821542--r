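#' Simulate phased admixed genomes with ancestry tracts
#'
#' Each haplotype is a mosaic of European / African ancestry tracts:
#' breakpoints arise as a Poisson process at rate `admix_generations` per
#' Morgan along the genetic map (restarting on each chromosome) and every
#' tract is African with probability `theta_i`, the individual's global
#' African-ancestry fraction. Alleles are drawn from the tract's ancestral
#' population, either independently per site (Bernoulli at the
#' Balding-Nichols frequency) or, when `ld_blocks` is on, by copying one of
#' `n_founders` population-specific founder haplotypes per 50-kb block,
#' which induces realistic within-block linkage disequilibrium that differs
#' stochastically between the two ancestral backgrounds. With LD blocks,
#' ancestry switches are snapped to block boundaries so the recorded truth
#' track always matches the copying process.
#'
#' @param config a [simulation_config()].
#' @param freqs an `ancestral_freqs` object covering all variants.
#' @param founders optional founder pool from [draw_ld_founders()]; pass the
#'   same pool to several cohorts so they share LD structure (e.g. a
#'   European reference cohort and the European segments of an admixed
#'   cohort). Drawn from the config seed when NULL and `ld_blocks` is on.
#' @return an object of class `admix_cohort`: list with integer haplotype
#'   matrices `hap1`, `hap2` (n x M), truth local-ancestry indicators
#'   `anc1`, `anc2` (1 = European), per-haplotype European posteriors
#'   accessible via [ancestry_posteriors()], genotypes `G = hap1 + hap2`,
#'   realized global African fraction `theta`, and a `variants` table.
#' @export
simulate_admixed_genomes <- function(config, freqs, founders = NULL) {
  stopifnot(inherits(config, "sim_config"))
  map <- config$genetic_map
  if (is.null(map) || nrow(map) == 0) stop("empty genetic map")
  M <- config$n_variants
  if (nrow(freqs) < M) stop("frequencies do not cover all variants")
  n <- config$n_individuals
  g <- config$admix_generations

  set.seed(config$seed)
  theta <- draw_theta(config$theta_distribution, n)
  if (any(theta < 0 | theta > 1)) stop("theta parameters outside [0, 1]")
  seed_haps <- config$seed + 13L   # haplotype draws independent of whether
                                   # the founder pool is drawn or supplied

  # block structure: LD copying snaps ancestry to block boundaries so the
  # truth track always matches the copying unit; without LD blocks the
  # ancestry track is resolved per site
  if (config$ld_blocks) {
    block <- block_index(map, config$block_length_bp)
    block_cm <- as.numeric(tapply(map$cm, block, stats::median))
    block_chrom <- as.integer(tapply(map$chrom, block, function(x) x[1]))
  } else {
    block <- seq_len(M)
    block_cm <- map$cm
    block_chrom <- map$chrom
  }
  chroms <- unique(map$chrom)
  cm_lo <- tapply(map$cm, map$chrom, min)[as.character(chroms)]
  cm_hi <- tapply(map$cm, map$chrom, max)[as.character(chroms)]

  if (config$ld_blocks && is.null(founders)) {
    founders <- draw_ld_founders(config, freqs)
  } else if (!config$ld_blocks) founders <- NULL

  set.seed(seed_haps)
  pure_european <- all(theta == 0)
  if (pure_european && !config$ld_blocks) {
    # vectorized fast path: no tracts to simulate
    hap1 <- matrix(stats::rbinom(n * M, 1L, rep(freqs$f_eu[seq_len(M)],
                                                each = n)), n, M)
    hap2 <- matrix(stats::rbinom(n * M, 1L, rep(freqs$f_eu[seq_len(M)],
                                                each = n)), n, M)
    anc1 <- anc2 <- NULL
  } else {
    hap1 <- matrix(0L, n, M); hap2 <- matrix(0L, n, M)
    anc1 <- matrix(1L, n, M); anc2 <- matrix(1L, n, M)
    for (i in seq_len(n)) {
      for (h in 1:2) {
        af <- draw_tract_ancestry(theta[i], g, chroms, cm_lo, cm_hi,
                                  block_chrom, block_cm)
        af_site <- af[block]
        if (config$ld_blocks) {
          allele <- copy_founder_alleles(founders, af, block, M,
                                         config$n_founders)
        } else {
          f_site <- ifelse(af_site == 1L, freqs$f_af[seq_len(M)],
                           freqs$f_eu[seq_len(M)])
          allele <- stats::rbinom(M, 1L, f_site)
        }
        if (h == 1) { hap1[i, ] <- allele; anc1[i, ] <- 1L - af_site }
        else        { hap2[i, ] <- allele; anc2[i, ] <- 1L - af_site }
      }
    }
  }

  if (pure_european) { anc1 <- NULL; anc2 <- NULL }  # implicit all-European
  G <- hap1 + hap2
  realized_theta <- if (is.null(anc1)) rep(0, n) else
    1 - (rowMeans(anc1) + rowMeans(anc2)) / 2

  variants <- data.frame(
    chrom = map$chrom, pos = map$pos, cm = map$cm,
    id = paste0(map$chrom, ":", map$pos),
    ref = "A", alt = "G",
    f_eu = freqs$f_eu[seq_len(M)], f_af = freqs$f_af[seq_len(M)])

  structure(list(hap1 = hap1, hap2 = hap2, anc1 = anc1, anc2 = anc2,
                 G = G, theta = realized_theta, theta_target = theta,
                 variants = variants, block = block,
                 ancestry_error = config$ancestry_error,
                 seed = config$seed),
            class = "admix_cohort")
}

#' @export
print.admix_cohort <- function(x, ...) {
  cat(sprintf("Admixed cohort: %d individuals x %d variants, mean African ancestry %.3f\n",
              nrow(x$G), ncol(x$G), mean(x$theta)))
  invisible(x)
}

block_index <- function(map, block_length_bp) {
  key <- paste0(map$chrom, "_", (map$pos - 1) %/% block_length_bp)
  as.integer(factor(key, levels = unique(key)))
}

#' Draw the founder-haplotype pools that induce LD blocks
#'
#' Per population, `n_founders` founder haplotypes are drawn from a latent
#' Gaussian with AR(1) correlation `latent_ar` between adjacent sites
#' within each block, thresholded at qnorm(f) so each site's marginal
#' allele frequency is its Balding-Nichols frequency. Pools are drawn
#' independently for the two populations, so realized LD differs
#' stochastically between ancestral backgrounds — the "local" source of PGS
#' nonportability. Seeded at `config$seed + 7777` so the same config always
#' yields the same pool.
#'
#' @inheritParams simulate_admixed_genomes
#' @return list with 0/1 matrices `eu`, `af` (founders x variants).
#' @export
draw_ld_founders <- function(config, freqs) {
  M <- config$n_variants
  block <- block_index(config$genetic_map, config$block_length_bp)
  set.seed(config$seed + 7777L)
  list(eu = draw_founder_pool(config$n_founders, freqs$f_eu[seq_len(M)],
                              block, config$latent_ar),
       af = draw_founder_pool(config$n_founders, freqs$f_af[seq_len(M)],
                              block, config$latent_ar))
}

# founder haplotypes per population: latent Gaussian AR(1) within block,
# thresholded at qnorm(f) so P(allele = 1) = f marginally
draw_founder_pool <- function(K, f, block, ar) {
  M <- length(f)
  z <- matrix(0, K, M)
  z[, 1] <- stats::rnorm(K)
  if (M > 1) {
    for (s in 2:M) {
      e <- stats::rnorm(K)
      z[, s] <- if (block[s] == block[s - 1])
        ar * z[, s - 1] + sqrt(1 - ar^2) * e else e
    }
  }
  thr <- stats::qnorm(f)
  (z < rep(thr, each = K)) + 0L
}

# per-haplotype tract ancestry at block resolution; returns African
# indicator per block (1 = African)
draw_tract_ancestry <- function(theta_af, g, chroms, cm_lo, cm_hi,
                                block_chrom, block_cm) {
  af <- integer(length(block_cm))
  for (ci in seq_along(chroms)) {
    L <- (cm_hi[ci] - cm_lo[ci]) / 100      # Morgans
    nb <- stats::rpois(1, g * L)
    brk <- sort(stats::runif(nb, cm_lo[ci], cm_hi[ci]))
    anc <- stats::rbinom(nb + 1, 1, theta_af)
    sel <- block_chrom == chroms[ci]
    tract <- findInterval(block_cm[sel], brk) + 1L
    af[sel] <- anc[tract]
  }
  af
}

copy_founder_alleles <- function(founders, af_block, block, M, K) {
  n_block <- length(af_block)
  fid <- sample.int(K, n_block, replace = TRUE)
  idx <- cbind(fid[block], seq_len(M))
  af_site <- af_block[block]
  allele <- founders$eu[idx]
  if (any(af_site == 1L)) {
    sel <- af_site == 1L
    allele[sel] <- founders$af[idx[sel, , drop = FALSE]]
  }
  allele
}

#' Per-haplotype European-ancestry posteriors of a simulated cohort
#'
#' Returns the truth tracks, optionally blurred toward 0.5 by the cohort's
#' configured `ancestry_error` rate e: posterior = (1-e) truth + e/2.
#'
#' @param cohort an `admix_cohort`.
#' @return list with matrices `a1`, `a2` of European posteriors in \[0, 1\].
#' @export
ancestry_posteriors <- function(cohort) {
  a1 <- cohort$anc1; a2 <- cohort$anc2
  if (is.null(a1)) {
    a1 <- matrix(1, nrow(cohort$G), ncol(cohort$G))
    a2 <- a1
  }
  e <- cohort$ancestry_error
  if (e > 0) {
    a1 <- (1 - e) * a1 + e / 2
    a2 <- (1 - e) * a2 + e / 2
  }
  list(a1 = a1, a2 = a2)
}
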