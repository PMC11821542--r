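#' Select causal variants
#'
#' Uniform placement draws J distinct variant indices without replacement.
#' Clustered placement selects J/10 nonoverlapping 10-kb regions, places
#' J/2 causal variants over them by a symmetric multinomial (each region
#' averaging five), and distributes the remaining J/2 uniformly along the
#' genome.
#'
#' @param config a [simulation_config()] (fields `n_causal`, `placement`).
#' @param variant_table data frame with `chrom` and `pos` columns.
#' @param region_bp clustered-region width (default 10 kb).
#' @return sorted integer vector of causal variant indices; attribute
#'   `in_region` marks the clustered half.
#' @export
select_causal_variants <- function(config, variant_table,
                                   region_bp = 1e4) {
  J <- config$n_causal
  M <- nrow(variant_table)
  if (J > M) stop(sprintf("J = %d exceeds the %d available variants", J, M))
  if (J == 0) return(integer(0))
  set.seed(config$seed + 1L)
  if (config$placement == "uniform") {
    idx <- sort(sample.int(M, J))
    attr(idx, "in_region") <- rep(FALSE, J)
    return(idx)
  }

  n_region <- max(1L, round(J / 10))
  n_clustered <- round(J / 2)
  tile <- paste0(variant_table$chrom, "_",
                 (variant_table$pos - 1) %/% region_bp)
  tile <- factor(tile, levels = unique(tile))
  tiles <- split(seq_len(M), tile)
  if (length(tiles) < n_region)
    stop(sprintf("clustered placement needs %d nonoverlapping %d-bp regions but only %d contain variants",
                 n_region, as.integer(region_bp), length(tiles)))
  regions <- tiles[sample.int(length(tiles), n_region)]
  cap <- lengths(regions)
  if (sum(cap) < n_clustered)
    stop(sprintf("the %d selected regions hold %d variants; %d clustered causal variants requested",
                 n_region, sum(cap), n_clustered))
  # symmetric multinomial, repaired so no region exceeds its variant count
  counts <- as.vector(stats::rmultinom(1, n_clustered,
                                       rep(1 / n_region, n_region)))
  repeat {
    over <- counts > cap
    if (!any(over)) break
    excess <- sum(counts[over] - cap[over])
    counts[over] <- cap[over]
    room <- which(counts < cap)
    add <- as.vector(stats::rmultinom(1, excess,
                                      rep(1 / length(room), length(room))))
    counts[room] <- counts[room] + add
  }
  clustered <- unlist(mapply(function(ids, k) {
    if (k == 0) integer(0) else ids[sample.int(length(ids), k)]
  }, regions, counts, SIMPLIFY = FALSE), use.names = FALSE)

  rest_pool <- setdiff(seq_len(M), clustered)
  n_rest <- J - length(clustered)
  if (length(rest_pool) < n_rest)
    stop("not enough variants outside the clustered regions")
  rest <- rest_pool[sample.int(length(rest_pool), n_rest)]
  idx <- c(clustered, rest)
  ord <- order(idx)
  out <- idx[ord]
  attr(out, "in_region") <- c(rep(TRUE, length(clustered)),
                              rep(FALSE, n_rest))[ord]
  attr(out, "regions") <- regions
  out
}

#' Draw cross-ancestry-correlated causal effect sizes
#'
#' European-background effects are gamma_E ~ N(0, sigma_j^2) with sigma_j = 1
#' (`normal`) or sigma_j = \[2 p_j (1 - p_j)\]^(-0.25) (`frequency_scaled`,
#' the LDAK-style convention: rarer variants get larger effects). The
#' African-background effect is generated conditionally,
#' gamma_A = rho gamma_E + sigma_j sqrt(1 - rho^2) Z with Z standard normal,
#' so marginally gamma_A ~ N(0, sigma_j^2) and corr(gamma_E, gamma_A) = rho.
#'
#' @param causal integer vector of causal variant indices.
#' @param freqs `ancestral_freqs` (or any data frame with the column named
#'   by `scale_freq`).
#' @param effect_dist `"normal"` or `"frequency_scaled"`.
#' @param rho effect-size correlation in \[-1, 1\].
#' @param seed integer seed.
#' @param scale_freq which frequency column scales the effects (default the
#'   European/GWAS background, `"f_eu"`).
#' @return data frame with columns `index`, `sigma`, `gamma_eu`, `gamma_af`.
#' @export
draw_effect_sizes <- function(causal, freqs,
                              effect_dist = c("normal", "frequency_scaled"),
                              rho, seed, scale_freq = "f_eu") {
  effect_dist <- match.arg(effect_dist)
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1]")
  J <- length(causal)
  set.seed(as.integer(seed))
  if (effect_dist == "normal") {
    sigma <- rep(1, J)
  } else {
    p <- freqs[[scale_freq]][causal]
    if (any(p <= 0 | p >= 1))
      stop("frequency scaling undefined at p in {0, 1}")
    sigma <- (2 * p * (1 - p))^(-0.25)
  }
  gamma_eu <- stats::rnorm(J) * sigma
  gamma_af <- rho * gamma_eu + sigma * sqrt(1 - rho^2) * stats::rnorm(J)
  data.frame(index = as.integer(causal), sigma = sigma,
             gamma_eu = gamma_eu, gamma_af = gamma_af)
}
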