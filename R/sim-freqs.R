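#' Draw ancestral allele frequencies under a Balding-Nichols model
#'
#' For each variant an ancestral frequency is drawn Uniform(0.05, 0.95) and
#' the two population frequencies `f_eu`, `f_af` are independent
#' Beta(p (1-F)/F, (1-p)(1-F)/F) deviates around it, so that
#' E\[(f_eu - f_af)^2\] = 2 F p (1-p). Frequencies are clipped to
#' \[0.01, 0.99\] to avoid monomorphic sites.
#'
#' @param n_variants number of variants.
#' @param fst divergence parameter F in \[0, 1); `fst = 0` returns identical
#'   frequencies in both populations.
#' @param seed integer seed.
#' @return object of class `ancestral_freqs`: data frame with columns
#'   `f_anc`, `f_eu`, `f_af`.
#' @export
draw_ancestral_frequencies <- function(n_variants, fst, seed) {
  if (fst < 0 || fst >= 1) stop("`fst` must lie in [0, 1)")
  stopifnot(n_variants >= 1)
  set.seed(as.integer(seed))
  p <- stats::runif(n_variants, 0.05, 0.95)
  if (fst == 0) {
    f_eu <- f_af <- p
  } else {
    k <- (1 - fst) / fst
    f_eu <- stats::rbeta(n_variants, k * p, k * (1 - p))
    f_af <- stats::rbeta(n_variants, k * p, k * (1 - p))
  }
  out <- data.frame(f_anc = p,
                    f_eu = pmin(pmax(f_eu, 0.01), 0.99),
                    f_af = pmin(pmax(f_af, 0.01), 0.99))
  class(out) <- c("ancestral_freqs", class(out))
  out
}

#' Hudson FST estimator from population frequency pairs
#'
#' Ratio-of-sums form: sum (p1-p2)^2 over sum \[p1(1-p2) + p2(1-p1)\]. With
#' population (not sample) frequencies the sample-size corrections vanish.
#'
#' @param f1,f2 numeric vectors of allele frequencies.
#' @return a single FST estimate.
#' @export
hudson_fst <- function(f1, f2) {
  stopifnot(length(f1) == length(f2))
  num <- (f1 - f2)^2
  den <- f1 * (1 - f2) + f2 * (1 - f1)
  sum(num) / sum(den)
}
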