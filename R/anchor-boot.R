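#' Bootstrap an ANCHOR fit
#'
#' Resamples individuals with replacement, refits, and attaches equal-tailed
#' percentile confidence intervals for every reported quantity. Replicates
#' that degenerate (constant resampled phenotype or a fitting error) are
#' dropped and counted.
#'
#' @inheritParams fit_anchor
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return the point `anchor_fit` augmented with `boot` (replicate data
#'   frame), `ci` (named list of lower/upper bounds), `n_boot`,
#'   `n_boot_dropped`, `seed`.
#' @export
bootstrap_fit <- function(Y, scores, omega_mode = c("fixed_zero", "free"),
                          n_boot = 1000L, seed = 1L, conf = 0.95,
                          n_grid = 1000L) {
  omega_mode <- match.arg(omega_mode)
  if (n_boot < 2) stop("`n_boot` must be at least 2")
  point <- fit_anchor(Y, scores, omega_mode, n_grid = n_grid)
  n <- length(Y)
  set.seed(as.integer(seed))
  idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  reps <- vector("list", n_boot)
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    ii <- idx_mat[, b]
    sub <- subset_scores(scores, ii)
    fb <- tryCatch(fit_anchor(Y[ii], sub, omega_mode, n_grid = n_grid),
                   error = function(e) NULL)
    if (is.null(fb)) { dropped <- dropped + 1L; next }
    reps[[b]] <- data.frame(I = fb$I, beta_eu = fb$beta_eu,
                            beta_af = fb$beta_af, omega = fb$omega,
                            beta_eu_af = fb$beta_eu_af,
                            beta_af_af = fb$beta_af_af)
  }
  boot <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  alpha <- (1 - conf) / 2
  point$ci <- lapply(boot, function(v)
    stats::quantile(v, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE))
  point$boot <- boot
  point$n_boot <- n_boot
  point$n_boot_dropped <- dropped
  point$seed <- as.integer(seed)
  point$conf <- conf
  point
}

subset_scores <- function(scores, ii) {
  structure(list(
    epgs = scores$epgs[ii], apgs = scores$apgs[ii],
    theta = if (is.null(scores$theta)) NULL else scores$theta[ii],
    covariates = if (is.null(scores$covariates)) NULL
                 else as.matrix(scores$covariates)[ii, , drop = FALSE]),
    class = "decomposed_pgs")
}

#' Fit the model independently within global-ancestry bins
#'
#' Bins individuals by global African-ancestry fraction (default edges
#' \[0.1, 0.35\], (0.35, 0.55\], (0.55, 0.78\], (0.78, 0.95\], (0.95, 1\]);
#' ancestry varies little within a bin, so omega is fixed at 0. Individuals
#' in the top bin are effectively 100% African and are fitted with the APGS
#' alone. Bins below a configurable size floor are skipped with a warning.
#'
#' @inheritParams fit_anchor
#' @param bins increasing vector of bin edges (first bin closed on both
#'   sides).
#' @param min_n minimal bin size (default 30).
#' @param n_boot bootstrap replicates per bin (0 disables).
#' @param seed integer seed.
#' @return list with `fits` (per-bin fit or NULL) and `summary` data frame
#'   (`bin`, `lo`, `hi`, `n`, `beta_eu`, `beta_af` and their CIs).
#' @export
bin_and_fit <- function(Y, scores, bins = c(0.1, 0.35, 0.55, 0.78, 0.95, 1),
                        min_n = 30L, n_boot = 0L, seed = 1L) {
  theta <- scores$theta
  if (is.null(theta)) stop("binned fitting needs `theta` in the scores")
  nb <- length(bins) - 1
  bin_id <- cut(theta, bins, include.lowest = TRUE, labels = FALSE)
  fits <- vector("list", nb)
  rows <- vector("list", nb)
  for (k in seq_len(nb)) {
    ii <- which(!is.na(bin_id) & bin_id == k)
    row <- data.frame(bin = k, lo = bins[k], hi = bins[k + 1],
                      n = length(ii), beta_eu = NA_real_, beta_af = NA_real_,
                      beta_eu_lo = NA_real_, beta_eu_hi = NA_real_,
                      beta_af_lo = NA_real_, beta_af_hi = NA_real_)
    if (length(ii) < min_n) {
      if (length(ii) > 0)
        warning(sprintf("bin %d has n = %d < %d; skipped", k, length(ii),
                        min_n))
      rows[[k]] <- row
      next
    }
    sub <- subset_scores(scores, ii)
    top_bin <- k == nb
    fit <- fit_bin(Y[ii], sub, apgs_only = top_bin, n_boot = n_boot,
                   seed = seed + k)
    fits[[k]] <- fit
    row$beta_eu <- fit$beta_eu; row$beta_af <- fit$beta_af
    if (!is.null(fit$ci)) {
      if (!top_bin) {
        row$beta_eu_lo <- fit$ci$beta_eu[1]; row$beta_eu_hi <- fit$ci$beta_eu[2]
      }
      row$beta_af_lo <- fit$ci$beta_af[1]; row$beta_af_hi <- fit$ci$beta_af[2]
    }
    rows[[k]] <- row
  }
  list(fits = fits, summary = do.call(rbind, rows))
}

# omega = 0 fit within one ancestry bin; the top (near-100% African) bin
# carries almost no European-segment signal, so only the APGS enters
fit_bin <- function(Y, scores, apgs_only, n_boot = 0L, seed = 1L) {
  fit_one <- function(Y, scores) {
    covs <- scores$covariates
    E <- scores$epgs; A <- scores$apgs
    if (!is.null(covs)) {
      covs <- as.matrix(covs)
      E <- residualize(E, covs); A <- residualize(A, covs)
    }
    X <- if (apgs_only) cbind(1, A, covs) else cbind(1, E, A, covs)
    f <- stats::lm.fit(X, Y)
    cf <- f$coefficients
    if (apgs_only)
      list(I = unname(cf[1]), beta_eu = NA_real_, beta_af = unname(cf[2]))
    else
      list(I = unname(cf[1]), beta_eu = unname(cf[2]),
           beta_af = unname(cf[3]))
  }
  out <- fit_one(Y, scores)
  out$omega <- 0
  out$n <- length(Y)
  out$apgs_only <- apgs_only
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    reps <- replicate(n_boot, {
      ii <- sample.int(length(Y), replace = TRUE)
      r <- tryCatch(fit_one(Y[ii], subset_scores(scores, ii)),
                    error = function(e) list(beta_eu = NA, beta_af = NA))
      c(r$beta_eu, r$beta_af)
    })
    out$ci <- list(
      beta_eu = stats::quantile(reps[1, ], c(0.025, 0.975), names = FALSE,
                                na.rm = TRUE),
      beta_af = stats::quantile(reps[2, ], c(0.025, 0.975), names = FALSE,
                                na.rm = TRUE))
  }
  class(out) <- "anchor_fit"
  out
}
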