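#' Decompose a polygenic score into ancestry-specific components
#'
#' `EPGS_i = sum_j w_j Gbar_E_ij` and `APGS_i = sum_j w_j Gbar_A_ij`, the
#' portions of the PGS accumulated over European- and African-ancestry
#' segments, computed from mean-centered ancestry-specific dosages
#' ([mean_center_dosages()]). When the centering frequencies were fitted on
#' the same cohort, `sum_i (EPGS_i + APGS_i) = 0`.
#'
#' @param centered list with matrices `GE`, `GA` (mean-centered).
#' @param weights `pgs_weights` table; matched by column index (`variant`).
#' @param theta optional per-individual global African-ancestry fraction.
#' @param covariates optional covariate matrix carried along for fitting.
#' @return `decomposed_pgs` list: `epgs`, `apgs`, `theta`, `covariates`.
#' @export
decompose_pgs <- function(centered, weights, theta = NULL,
                          covariates = NULL) {
  idx <- weights$variant
  keep <- !is.na(idx) & idx >= 1 & idx <= ncol(centered$GE)
  if (!any(keep)) stop("no weight variant overlaps the cohort")
  idx <- idx[keep]; w <- weights$weight[keep]
  epgs <- drop(centered$GE[, idx, drop = FALSE] %*% w)
  apgs <- drop(centered$GA[, idx, drop = FALSE] %*% w)
  structure(list(epgs = epgs, apgs = apgs, theta = theta,
                 covariates = covariates, n_weights = length(idx)),
            class = "decomposed_pgs")
}

#' Residualize a vector on covariates
#'
#' OLS residual of `x` on the covariates plus an intercept; the result has
#' mean zero and is orthogonal to every covariate column.
#'
#' @param x numeric vector.
#' @param covariates numeric matrix (or NULL: demeaning only).
#' @return residual vector.
#' @export
residualize <- function(x, covariates = NULL) {
  X <- cbind(Intercept = rep(1, length(x)), covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariates; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qx, x)
}

#' Fit the ancestry-decomposed PGS model
#'
#' Fits `Y_i = I + (beta_Eu EPGS_i + beta_Af APGS_i)(1 + omega theta_i) +
#' covariates + eps_i`. With `omega_mode = "fixed_zero"` the model is linear
#' and fitted by OLS. With `"free"` it is linear conditional on the ratio
#' `r = beta_Eu / (beta_Eu + beta_Af)`, so a grid of `n_grid` values of r in
#' \[0, 1\] is searched: for each r the composite score
#' `Z = r EPGS + (1 - r) APGS` enters `Y = I + a Z + b (Z theta) + covs`,
#' and the grid point minimizing the residual sum of squares gives
#' `beta_Eu = a r`, `beta_Af = a (1 - r)`, `omega = b / a`. When the
#' composite slope `a` is numerically zero omega is unidentifiable and
#' flagged. Projections to 100% African ancestry are
#' `beta_eu_af = beta_Eu (1 + omega)` and `beta_af_af = beta_Af (1 + omega)`
#' (theta is the African fraction, so 100% European ancestry is theta = 0).
#'
#' When covariates are supplied, EPGS and APGS are first residualized on
#' them (with intercept) and the covariates also enter the fit; without
#' covariates the scores are used as-is.
#'
#' @param Y phenotype vector.
#' @param scores a `decomposed_pgs` (fields `epgs`, `apgs`, `theta`,
#'   `covariates`).
#' @param omega_mode `"fixed_zero"` or `"free"`.
#' @param n_grid grid size for the free-omega ratio search (default 1000).
#' @return `anchor_fit` list: `I`, `beta_eu`, `beta_af`, `omega`,
#'   `beta_eu_af`, `beta_af_af`, `ratio`, `sse`, `omega_identifiable`,
#'   `omega_mode`, `n`.
#' @export
fit_anchor <- function(Y, scores, omega_mode = c("fixed_zero", "free"),
                       n_grid = 1000L) {
  omega_mode <- match.arg(omega_mode)
  n <- length(Y)
  if (n < 10) stop("need at least 10 individuals")
  if (stats::var(Y) < 1e-14) stop("constant phenotype")
  E <- scores$epgs; A <- scores$apgs
  stopifnot(length(E) == n, length(A) == n)
  covs <- scores$covariates
  if (!is.null(covs)) {
    covs <- as.matrix(covs)
    E <- residualize(E, covs)
    A <- residualize(A, covs)
  }

  if (omega_mode == "fixed_zero") {
    X <- cbind(1, E, A, covs)
    fit <- stats::lm.fit(X, Y)
    cf <- fit$coefficients
    out <- list(I = unname(cf[1]), beta_eu = unname(cf[2]),
                beta_af = unname(cf[3]), omega = 0,
                ratio = NA_real_, sse = sum(fit$residuals^2),
                omega_identifiable = NA)
  } else {
    theta <- scores$theta
    if (is.null(theta)) stop("free-omega fit needs `theta` in the scores")
    grid <- seq(0, 1, length.out = n_grid)
    best <- list(sse = Inf)
    for (r in grid) {
      Z <- r * E + (1 - r) * A
      X <- cbind(1, Z, Z * theta, covs)
      fit <- stats::lm.fit(X, Y)
      sse <- sum(fit$residuals^2)
      if (!is.finite(sse)) stop("non-finite SSE in grid search")
      if (sse < best$sse)
        best <- list(sse = sse, r = r, cf = fit$coefficients, Z = Z)
    }
    a <- unname(best$cf[2]); b <- unname(best$cf[3])
    sdZ <- stats::sd(best$Z)
    identifiable <- is.finite(a) && sdZ > 0 &&
      abs(a) >= 1e-10 * stats::sd(Y) / sdZ
    out <- list(I = unname(best$cf[1]),
                beta_eu = a * best$r, beta_af = a * (1 - best$r),
                omega = if (identifiable) b / a else NA_real_,
                ratio = best$r, sse = best$sse,
                omega_identifiable = identifiable)
  }
  out$beta_eu_af <- out$beta_eu * (1 + ifelse(is.na(out$omega), 0, out$omega))
  out$beta_af_af <- out$beta_af * (1 + ifelse(is.na(out$omega), 0, out$omega))
  out$omega_mode <- omega_mode
  out$n <- n
  class(out) <- "anchor_fit"
  out
}

#' @export
print.anchor_fit <- function(x, ...) {
  cat(sprintf("ANCHOR fit (omega %s), n = %d\n", x$omega_mode, x$n))
  cat(sprintf("  I = %.4g, beta_Eu = %.4g, beta_Af = %.4g, omega = %.4g\n",
              x$I, x$beta_eu, x$beta_af, x$omega))
  if (!is.null(x$ci)) {
    for (nm in names(x$ci))
      cat(sprintf("  %s 95%% CI: (%.4g, %.4g)\n", nm, x$ci[[nm]][1],
                  x$ci[[nm]][2]))
  }
  invisible(x)
}
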