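#' Per-variant linear-regression GWAS
#'
#' Regresses the (unnormalized) phenotype on each variant's dosage plus a
#' shared covariate design, so effect estimates stay in phenotype units per
#' allele copy. Implemented by Frisch-Waugh projection: phenotype and
#' dosages are residualized on the covariates (plus intercept) once, then
#' per-variant slopes, standard errors and two-sided t-test p-values follow
#' in closed form — numerically identical to fitting `lm()` per variant.
#' Monomorphic variants are flagged missing rather than raising an error.
#'
#' @param G n x M dosage matrix (may contain NA; sites are then fitted on
#'   complete rows for that site).
#' @param Y phenotype vector, length n.
#' @param covariates optional n x q numeric matrix (no intercept column
#'   needed; one is always included).
#' @return `gwas_result` data frame: `variant` (column index), `beta`, `se`,
#'   `p`, `n_used`.
#' @export
run_gwas <- function(G, Y, covariates = NULL) {
  G <- as.matrix(G)
  n <- length(Y)
  stopifnot(nrow(G) == n)
  X <- cbind(Intercept = rep(1, n), covariates)
  q <- ncol(X)
  if (n <= q + 2) stop("too few individuals for the covariate design")

  any_na <- anyNA(G)
  qr_x <- qr(X)
  Yr <- qr.resid(qr_x, Y)
  if (!any_na) {
    Gr <- qr.resid(qr_x, G)
    sxx <- colSums(Gr * Gr)
    sxy <- drop(crossprod(Gr, Yr))
    syy <- sum(Yr * Yr)
    df <- n - q - 1
    beta <- sxy / sxx
    sigma2 <- pmax(syy - beta^2 * sxx, 0) / df
    se <- sqrt(sigma2 / sxx)
    tt <- beta / se
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    mono <- sxx < n * 1e-12
    beta[mono] <- NA_real_; se[mono] <- NA_real_; p[mono] <- NA_real_
    res <- data.frame(variant = seq_len(ncol(G)), beta = beta, se = se,
                      p = p, n_used = n)
  } else {
    res <- do.call(rbind, lapply(seq_len(ncol(G)), function(j) {
      ok <- !is.na(G[, j])
      gj <- G[ok, j]
      if (stats::var(gj) < 1e-12 || sum(ok) <= q + 2)
        return(data.frame(variant = j, beta = NA_real_, se = NA_real_,
                          p = NA_real_, n_used = sum(ok)))
      fit <- stats::lm.fit(cbind(X[ok, , drop = FALSE], gj), Y[ok])
      cf <- fit$coefficients
      rdf <- fit$df.residual
      s2 <- sum(fit$residuals^2) / rdf
      R <- qr.R(fit$qr)
      vcv <- chol2inv(R) * s2
      b <- cf[length(cf)]; se <- sqrt(vcv[length(cf), length(cf)])
      data.frame(variant = j, beta = b, se = se,
                 p = 2 * stats::pt(abs(b / se), rdf, lower.tail = FALSE),
                 n_used = sum(ok))
    }))
  }
  class(res) <- c("gwas_result", class(res))
  res
}
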