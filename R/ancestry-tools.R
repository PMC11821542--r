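#' Non-negative least-squares ancestry mixture coefficients
#'
#' Fits `target ~ reference_matrix' b` subject to `b >= 0` by the
#' Lawson-Hanson active-set algorithm and renormalizes the solution to sum
#' to 1, yielding ancestry proportions with respect to the reference
#' groups (rows of `reference_matrix`).
#'
#' @param target numeric vector (e.g. a haplotype-matching profile).
#' @param reference_matrix matrix with one reference group per row.
#' @return named numeric vector of coefficients, non-negative, summing to 1.
#' @export
nnls_mixture <- function(target, reference_matrix) {
  A <- t(as.matrix(reference_matrix))   # columns = reference groups
  if (nrow(A) != length(target)) stop("dimension mismatch")
  if (all(abs(A) < 1e-14)) stop("reference rows are all zero")
  b <- nnls_solve(A, as.numeric(target))
  s <- sum(b)
  if (s <= 0) stop("all-zero NNLS solution: target outside the reference cone")
  out <- b / s
  names(out) <- rownames(reference_matrix)
  out
}

# Lawson-Hanson NNLS: minimize ||A x - y|| subject to x >= 0
nnls_solve <- function(A, y, tol = NULL) {
  m <- ncol(A)
  x <- numeric(m)
  passive <- logical(m)
  w <- drop(crossprod(A, y))
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * m
  iter <- 0
  while (any(!passive) && max(w[!passive]) > tol && iter < 30 * m) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(m)
      z[P] <- stats::lm.fit(A[, P, drop = FALSE], y)$coefficients
      z[is.na(z)] <- 0
      if (all(z[P] > tol)) break
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
    }
    x <- z
    w <- drop(crossprod(A, y - A %*% x))
  }
  pmax(x, 0)
}

#' Ancestry entropy over a subset of components
#'
#' Renormalizes the selected coefficients and returns
#' `E = -sum p log p` in nats (`0 log 0 = 0`). Maximal (`log k`) iff the k
#' selected components are uniform; invariant to permutation.
#'
#' @param coefficients numeric vector of ancestry coefficients.
#' @param subset indices (or logical mask) of the components to include;
#'   default all.
#' @return entropy in nats.
#' @export
ancestry_entropy <- function(coefficients, subset = NULL) {
  a <- if (is.null(subset)) coefficients else coefficients[subset]
  if (any(a < 0)) stop("coefficients must be non-negative")
  s <- sum(a)
  if (s <= 0) stop("selected components are all zero")
  p <- a / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gaussian kernel smoothing of point values onto a grid
#'
#' At each grid point the smoothed value is a convex combination of the
#' observed values, `sum_i w_i O_i` with
#' `w_i` proportional to `exp(-q d^2(grid point, point_i))` and normalized
#' to sum to 1, so the field is bounded by the range of the observations.
#' With `q = NULL` an adaptive bandwidth is used per grid point:
#' `q_p = 1 / (2 d_k(p)^2)` where `d_k(p)` is the distance to the k-th
#' nearest observation.
#'
#' @param points n x 2 matrix of observation coordinates.
#' @param values length-n vector of observed values O_i.
#' @param grid m x 2 matrix of grid coordinates.
#' @param q kernel precision (> 0), or NULL for the adaptive rule.
#' @param k neighbor order for the adaptive bandwidth (default 10).
#' @return length-m vector of smoothed values.
#' @export
kernel_smooth <- function(points, values, grid, q = 1, k = 10) {
  points <- as.matrix(points); grid <- as.matrix(grid)
  n <- nrow(points)
  if (n < 1) stop("need at least one observation point")
  stopifnot(length(values) == n, ncol(points) == 2, ncol(grid) == 2)
  if (!is.null(q) && q <= 0) stop("`q` must be positive")
  d2 <- outer(grid[, 1], points[, 1], "-")^2 +
        outer(grid[, 2], points[, 2], "-")^2
  if (is.null(q)) {
    k <- min(k, n)
    dk2 <- apply(d2, 1, function(row) sort(row)[k])
    dk2[dk2 <= 0] <- min(dk2[dk2 > 0], 1)
    qv <- 1 / (2 * dk2)
  } else qv <- rep(q, nrow(grid))
  lw <- -qv * d2
  lw <- lw - apply(lw, 1, max)          # stabilize before exponentiation
  w <- exp(lw)
  drop((w / rowSums(w)) %*% values)
}
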