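test_that("PGS decomposition is a weighted sum of centered dosages", {
  set.seed(201)
  GE <- matrix(rnorm(50), 10); GA <- matrix(rnorm(50), 10)
  w <- data.frame(variant = 2L, weight = 1.7)
  sc <- decompose_pgs(list(GE = GE, GA = GA), w)
  expect_equal(sc$epgs, 1.7 * GE[, 2])
  expect_equal(sc$apgs, 1.7 * GA[, 2])

  # fully European unmasked individual: APGS is exactly zero
  GA2 <- GA; GA2[3, ] <- 0
  sc2 <- decompose_pgs(list(GE = GE, GA = GA2),
                       data.frame(variant = 1:5, weight = rnorm(5)))
  expect_identical(sc2$apgs[3], 0)

  expect_error(decompose_pgs(list(GE = GE, GA = GA),
                             data.frame(variant = 99L, weight = 1)),
               "overlap")
})

test_that("decomposed scores inherit the per-site zero-sum identity", {
  fx <- tiny_cohort(n = 100, M = 60, theta = 0.5, seed = 202)
  co <- fx$cohort
  pr <- cohort_state_probs(co)
  post <- ancestry_posteriors(co)
  dos <- expected_ancestry_dosages(co$hap1, co$hap2, post$a1, post$a2)
  ff <- fit_site_frequencies(co$G, pr)
  cc <- mean_center_dosages(dos, pr, ff)
  ok <- which(!ff$clipped)        # clipped sites break the exact identity
  w <- data.frame(variant = ok, weight = rnorm(length(ok)))
  sc <- decompose_pgs(cc, w)
  expect_lt(abs(sum(sc$epgs + sc$apgs)), 1e-7)
})

test_that("residualization matches the projection-matrix oracle", {
  set.seed(203)
  n <- 80
  covs <- cbind(rnorm(n), rnorm(n))
  x <- rnorm(n)
  r <- residualize(x, covs)
  X <- cbind(1, covs)
  P <- diag(n) - X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(r, drop(P %*% x), tolerance = 1e-10)
  expect_lt(abs(mean(r)), 1e-12)
  expect_lt(max(abs(crossprod(covs, r))), 1e-8)

  # mean-zero vector orthogonal to covariates passes through unchanged
  xo <- drop(P %*% x)
  expect_equal(residualize(xo, covs), xo, tolerance = 1e-10)

  expect_error(residualize(x, cbind(a = covs[, 1], b = covs[, 1])),
               "collinear")
})

test_that("the decomposition model recovers noise-free parameters exactly", {
  sc <- toy_scores(n = 300, seed = 204)
  Y <- 3 + 2 * sc$epgs + 1 * sc$apgs
  f <- fit_anchor(Y, sc, "fixed_zero")
  expect_equal(f$I, 3, tolerance = 1e-10)
  expect_equal(f$beta_eu, 2, tolerance = 1e-10)
  expect_equal(f$beta_af, 1, tolerance = 1e-10)
  expect_identical(f$omega, 0)

  # free omega: generating model on the grid recovered to grid resolution
  Yw <- (2 * sc$epgs + 1 * sc$apgs) * (1 + 0.5 * sc$theta)
  fw <- fit_anchor(Yw, sc, "free")
  expect_equal(fw$beta_eu, 2, tolerance = 5e-3)
  expect_equal(fw$beta_af, 1, tolerance = 5e-3)
  expect_equal(fw$omega, 0.5, tolerance = 5e-3)
  expect_true(fw$omega_identifiable)
  expect_equal(fw$beta_eu_af, fw$beta_eu * 1.5, tolerance = 1e-8)

  expect_error(fit_anchor(rep(1, 300), sc), "constant")
})

test_that("the 1,000-point grid matches a 10x finer grid to one step", {
  sc <- toy_scores(n = 250, seed = 205)
  set.seed(205)
  Y <- (1.2 * sc$epgs + 0.6 * sc$apgs) * (1 + 0.4 * sc$theta) + rnorm(250)
  f1k <- fit_anchor(Y, sc, "free", n_grid = 1000L)
  f10k <- fit_anchor(Y, sc, "free", n_grid = 10000L)
  # the finer grid is a different lattice, so allow one-step slack both ways
  expect_lt(abs(f1k$sse - f10k$sse), 1e-3 * f10k$sse)
  expect_lt(abs(f1k$ratio - f10k$ratio), 1 / 999 + 1 / 9999)
})

test_that("scale equivariance: rescaling Y rescales the linear parameters", {
  sc <- toy_scores(n = 200, seed = 206)
  set.seed(206)
  Y <- 1 + sc$epgs + 0.5 * sc$apgs + rnorm(200)
  f <- fit_anchor(Y, sc, "free")
  fc <- fit_anchor(10 * Y, sc, "free")
  expect_equal(fc$I, 10 * f$I, tolerance = 1e-8)
  expect_equal(fc$beta_eu, 10 * f$beta_eu, tolerance = 1e-8)
  expect_equal(fc$beta_af, 10 * f$beta_af, tolerance = 1e-8)
  expect_equal(fc$omega, f$omega, tolerance = 1e-8)
})

test_that("bootstrap fits are seed-deterministic with percentile CIs", {
  sc <- toy_scores(n = 150, seed = 207)
  set.seed(207)
  Y <- 1 + 2 * sc$epgs + sc$apgs + rnorm(150)
  b1 <- bootstrap_fit(Y, sc, "fixed_zero", n_boot = 100, seed = 31)
  b2 <- bootstrap_fit(Y, sc, "fixed_zero", n_boot = 100, seed = 31)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$boot, b2$boot)
  expect_equal(b1$n_boot_dropped, 0L)

  # noise-free data: every replicate identical, zero-width intervals
  Yx <- 3 + 2 * sc$epgs + sc$apgs
  bx <- bootstrap_fit(Yx, sc, "fixed_zero", n_boot = 50, seed = 32)
  expect_equal(bx$ci$beta_eu[1], bx$ci$beta_eu[2], tolerance = 1e-10)
  expect_equal(bx$ci$beta_eu[1], 2, tolerance = 1e-8)

  expect_error(bootstrap_fit(Y, sc, n_boot = 1), "at least 2")
})

test_that("ancestry-bin fits follow the binning and top-bin rules", {
  set.seed(208)
  n <- 600
  theta <- c(0.2, runif(n - 1, 0.1, 1))
  sc <- structure(list(epgs = rnorm(n), apgs = rnorm(n), theta = theta,
                       covariates = NULL), class = "decomposed_pgs")
  Y <- 1 + 1.5 * sc$epgs + 0.7 * sc$apgs + rnorm(n)
  bf <- bin_and_fit(Y, sc, min_n = 10)
  expect_identical(nrow(bf$summary), 5L)
  # theta = 0.2 falls in the first bin
  expect_identical(findInterval(0.2, c(0.1, 0.35, 0.55, 0.78, 0.95, 1)), 1L)
  expect_gt(bf$summary$n[1], 0)
  # top bin: APGS-only fit
  expect_true(bf$fits[[5]]$apgs_only)
  expect_true(is.na(bf$summary$beta_eu[5]))
  expect_false(is.na(bf$summary$beta_af[5]))

  # empty bin recorded with n = 0 and skipped
  sc2 <- subset_theta <- sc; sc2$theta <- rep(0.2, n)
  bf2 <- suppressWarnings(bin_and_fit(Y, sc2, min_n = 10))
  expect_identical(bf2$summary$n[3], 0L)
  expect_true(is.na(bf2$summary$beta_af[3]))
})

test_that("rho estimation and projection follow the slope ratios", {
  fit <- structure(list(beta_eu = 2, beta_af = 0.8, omega = 0,
                        boot = NULL), class = "anchor_fit")
  ref <- structure(list(beta = 2, ci = c(1.5, 2.5), boot = numeric(0)),
                   class = "reference_slope")
  e <- estimate_rho(fit, ref)
  expect_equal(e$rho, 1)
  expect_equal(e$rho_projected_af, e$rho)   # omega = 0: no projection shift
  expect_equal(e$local_ratio, 0.4)
  expect_false(e$unstable)

  fit$omega <- 0.25
  e2 <- estimate_rho(fit, ref)
  expect_equal(e2$rho_projected_af, 1.25)

  ref0 <- ref; ref0$ci <- c(-0.5, 2.5)
  expect_true(estimate_rho(fit, ref0)$unstable)
  refz <- ref; refz$beta <- 0
  expect_error(estimate_rho(fit, refz), "zero")

  # joint bootstrap pairs replicate b of both cohorts
  fitb <- fit
  fitb$boot <- data.frame(beta_eu = c(2, 2.2, 1.8), beta_af = c(1, 1, 1),
                          omega = c(0, 0, 0))
  refb <- ref; refb$boot <- c(2, 2, 2)
  e3 <- estimate_rho(fitb, refb)
  expect_equal(e3$boot$rho, c(1, 1.1, 0.9))
})

test_that("pooling across traits is a ratio of weighted means", {
  mk <- function(be, bo) structure(list(beta_eu = be, beta_obs_eu = bo,
                                        boot = NULL),
                                   class = "rho_estimate")
  one <- pool_traits(list(mk(1.4, 2)), weighting = "equal")
  expect_equal(one$rho, 0.7)
  same <- pool_traits(list(mk(1.5, 2), mk(1.5, 2), mk(1.5, 2)),
                      weighting = "equal")
  expect_equal(same$rho, 0.75)
  two <- pool_traits(list(mk(1, 1), mk(3, 1)), weighting = "equal")
  expect_equal(two$rho, 2)
  expect_error(pool_traits(list()), "at least one")
})
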