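test_that("ancestral frequency draws honor the divergence model", {
  # no drift: both populations equal the ancestral frequency
  f0 <- draw_ancestral_frequencies(50, fst = 0, seed = 1)
  expect_identical(f0$f_eu, f0$f_af)
  expect_identical(f0$f_eu, f0$f_anc)

  # Hudson estimator over many variants recovers the configured FST
  f <- draw_ancestral_frequencies(1e5, fst = 0.15, seed = 3)
  expect_lt(abs(hudson_fst(f$f_eu, f$f_af) - 0.15), 0.02)

  # clipping keeps every frequency polymorphic
  expect_true(all(f$f_eu >= 0.01 & f$f_eu <= 0.99))
  expect_true(all(f$f_af >= 0.01 & f$f_af <= 0.99))

  expect_error(draw_ancestral_frequencies(10, fst = 1, seed = 1), "fst")
  expect_error(draw_ancestral_frequencies(10, fst = -0.1, seed = 1), "fst")
})

test_that("admixed genomes conserve genotypes and honor degenerate admixture", {
  fx <- tiny_cohort(n = 30, M = 80, theta = 0.4, seed = 11)
  co <- fx$cohort
  expect_identical(co$G, co$hap1 + co$hap2)
  expect_true(all(co$theta >= 0 & co$theta <= 1))

  # theta = 0: every tract European, zero expected African dosage
  fx0 <- tiny_cohort(n = 10, M = 50, theta = 0, seed = 5)
  post <- ancestry_posteriors(fx0$cohort)
  dos <- expected_ancestry_dosages(fx0$cohort$hap1, fx0$cohort$hap2,
                                   post$a1, post$a2)
  expect_true(all(dos$GA == 0))
  expect_identical(dos$GE, fx0$cohort$G + 0)

  cfg_bad <- fx$config
  cfg_bad$genetic_map <- fx$config$genetic_map[0, ]
  expect_error(simulate_admixed_genomes(cfg_bad, fx$freqs), "map")
})

test_that("fixed seed gives bit-identical cohorts and phenotypes", {
  a <- tiny_cohort(n = 15, M = 40, theta = 0.5, seed = 99, ld_blocks = TRUE)
  b <- tiny_cohort(n = 15, M = 40, theta = 0.5, seed = 99, ld_blocks = TRUE)
  expect_identical(a$cohort$hap1, b$cohort$hap1)
  expect_identical(a$cohort$anc2, b$cohort$anc2)
  eff <- draw_effect_sizes(1:10, a$freqs, "normal", rho = 0.5, seed = 4)
  p1 <- simulate_phenotype(a$cohort, eff, 0.5, TRUE, seed = 8)
  p2 <- simulate_phenotype(b$cohort, eff, 0.5, TRUE, seed = 8)
  expect_identical(p1$y, p2$y)
})

test_that("ancestry runs follow the Poisson-tract law", {
  # one long chromosome, per-site ancestry resolution, 0.5-cM site spacing
  # (fine enough that lattice effects stay below the KS 1%-level critical
  # distance for the run counts below)
  M <- 4000
  map <- data.frame(chrom = 1L, pos = seq(5e5, by = 5e5, length.out = M))
  map$cm <- map$pos / 1e6  # ~2,000 cM total
  g <- 10
  cfg <- simulation_config(n_individuals = 30, n_variants = M,
                           theta_distribution = 0.5, admix_generations = g,
                           genetic_map = map, ld_blocks = FALSE, seed = 21)
  co <- simulate_admixed_genomes(cfg, draw_ancestral_frequencies(M, 0.15, 21))

  # Latent tracts are Exponential(mean 1/g Morgans), but consecutive tracts
  # drawing the same ancestry merge: an observable European run ends only
  # when a breakpoint switches to African, a thinned Poisson process of
  # rate g * theta. At theta = 0.5 observable runs average 2/g Morgans.
  run_lengths <- function(anc_row) {
    r <- rle(anc_row)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- seq_along(r$lengths)[-c(1, length(r$lengths))]  # uncensored
    list(len = (map$cm[ends[keep]] - map$cm[starts[keep] - 1]) / 100,
         anc = r$values[keep])
  }
  runs <- unlist(lapply(seq_len(nrow(co$G)), function(i) {
    list(run_lengths(co$anc1[i, ]), run_lengths(co$anc2[i, ]))
  }), recursive = FALSE)
  len <- unlist(lapply(runs, `[[`, "len"))
  anc <- unlist(lapply(runs, `[[`, "anc"))
  eu <- len[anc == 1]
  expect_gt(length(eu), 2000)
  expect_lt(abs(mean(eu) - 2 / g) / (2 / g), 0.05)
  # goodness of fit against the exponential law at the 1% level
  ks <- suppressWarnings(stats::ks.test(eu, "pexp", rate = g * 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("causal-variant placement follows the uniform and clustered rules", {
  # 1-kb variant spacing so 10-kb regions hold ~10 variants each
  map <- data.frame(chrom = 1L, pos = seq(1000, by = 1000,
                                          length.out = 10000))
  map$cm <- map$pos / 1e6
  fx <- tiny_cohort(n = 5, M = 10000, theta = 0, seed = 31,
                    genetic_map = map)
  cfg <- fx$config

  cfg$n_causal <- 100L; cfg$placement <- "uniform"
  idx <- select_causal_variants(cfg, fx$cohort$variants)
  expect_length(idx, 100)
  expect_false(any(duplicated(idx)))
  expect_true(all(idx >= 1 & idx <= 10000))

  cfg$n_causal <- 1000L; cfg$placement <- "clustered"
  idx <- select_causal_variants(cfg, fx$cohort$variants)
  expect_length(idx, 1000)
  expect_false(any(duplicated(idx)))
  # exactly half inside the 100 designated 10-kb regions
  expect_identical(sum(attr(idx, "in_region")), 500L)
  regions <- attr(idx, "regions")
  expect_length(regions, 100)
  in_reg <- idx[attr(idx, "in_region")]
  expect_true(all(in_reg %in% unlist(regions)))

  cfg$n_causal <- 0L
  expect_length(select_causal_variants(cfg, fx$cohort$variants), 0)

  cfg$n_causal <- 20000L
  expect_error(select_causal_variants(cfg, fx$cohort$variants), "exceeds")
})

test_that("effect sizes follow the conditional cross-ancestry model", {
  f <- draw_ancestral_frequencies(1e5, 0.15, seed = 41)

  # rho = 1 collapses to identical effects
  e1 <- draw_effect_sizes(1:1000, f, "normal", rho = 1, seed = 2)
  expect_identical(e1$gamma_eu, e1$gamma_af)

  # frequency-scaled sd at p = 0.5 is [2 * 0.5 * 0.5]^(-1/4) = 2^(1/4)
  fhalf <- data.frame(f_eu = rep(0.5, 3), f_af = rep(0.5, 3))
  eh <- draw_effect_sizes(1:3, fhalf, "frequency_scaled", rho = 1, seed = 3)
  expect_equal(eh$sigma, rep(2^0.25, 3), tolerance = 1e-12)

  # empirical correlation across many draws matches rho
  e7 <- draw_effect_sizes(seq_len(1e5), f, "normal", rho = 0.7, seed = 5)
  expect_lt(abs(stats::cor(e7$gamma_eu, e7$gamma_af) - 0.7), 0.01)
  # the conditional construction preserves the marginal variance
  expect_lt(abs(stats::var(e7$gamma_af) / stats::var(e7$gamma_eu) - 1), 0.02)

  fbad <- data.frame(f_eu = c(0.5, 1), f_af = c(0.5, 1))
  expect_error(draw_effect_sizes(1:2, fbad, "frequency_scaled", rho = 1,
                                 seed = 1), "undefined")
})

test_that("phenotype heritability is calibrated from the genetic variance", {
  fx <- tiny_cohort(n = 5000, M = 150, theta = 0.3, seed = 51)
  eff <- draw_effect_sizes(1:50, fx$freqs, "normal", rho = 1, seed = 6)

  # noiseless limit
  p1 <- simulate_phenotype(fx$cohort, eff, h2 = 1, seed = 7)
  expect_identical(p1$y, p1$genetic)
  expect_identical(p1$sigma_e2, 0)

  p6 <- simulate_phenotype(fx$cohort, eff, h2 = 0.6, seed = 7)
  expect_lt(abs(p6$h2_realized - 0.6), 0.02)
  expect_equal(p6$sigma_e2, (1 - 0.6) / 0.6 * stats::var(p6$genetic))

  eff0 <- eff; eff0$gamma_eu <- 0 * eff0$gamma_eu
  expect_error(simulate_phenotype(fx$cohort, eff0, 0.6, seed = 7),
               "degenerate")
})

test_that("ancestry-specific phenotypes: individual vs tract effect models", {
  fx <- tiny_cohort(n = 400, M = 100, theta = 0.5, seed = 61)
  eff <- draw_effect_sizes(1:40, fx$freqs, "normal", rho = 0, seed = 8)
  ind <- simulate_phenotype(fx$cohort, eff, 1, TRUE, "individual", seed = 9)
  expect_equal(ind$genetic,
               drop(fx$cohort$G[, 1:40] %*% eff$gamma_af))
  tra <- simulate_phenotype(fx$cohort, eff, 1, TRUE, "tract", seed = 9)
  ge <- fx$cohort$hap1[, 1:40] * fx$cohort$anc1[, 1:40] +
        fx$cohort$hap2[, 1:40] * fx$cohort$anc2[, 1:40]
  ga <- fx$cohort$G[, 1:40] - ge
  expect_equal(tra$genetic,
               drop(ge %*% eff$gamma_eu + ga %*% eff$gamma_af))
})

test_that("the factorial scenario grid enumerates 24 scenarios", {
  g <- scenario_grid()
  expect_identical(nrow(g), 24L)
  expect_identical(anyDuplicated(g$label), 0L)
  expect_true("#causal:1K(uniform)S:0 h2:0.6" %in% g$label)
})
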