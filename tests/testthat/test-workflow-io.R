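test_that("cohort write/read round trip preserves all matrices", {
  fx <- tiny_cohort(n = 8, M = 25, theta = 0.5, seed = 401)
  dir <- withr::local_tempdir()
  phe <- data.frame(height = rnorm(8))
  paths <- write_cohort(fx$cohort, dir, "demo", phenotypes = phe)
  geno <- read_cohort_vcf(paths$vcf)
  expect_identical(geno$hap1, fx$cohort$hap1)
  expect_identical(geno$hap2, fx$cohort$hap2)
  expect_identical(geno$G, fx$cohort$G)
  expect_identical(geno$variants$pos, fx$cohort$variants$pos)

  pr <- read_ancestry_tsv(paths$ancestry, geno$samples, geno$variants)
  truth <- cohort_state_probs(fx$cohort)
  expect_equal(pr$EE, truth$EE, ignore_attr = TRUE)
  expect_equal(pr$AA, truth$AA, ignore_attr = TRUE)

  b <- load_cohort_bundle(paths$vcf, paths$ancestry, paths$samples)
  expect_identical(b$G, fx$cohort$G)
  expect_equal(b$theta, fx$cohort$theta, tolerance = 1e-6)
  expect_equal(b$phenotypes$height, phe$height, tolerance = 1e-6)
})

test_that("strict loading reports missing samples by name", {
  fx <- tiny_cohort(n = 5, M = 10, theta = 0.3, seed = 402)
  dir <- withr::local_tempdir()
  paths <- write_cohort(fx$cohort, dir, "x")
  smp <- read.delim(paths$samples)
  write.table(smp[-2, ], paths$samples, sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(load_cohort_bundle(paths$vcf, paths$ancestry, paths$samples),
               "S0002")
})

test_that("weight allele orientation is harmonized on load", {
  fx <- tiny_cohort(n = 30, M = 12, theta = 0.2, seed = 403)
  dir <- withr::local_tempdir()
  paths <- write_cohort(fx$cohort, dir, "w")
  v <- fx$cohort$variants
  w <- data.frame(id = v$id[1:3], chrom = v$chrom[1:3], pos = v$pos[1:3],
                  effect_allele = c(v$alt[1], v$ref[2], "T"),
                  other_allele = c(v$ref[1], v$alt[2], "C"),
                  weight = c(0.5, 0.5, 0.5))
  wpath <- file.path(dir, "w.tsv")
  write.table(w, wpath, sep = "\t", row.names = FALSE, quote = FALSE)
  suppressMessages(
    b <- load_cohort_bundle(paths$vcf, paths$ancestry, paths$samples,
                            weights = wpath))
  # variant 2 had swapped alleles: sign flipped; variant 3 dropped
  expect_identical(nrow(b$weights), 2L)
  expect_equal(b$weights$weight, c(0.5, -0.5))
  expect_identical(b$n_dropped_weights, 1L)
  # flipped weighting equals counting the other allele (dosage 2 - G)
  pgs <- compute_pgs(b$G, b$weights, b$variants)
  manual <- 0.5 * b$G[, b$weights$variant[1]] +
    0.5 * (2 - b$G[, b$weights$variant[2]]) - 1  # constant offset
  expect_equal(pgs - mean(pgs), manual - mean(manual), tolerance = 1e-12)
})

test_that("fit reports are reproducible, re-readable and poolable", {
  sc <- toy_scores(n = 120, seed = 404)
  set.seed(404)
  Y <- 1 + 2 * sc$epgs + sc$apgs + rnorm(120)
  fit <- bootstrap_fit(Y, sc, "fixed_zero", n_boot = 50, seed = 7)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.json"); p2 <- file.path(dir, "b.json")
  write_fit_report(fit, p1)
  write_fit_report(fit, p2)
  expect_identical(readLines(p1), readLines(p2))
  rep <- read_fit_report(p1)
  expect_equal(rep$estimates$beta_eu, fit$beta_eu, tolerance = 1e-12)
  expect_equal(rep$n_boot, 50)
  expect_identical(rep$schema, "anchor-fit-report/1")
})

test_that("the CLI chains simulate through fit on files", {
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "sim.cfg")
  writeLines(c("n_individuals: 40", "n_variants: 40", "n_causal: 8",
               "h2: 0.8", "theta: 0.5", "seed: 11", "ld_blocks: 0"), cfgp)
  suppressMessages(anchor_cli(c("simulate", "--config", cfgp,
                                "--out", dir, "--prefix", "c")))
  vcf <- file.path(dir, "c.vcf")
  expect_true(file.exists(vcf))

  fqp <- file.path(dir, "freqs.tsv")
  suppressMessages(anchor_cli(c(
    "freqs", "--vcf", vcf, "--ancestry", file.path(dir, "c.ancestry.tsv"),
    "--samples", file.path(dir, "c.samples.tsv"), "--out", fqp,
    "--min-length-bp", "1")))
  expect_true(file.exists(fqp))
  fq <- read.delim(fqp)
  expect_identical(nrow(fq), 40L)

  gwp <- file.path(dir, "gwas.tsv")
  suppressMessages(anchor_cli(c(
    "gwas", "--vcf", vcf, "--ancestry", file.path(dir, "c.ancestry.tsv"),
    "--samples", file.path(dir, "c.samples.tsv"), "--pheno", "phenotype",
    "--out", gwp)))
  gw <- read.delim(gwp)
  expect_identical(nrow(gw), 40L)
  expect_true(all(gw$p > 0 & gw$p <= 1, na.rm = TRUE))

  wp <- file.path(dir, "weights.tsv")
  suppressMessages(anchor_cli(c(
    "clump", "--vcf", vcf, "--ancestry", file.path(dir, "c.ancestry.tsv"),
    "--samples", file.path(dir, "c.samples.tsv"), "--gwas", gwp,
    "--p1", "0.5", "--out", wp)))
  expect_true(file.exists(wp))

  fitp <- file.path(dir, "fit.json")
  suppressMessages(anchor_cli(c(
    "fit", "--vcf", vcf, "--ancestry", file.path(dir, "c.ancestry.tsv"),
    "--samples", file.path(dir, "c.samples.tsv"), "--weights", wp,
    "--pheno", "phenotype", "--n-boot", "20", "--seed", "5",
    "--min-length-bp", "1", "--out", fitp)))
  rep <- read_fit_report(fitp)
  expect_true(is.finite(rep$estimates$beta_eu))

  poolp <- file.path(dir, "pool.json")
  suppressMessages(anchor_cli(c("pool", fitp, "--out", poolp)))
  expect_true(file.exists(poolp))
})

test_that("config reader parses key-value lines and requires a seed", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "a.cfg")
  writeLines(c("# comment", "n_individuals = 10", "label: test",
               "seed: 3"), p)
  cfg <- read_config(p)
  expect_identical(cfg$n_individuals, 10)
  expect_identical(cfg$label, "test")
  writeLines("n_individuals = 10", p)
  expect_error(read_config(p), "seed")
})
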