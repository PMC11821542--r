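#' Write a simulated cohort to VCF + TSV files
#'
#' Emits a phased-GT VCF (1-based positions), a long-format local-ancestry
#' TSV (`individual`, `chrom`, `pos`, `pEE`, `pEA`, `pAE`, `pAA`) and a
#' sample TSV (`individual`, `theta_af`, plus any phenotype columns).
#'
#' @param cohort an `admix_cohort`.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @param phenotypes optional data frame of phenotype columns (n rows).
#' @return invisibly, a named list of the written paths.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort", phenotypes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(cohort$G); v <- cohort$variants
  ids <- sprintf("S%04d", seq_len(n))
  paths <- list(vcf = file.path(dir, paste0(prefix, ".vcf")),
                ancestry = file.path(dir, paste0(prefix, ".ancestry.tsv")),
                samples = file.path(dir, paste0(prefix, ".samples.tsv")))

  gt <- matrix(paste0(t(cohort$hap1), "|", t(cohort$hap2)),
               nrow(v), n)  # variants x samples
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=anchor simulate (seed=%d)", cohort$seed),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                gt)
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), paths$vcf)

  post <- ancestry_posteriors(cohort)
  dp <- diploid_state_probs(post$a1, post$a2)
  # symmetric storage: the phase of the two chromosomes is arbitrary
  pEA <- (dp$EA + dp$AE) / 2
  anc <- data.frame(individual = rep(ids, each = nrow(v)),
                    chrom = rep(v$chrom, n), pos = rep(v$pos, n),
                    pEE = as.vector(t(dp$EE)), pEA = as.vector(t(pEA)),
                    pAE = as.vector(t(pEA)), pAA = as.vector(t(dp$AA)))
  utils::write.table(anc, paths$ancestry, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  smp <- data.frame(individual = ids, theta_af = cohort$theta)
  if (!is.null(phenotypes)) smp <- cbind(smp, phenotypes)
  utils::write.table(smp, paths$samples, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Read a phased-genotype VCF into haplotype matrices
#'
#' Supports the subset of VCF this package writes: biallelic sites, a GT
#' field with `|` (or `/`) separators, missing calls `.` mapped to NA.
#'
#' @param path VCF file path.
#' @return list: `hap1`, `hap2`, `G` (n x M, NA where missing), `variants`,
#'   `samples`.
#' @export
read_cohort_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("malformed VCF: no #CHROM header")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t")
  M <- length(fields); n <- length(samples)
  variants <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    pos = as.integer(vapply(fields, `[`, "", 2)),
    id = vapply(fields, `[`, "", 3),
    ref = vapply(fields, `[`, "", 4),
    alt = vapply(fields, `[`, "", 5))
  suppressWarnings(variants$chrom <- ifelse(
    is.na(as.integer(variants$chrom)), variants$chrom,
    as.integer(variants$chrom)))
  hap1 <- matrix(NA_integer_, n, M); hap2 <- matrix(NA_integer_, n, M)
  for (j in seq_len(M)) {
    gt <- sub(":.*", "", fields[[j]][-(1:9)])
    al <- strsplit(gt, "[|/]")
    a1 <- vapply(al, `[`, "", 1); a2 <- vapply(al, function(x)
      if (length(x) > 1) x[2] else NA_character_, "")
    hap1[, j] <- suppressWarnings(as.integer(a1))
    hap2[, j] <- suppressWarnings(as.integer(a2))
  }
  list(hap1 = hap1, hap2 = hap2, G = hap1 + hap2, variants = variants,
       samples = samples)
}

#' Read a long-format local-ancestry TSV into diploid probability matrices
#'
#' @param path TSV with columns `individual`, `chrom`, `pos`, `pEE`, `pEA`,
#'   `pAE`, `pAA`, or the two-column per-haplotype form `individual`,
#'   `chrom`, `pos`, `hap1_eu`, `hap2_eu` (converted via
#'   [diploid_state_probs()]).
#' @param samples,variants ordering references (sample ids; data frame with
#'   `chrom`, `pos`).
#' @return a `diploid_probs` list of n x M matrices.
#' @export
read_ancestry_tsv <- function(path, samples, variants) {
  d <- utils::read.delim(path, check.names = FALSE)
  key <- paste0(d$chrom, ":", d$pos)
  vkey <- paste0(variants$chrom, ":", variants$pos)
  i <- match(d$individual, samples)
  j <- match(key, vkey)
  if (anyNA(i)) stop("ancestry file contains unknown samples: ",
                     paste(unique(d$individual[is.na(i)]), collapse = ", "))
  if (anyNA(j)) stop("ancestry file contains unknown variants")
  n <- length(samples); M <- nrow(variants)
  mk <- function(col) {
    m <- matrix(NA_real_, n, M); m[cbind(i, j)] <- col; m
  }
  if (all(c("hap1_eu", "hap2_eu") %in% names(d)))
    return(diploid_state_probs(mk(d$hap1_eu), mk(d$hap2_eu)))
  if (!all(c("pEE", "pEA", "pAE", "pAA") %in% names(d)))
    stop("ancestry TSV needs pEE/pEA/pAE/pAA or hap1_eu/hap2_eu columns")
  structure(list(EE = mk(d$pEE), EA = mk(d$pEA), AE = mk(d$pAE),
                 AA = mk(d$pAA)), class = "diploid_probs")
}

#' Write / read a PGS weight table
#'
#' TSV columns: `id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `weight` (phenotype units per copy of the effect allele).
#'
#' @param weights a `pgs_weights` data frame.
#' @param path file path.
#' @export
write_weights <- function(weights, path) {
  utils::write.table(
    weights[, c("id", "chrom", "pos", "effect_allele", "other_allele",
                "weight")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  w <- utils::read.delim(path)
  w$variant <- NA_integer_
  class(w) <- c("pgs_weights", class(w))
  w
}

#' Write fitted ancestral frequencies as TSV
#'
#' @param freqs `ancestral_freqs` from [fit_site_frequencies()].
#' @param variants variant table supplying ids.
#' @param path file path.
#' @export
write_frequencies <- function(freqs, variants, path) {
  d <- data.frame(variant = variants$id, f_eu = freqs$f_eu,
                  f_af = freqs$f_af, n_used = freqs$n_used,
                  degenerate = freqs$degenerate)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and align a cohort bundle
#'
#' Reads the genotype VCF, local-ancestry TSV and sample TSV, checks sample
#' and variant consistency, and (when a weight table is given) harmonizes
#' allele orientation to the cohort's counted (ALT) allele: weights whose
#' effect allele is the cohort REF get their sign flipped (counting the
#' effect allele is then `2 - G`, which changes only the score's constant
#' offset), irreconcilable variants are dropped with a count, and
#' strand-ambiguous (A/T, C/G) variants are flagged.
#'
#' @param vcf,ancestry,samples,weights file paths (`weights` optional).
#' @param strict error (rather than warn) on sample-set mismatch.
#' @return `cohort_bundle` list: `hap1`, `hap2`, `G`, `probs`, `samples`,
#'   `variants`, `theta`, `phenotypes`, `weights`, `n_dropped_weights`,
#'   `ambiguous_ids`.
#' @export
load_cohort_bundle <- function(vcf, ancestry, samples, weights = NULL,
                               strict = TRUE) {
  geno <- read_cohort_vcf(vcf)
  smp <- utils::read.delim(samples)
  missing_s <- setdiff(geno$samples, smp$individual)
  extra_s <- setdiff(smp$individual, geno$samples)
  if (length(missing_s) || length(extra_s)) {
    msg <- paste0("sample-set mismatch; missing from sample file: ",
                  paste(missing_s, collapse = ", "),
                  if (length(extra_s)) paste0("; unknown samples: ",
                                              paste(extra_s, collapse = ", ")))
    if (strict) stop(msg) else warning(msg)
  }
  smp <- smp[match(geno$samples, smp$individual), , drop = FALSE]
  probs <- tryCatch(
    read_ancestry_tsv(ancestry, geno$samples, geno$variants),
    error = function(e) if (strict) stop(e) else { warning(conditionMessage(e)); NULL })

  out <- list(hap1 = geno$hap1, hap2 = geno$hap2, G = geno$G,
              probs = probs, samples = geno$samples,
              variants = geno$variants, theta = smp$theta_af,
              phenotypes = smp[, setdiff(names(smp),
                                         c("individual", "theta_af")),
                               drop = FALSE],
              weights = NULL, n_dropped_weights = 0L,
              ambiguous_ids = character(0))
  if (!is.null(weights)) {
    w <- if (is.character(weights)) read_weights(weights) else weights
    out <- harmonize_weights(out, w)
  }
  class(out) <- "cohort_bundle"
  out
}

harmonize_weights <- function(bundle, w) {
  v <- bundle$variants
  idx <- match(w$id, v$id)
  keep <- !is.na(idx)
  w <- w[keep, , drop = FALSE]; idx <- idx[keep]
  dropped <- sum(!keep)
  flip <- w$effect_allele == v$ref[idx] & w$other_allele == v$alt[idx]
  ok <- (w$effect_allele == v$alt[idx] & w$other_allele == v$ref[idx]) | flip
  dropped <- dropped + sum(!ok)
  if (dropped > 0)
    message(dropped, " weight variants dropped (unmatched or irreconcilable alleles)")
  w <- w[ok, , drop = FALSE]; idx <- idx[ok]; flip <- flip[ok]
  w$weight[flip] <- -w$weight[flip]
  w$variant <- idx
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  amb <- w$id[comp[w$effect_allele] == w$other_allele]
  if (length(amb))
    message(length(amb), " strand-ambiguous (A/T or C/G) weight variants flagged")
  bundle$weights <- w
  bundle$n_dropped_weights <- dropped
  bundle$ambiguous_ids <- amb
  bundle
}

#' Write / read an ANCHOR fit report as JSON
#'
#' The report is schema-versioned and re-readable for pooling; a
#' fixed-seed fit produces a byte-identical report.
#'
#' @param fit an `anchor_fit` (optionally with bootstrap CIs) or a
#'   `rho_estimate`.
#' @param path output path.
#' @param config optional config echo (named list).
#' @export
write_fit_report <- function(fit, path, config = NULL) {
  rep <- list(schema = "anchor-fit-report/1",
              estimates = fit[intersect(
                c("I", "beta_eu", "beta_af", "omega", "beta_eu_af",
                  "beta_af_af", "ratio", "rho", "rho_projected_af",
                  "local_ratio", "beta_obs_eu", "sse"), names(fit))],
              ci = fit$ci,
              flags = list(
                omega_identifiable = fit$omega_identifiable,
                unstable = fit$unstable),
              n = fit$n, n_boot = fit$n_boot,
              n_boot_dropped = fit$n_boot_dropped,
              seed = fit$seed, omega_mode = fit$omega_mode,
              config = config)
  rep <- rep[!vapply(rep, is.null, logical(1))]
  writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

log_msg <- function(...) {
  message(sprintf(...))
}
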