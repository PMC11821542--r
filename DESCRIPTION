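Package: anchor
Title: Local-Ancestry-Aware Decomposition of Polygenic Scores
Version: 0.1.0
Authors@R:
    person("ANCHOR", "Developers", email = "anchor@example.org", role = c("aut", "cre"))
Description: Estimates the correlation of causal effect sizes between an
    admixed group and the GWAS reference group by decomposing a polygenic
    score into ancestry-specific components built from mean-centered,
    ancestry-specific allele dosages (the ANCHOR approach). Includes an
    admixture-aware cohort and phenotype simulator (Balding-Nichols
    ancestral divergence, Poisson-recombination ancestry tracts,
    haplotype-block linkage disequilibrium, additive traits with
    configurable cross-ancestry effect-size correlation and heritability),
    a miniature GWAS / LD-clumping / scoring pipeline, local-ancestry
    masking utilities, bootstrap inference for the effect-size correlation,
    and ancestry-summary tools (non-negative least-squares mixture
    coefficients, ancestry entropy, Gaussian kernel smoothing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
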