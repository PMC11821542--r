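# anchor — local-ancestry-aware decomposition of polygenic scores

Polygenic scores (PGS) trained by GWAS in European-ancestry cohorts lose
predictive power in other groups. Part of that loss is *local* — tag SNPs
correlate differently with unobserved causal variants on different
ancestral backgrounds — and part may be *nonlocal*: the causal effect
sizes themselves may differ between groups, summarized by their
correlation ρ. Admixed genomes can separate the two: European-ancestry
segments of an admixed genome carry the same LD as the GWAS population,
so any attenuation specific to those segments must be nonlocal.

`anchor` implements this decomposition (the ANCHOR approach) for
quantitative traits, plus everything needed to test its calibration on
synthetic cohorts:

* mean-centered, ancestry-specific allele dosages from diploid
  local-ancestry probabilities, with 5-Mb / posterior-0.9 segment masking
  and per-site background allele-frequency regression;
* the decomposition fit
  `Y = I + (β_Eu·EPGS + β_Af·APGS)(1 + ω·θ) + covariates + ε`, with a
  1,000-point grid search for the nonlinear ω case, ancestry-bin fits,
  joint bootstrap CIs, ρ̂ = β_Eu/β_Obs.Eu, projections to 100% ancestry
  and multi-trait pooling;
* a miniature GWAS → LD-clumping (p1 0.05, r² 0.1, 500 kb) → scoring
  pipeline with closed-form per-variant OLS;
* an admixture-aware simulator: Balding–Nichols ancestral divergence,
  Poisson-recombination ancestry tracts, founder-haplotype LD blocks,
  additive phenotypes with calibrated heritability and configurable
  cross-ancestry effect-size correlation ρ (the 24-scenario factorial
  grid);
* ancestry utilities (NNLS mixture coefficients, ancestry entropy,
  Gaussian kernel smoothing) and a file-based CLI
  (`inst/cli/anchor simulate|freqs|gwas|clump|pgs|decompose|fit|bins|pool`).

The methods vignette (`vignettes/anchor-methods.Rmd`) documents the model,
the simulator's assumptions and every numerical choice.

## Worked example

Simulate a small study (600 admixed individuals, 1,500-individual
European training cohort, 600-individual held-out European cohort, 2,000
variants with block LD on two 10-Mb chromosomes), then push one
shared-effect (ρ = 1) trait through the whole pipeline:

```r
library(anchor)

study <- build_anchor_study(n_admixed = 600, n_eu_train = 1500,
                            n_eu_test = 600, n_variants = 2000,
                            n_chrom = 2, seed = 7)
tr <- run_trait(study, trait_seed = 2024, rho = 1, h2 = 0.6,
                n_causal = 60, n_boot = 200)
print(tr$estimate)
print(tr$ref)
```

```
rho_hat = 1.1523 (95% CI 0.2013, 2.3805); local ratio beta_Af/beta_Obs.Eu = 0.7487
beta_Obs = 0.3499 (95% CI 0.2618, 0.4632), delta_R2 = 0.0638, n = 600
```

Reading the output: `beta_Obs` is the phenotype increase per PGS unit in
the held-out European cohort (with ΔR², the variance it explains beyond
covariates). `rho_hat` is the European-segment slope in the admixed
cohort divided by that reference slope — here its CI comfortably covers
the generating value 1, as it should for a shared-effect trait (the wide
interval reflects the deliberately small example). The local ratio
β_Af/β_Obs.Eu ≈ 0.75 < 1 shows the purely local (tag-SNP) loss of
predictive power on African-background segments — the clumped score here
holds 102 tag SNPs and excludes the causal variants — even though the
causal effects are identical by construction. Rerunning the same commands
reproduces these numbers bit for bit.

At acceptance scale (2,000 admixed individuals, 5,000 variants, 50 null
traits) the same pipeline yields mean ρ̂ ≈ 1 with ~95% CI coverage of
ρ = 1, recovers ρ = 0.5 from cohorts generated at the middle of the
{0.1, …, 0.9} grid, and keeps the local ratio below 1 in every replicate
— see the acceptance tests and report.

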