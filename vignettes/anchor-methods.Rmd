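---
title: "Ancestry-decomposed polygenic scores: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-decomposed polygenic scores: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Polygenic scores (PGS) trained by GWAS in one ancestry group predict less
well in others. Two mechanisms contribute:

* **local factors** — a tag SNP's correlation with unobserved causal
  variants differs between ancestral backgrounds (LD and allele-frequency
  differences), so the same weights capture less causal signal on, say, an
  African-ancestry chromosome segment;
* **nonlocal factors** — gene–gene or gene–environment interactions that
  make the causal effect sizes themselves differ between groups,
  summarized by the correlation ρ of per-copy causal effects.

Admixed genomes let us separate the two: in a European–African admixed
individual, European-ancestry segments carry the *same* local LD as the
GWAS population, so any loss of predictive power on those segments must be
nonlocal. This package implements that decomposition (the ANCHOR
approach) together with an admixture-aware simulator that generates
cohorts with known ρ, so the estimator's calibration is testable end to
end.

## The decomposition model

For individual $i$ and site $j$, diploid local-ancestry state
probabilities $P^{EE}_{ij}, P^{EA}_{ij}, P^{AE}_{ij}, P^{AA}_{ij}$ (an
input; in real data from an HMM such as HAPMIX, in simulations the truth
track) give background-specific expected allele counts $G^E_{ij},
G^A_{ij}$ with $G^E + G^A = G$. Background allele frequencies are
estimated per site by the regression

$$G_{ij} = I_j + S_j\,(2P^{EE}_{ij} + 2P^{EA}_{ij}) + \varepsilon,$$

giving $f^E_j = S_j + I_j/2$ and $f^A_j = I_j/2$ (`fit_site_frequencies`).
The dosages are then **mean-centered** conditional on local ancestry:

$$\bar G^E_{ij} = G^E_{ij} - f^E_j(2P^{EE}_{ij}+2P^{EA}_{ij}), \qquad
  \bar G^A_{ij} = G^A_{ij} - f^A_j(2P^{AA}_{ij}+2P^{EA}_{ij}).$$

Centering removes the component of ancestry-specific dosage that is
predictable from ancestry alone; without it the estimator is confounded by
global ancestry and ρ̂ is biased downward (shown by an acceptance
property test). With GWAS weights $\hat\gamma_j$ the score decomposes as
$\mathrm{EPGS}_i = \sum_j \hat\gamma_j \bar G^E_{ij}$ and
$\mathrm{APGS}_i = \sum_j \hat\gamma_j \bar G^A_{ij}$, and the model

$$Y_i = I + (\beta_{Eu}\,\mathrm{EPGS}_i + \beta_{Af}\,\mathrm{APGS}_i)
        (1 + \omega\,\theta_i) + \mathrm{covariates} + \varepsilon_i$$

is fitted by least squares (`fit_anchor`). $\theta_i$ is the global
African-ancestry fraction. With $\omega$ free the model is linear
conditional on $r = \beta_{Eu}/(\beta_{Eu}+\beta_{Af})$, so a 1,000-point
grid over $r \in [0,1]$ is searched and the minimum-SSE point kept; a test
verifies agreement with a 10× finer grid to one step. The headline
quantity is

$$\hat\rho = \hat\beta_{Eu}^{All} \,/\, \hat\beta_{Obs.Eu},$$

the European-segment slope in the admixed cohort over the
phenotype-per-PGS slope in a held-out European reference cohort
(`fit_reference_slope`, `estimate_rho`). $\hat\beta_{Af}/\hat\beta_{Obs.Eu}$
isolates the local (tagging) attenuation and is below 1 whenever the PGS
tags rather than contains the causal variants. Uncertainty comes from a
joint bootstrap: individuals are resampled with replacement in both
cohorts, replicate $b$ of one paired with replicate $b$ of the other, and
equal-tailed percentile intervals taken ("central" 95% CIs). Multi-trait
pooling is the ratio of (weighted) means of $\beta_{Eu}$ and
$\beta_{Obs.Eu}$; the default weight is the inverse bootstrap variance of
the per-trait ratio, with equal weights available, since the exact
weighting used for the published averages is not specified.

### θ convention

The Methods text of the source approach describes θ as the European
proportion, but its projection rule
($\beta^{Af}_{Eu} = \beta_{Eu}(1+\hat\omega)$ with
$\beta^{Eu}_{Eu} = \beta_{Eu}$) and its African-ancestry binning are
mutually consistent only if the European end is anchored at factor 1,
i.e. θ is the African fraction. We adopt θ = African fraction throughout.

## The simulator

`build_anchor_study` assembles the full stated world; each piece is also
usable alone.

* **Ancestral divergence.** Balding–Nichols: ancestral frequency
  $p \sim U(0.05, 0.95)$, population frequencies Beta-distributed around
  $p$ with divergence $F_{ST}$ (default 0.15, typical African–European
  differentiation), clipped to $[0.01, 0.99]$. A test recovers
  $F_{ST}$ by the Hudson estimator to ±0.02.
* **Admixture tracts.** Per haplotype, breakpoints are Poisson with rate
  $g$ per Morgan ($g = 6$ generations by default, the order of magnitude
  inferred for African–European admixture in population references; the
  source data's value is not stated). Each tract is African with
  probability $\theta_i$. $\theta_i$ is drawn from a five-bin mixture
  matching the bin occupancies of the 8,003-individual admixed reference
  subset (373/560/475/2,556/4,039 across bins [0.1,0.35] … (0.95,1]),
  uniform within bin — the full empirical distribution is not published,
  so bin occupancies are the available constraint.
* **Linkage disequilibrium.** Real LD cannot be inherited at desk scale,
  so within 50-kb blocks haplotypes copy one of $K = 40$ founder
  haplotypes per population; founders are drawn from a latent Gaussian
  with AR(1) correlation 0.85 between adjacent sites, thresholded at the
  population frequency. Pools are independent between populations, which
  makes realized LD ancestry-specific — the local mechanism the method
  must separate from ρ. Ancestry switches snap to block boundaries so the
  truth track always matches the copying process. Without LD
  (`ld_blocks = FALSE`) alleles are independent Bernoulli draws and the
  ancestry track is per-site.
* **Causal architecture.** $J$ causal variants placed uniformly, or
  clustered: $J/10$ nonoverlapping 10-kb regions receive $J/2$ variants by
  a symmetric multinomial (repaired so no region exceeds its variant
  count) and the rest are uniform. Effects are $N(0, \sigma_j^2)$ with
  $\sigma_j = 1$ or the LDAK-style $[2p_j(1-p_j)]^{-1/4}$ — the published
  bracket is typographically ambiguous and this reading matches the cited
  LDAK convention; the scaling frequency defaults to the European (GWAS)
  background. African-background effects come from the conditional form
  $\gamma^A = \rho\gamma^E + \sigma_j\sqrt{1-\rho^2}Z$, preserving the
  marginal variance for any ρ. The factorial of
  {100, 1,000, 10,000} × {uniform, clustered} × {normal, scaled} ×
  {h² 0.3, 0.6} gives the canonical 24 scenarios (`scenario_grid`).
* **Phenotypes.** $Y_i = \sum_j \gamma_j g_{ij} + \varepsilon_i$ with
  $\sigma_e^2 = \frac{1-h^2}{h^2}\sigma_g^2$, $\sigma_g^2$ the observed
  variance of the genetic term, so each simulated cohort is calibrated to
  its own genetic variance — an admixed cohort simulated alongside a
  European one automatically keeps its heritability at the target.

### Which effect-size model rho refers to

Two interaction models are implemented (`simulate_phenotype`):

* `effect_model = "individual"` (default): the admixed cohort's phenotype
  uses $\gamma^A$ at **all** sites. This is the construction used in the
  source simulations ("without modifying effect sizes for
  non-African-ancestry individuals") and describes nonlocal interactions
  that act on the whole genome of an individual. Under it,
  $\hat\beta_{Eu}/\hat\beta_{Obs.Eu}$ estimates ρ.
* `effect_model = "tract"`: each allele copy contributes $\gamma^E$ or
  $\gamma^A$ by the true ancestry of its tract — a strictly local
  interaction model, kept for contrast. Under it European segments carry
  unchanged effects and ρ̂ stays near 1 for any generating ρ: that is a
  property of the estimand, not an estimator defect, and it is why the
  default is the individual model.

## Masking

Sites are masked per individual when the most-probable unphased ancestry
state (EA/AE collapsed — the phase of the two chromosomes is arbitrary,
so a confident heterozygous-ancestry call has EA = AE = 0.5 and must not
count as uncertain) has posterior below 0.9, or when the site lies in a
run of constant state spanning under 5 Mb of physical map. Masked entries
are zeroed in both centered matrices, and frequency fitting excludes them;
fully masked sites fall back to the unmasked mean and are flagged. Whether
the original procedure masked per site or extended windows is unstated;
whole short runs are masked per site here. Masking choice does not alter
the estimates materially provided centering is done, which matches the
published robustness claim.

## The desk-scale stated world

Acceptance runs use: admixed n = 2,000, M = 5,000 variants on five 10-Mb
chromosomes at 1 cM/Mb (10-kb variant spacing), European training
n = 5,000 and held-out European evaluation n = 2,000 (the original
evaluates its PGS on held-out individuals; the evaluation set is sized
at the training set's ratio of roughly 0.4), J = 100 uniform
normal-effect causal variants per trait, h² = 0.6, 200-replicate
bootstraps, clumping at p1 = 0.05 / r² = 0.1 / 500 kb. J = 100 of 5,000
keeps per-variant association power comparable to the full-scale setting
(which spreads up to 10,000 causal variants over 12.7 M sites). Causal
variants are excluded from the GWAS panel, so the PGS is built from tag
SNPs only and the local ratio $\beta_{Af}/\beta_{Obs.Eu}$ is strictly a
tagging quantity.

What a green run establishes: on cohorts with Balding–Nichols divergence,
block-copy LD and exponential tracts, the pipeline's ρ̂ is calibrated
(null coverage near 95%, mean ρ̂ ≈ 1 and ≈ 0.5 under those generating
values) and the tagging ratio behaves as claimed. What it does not
establish: behavior under real LD spectra, frequency spectra, imputation
error, or inferred (rather than true) local ancestry with realistic HMM
error; those require real reference data outside this package's scope.

## Numerical choices

* Frequencies and fitted values use closed-form per-site OLS sums;
  degenerate predictors (variance < 1e-8) fall back to mean(G)/2, and
  fitted frequencies are clipped to [0, 1] (clipping is flagged because it
  breaks the exact per-site zero-sum residual identity at those sites).
* GWAS uses Frisch–Waugh residualization once per trait, exact to 1e-10
  against per-variant `lm()`; monomorphic sites are flagged missing.
* Clumping breaks p-value ties by genomic order for determinism; r² is
  the squared Pearson correlation of unphased dosages in the cohort
  itself (no external panel exists at desk scale).
* The free-ω grid includes the endpoints r = 0, 1; |â| below
  1e-10·sd(Y)/sd(Z) marks ω unidentifiable rather than returning a
  spurious ratio.
* Bootstrap replicates that degenerate (constant resampled phenotype) are
  dropped and counted.
* Ancestry entropy is reported in nats (the published base is unstated);
  the kernel smoother normalizes weights per pixel, and its adaptive
  bandwidth uses $q_p = 1/(2 d_k(p)^2)$ with $d_k$ the distance to the
  k-th nearest observation — the original defers its rule to an
  unpublished note.
* NNLS is a Lawson–Hanson active-set implementation (no NNLS solver is
  available among the package's allowed dependencies), renormalized to
  the simplex.

## Known limitations

* Local-ancestry *inference* is out of scope: probabilities are inputs
  (or simulator truth, optionally blurred by `ancestry_error`).
* The simulator's LD is block-local; long-range LD and frequency-LD
  coupling of real genomes are absent, so clumping behaves more cleanly
  than on real data.
* Binary traits, mixed-model GWAS and covariance-component estimators of
  cross-ancestry correlation are not implemented.
* At desk scale the European reference cohort shares the simulator's
  founder pools with the admixed cohort's European segments; with real
  data the analogous assumption (shared LD between reference and admixed
  European segments) is an approximation the method itself relies on.
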