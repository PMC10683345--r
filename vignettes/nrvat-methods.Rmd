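---
title: "Copula-based variant-set tests for binary traits in families: model, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copula-based variant-set tests for binary traits in families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`nrvat` tests whether a set of `r` biallelic variants is associated with a
binary trait observed on `I` independent families. The joint model has two
layers:

**Marginal layer.** For individual `j` of family `i`, the trait follows a
logistic regression

$$\mathrm{logit}(\mu_{ij}) = X_{ij}^\top \gamma + G_{ij}^\top \beta,$$

with covariates `X` (including an intercept) and dosages `G` coded 0/1/2.
Coefficients are marginally interpretable: they describe each subject's risk,
not risk conditional on an unobserved family effect.

**Dependence layer.** Within a family, outcomes are coupled through a latent
Gaussian vector `Z_i ~ N(0, Gamma_i)` with

$$\Gamma_i = h^2 \Psi_i + (1 - h^2) I_{n_i},$$

where `Psi_i` is twice the kinship matrix (expected IBD sharing) and `h^2` is
the polygenic heritability on the latent scale. Setting
`Y_ij = 1{Z_ij <= qnorm(mu_ij)}` makes the joint law of `Y_i` a Gaussian
copula with the stated margins; the margins are untouched by `h^2`, which is
what makes the heritability "margin-free" here.

## The test

Association is tested as a variance component: `beta` is treated as random
with mean zero and covariance `tau * W` (diagonal per-variant weights `W`),
and `H0: tau = 0` is tested with the score-type statistic

$$Q = (Y - \hat\mu)^\top K (Y - \hat\mu),$$

where `mu_hat` comes from the null logistic fit under working independence
and `K` is a genotype-similarity kernel (the linear kernel `G W G'` by
default; quadratic, IBS, Gaussian and polynomial kernels are available).
The score derivative also carries a centering term `tr(K Delta)`; its
sampling variability is negligible relative to the quadratic form, so it is
reported as a diagnostic only and never enters the p-value.

Under the null, `Q` is distributed as a weighted sum of independent
chi-square(1) variables with weights the eigenvalues of
`Omega^{1/2} K Omega^{1/2}`, where `Omega = Var(Y - mu_hat)` accounts both
for the copula dependence (through per-family blocks `Sigma_i` built from
bivariate-normal rectangle probabilities) and for the estimation of `gamma`
(through a sandwich correction with bread `A = (1/I) sum X_i' Delta_i X_i`).
Two estimators of the meat `B` are offered: the model-based
`(1/I) sum X_i' Sigma_i X_i` (default: it reuses the fitted copula and is
smoother at moderate family counts) and the empirical
`(1/I) sum S_i S_i'` of per-family scores; both are consistent, and they
agree closely at the default design (relative difference a few percent at
`I = 120`).

The unknown `h^2` inside `Omega` is replaced by a pairwise composite
likelihood estimate: the sum over within-family relative pairs of bivariate
log-likelihood terms whose four cell probabilities come from the Gaussian
copula with pair correlation `h^2 * Psi_jk`. The defining double sum runs
over ordered pairs; the factor 2 relative to unordered pairs is constant in
`h^2` and does not move the maximizer, so unordered pairs are used, and pairs
with `Psi_jk = 0` (married-in founders) are skipped for the same reason.
Maximization is bounded scalar optimization on `[0, 1 - 1e-6]` with
tolerance `1e-4`. The estimator is boundary-censored at 0: under a true
`h^2 = 0` its sampling distribution is a point mass at 0 mixed with a
positive half-normal-like component (mean around 0.07 at `I = 120`), which
is the expected behaviour of a variance-type parameter at the edge of its
space, not bias in the interior.

## Simulation machinery

The package generates the data it is validated on.

**Pedigrees.** The default design is 120 families: 40 parent-parent-child
trios, 40 two-parent/two-child quartets, and 40 three-generation octets (two
grandparents, their two children with married-in spouses, and two
first-cousin grandchildren) — 600 subjects, 320 founders, 280 nonfounders.
Kinship is computed by the standard recursion over a founder-first order;
inbred pedigrees (self-kinship above 1/2) are rejected because `Gamma`
requires a unit diagonal.

**Genotypes.** Founder haplotypes for `r` linked SNPs come from thresholding
a latent AR(1) Gaussian process at `qnorm(maf_l)`. The target is stated on
the allele scale: the squared Pearson correlation between adjacent minor
allele indicators equals `d2` (default 0.16). Because thresholding deflates
correlation, each adjacent latent correlation is calibrated numerically by
root-finding on the bivariate-normal orthant probability; infeasible `d2`
(beyond the Frechet bound for the MAF pair) is a reported error. Defaults:
`r = 20` SNPs with MAFs drawn uniformly from (0.003, 0.01) — deeply rare
variants, where a typical region carries only a handful of carriers.
Nonfounders receive one whole haplotype from each parent, chosen uniformly:
with 20 tightly linked SNPs recombination within the region is negligible,
and whole-haplotype transmission preserves the founder LD exactly; an
optional per-interval crossover probability is available.

**Phenotypes.** Four generators share the marginal layer and differ in the
dependence:

* `simulate_setting1()` — the Gaussian copula itself (the model the test
  assumes);
* `simulate_glmm()` — a logistic GLMM with family random effects
  `b_i ~ N(0, h^2 Psi_i)` (a conditional model: the margins shift with
  `h^2`);
* `simulate_t_copula()` — latent multivariate Student t (df = 3 by default)
  thresholded at `qnorm(mu)`. Thresholding a t variate at a normal quantile
  deliberately mis-specifies the margins (realized means are
  `pt(qnorm(mu), df)`); this is kept as the primary behaviour because the
  robustness scenario is defined that way, with a `correct_margins` flag for
  users who want a pure t copula with preserved margins;
* `simulate_chisq_copula()` — the latent vector is pushed through the
  distribution function of `(z + a)^2` (noncentrality `a`, default 1) and
  back through `qnorm`, giving standard-normal margins with an asymmetric
  chi-square copula. `sign(0)` is taken as 0 and the uniform is clipped to
  `[1e-12, 1 - 1e-12]` so `qnorm` stays finite at the measure-zero point
  `z = -a`.

Covariates default to an intercept, `X1 ~ U[0, 1]` and `X2 ~ Bernoulli(0.2)`
with coefficients `(-2, 1, 1)` (a ~17% average prevalence). Under the
alternative, 5 of the 20 SNPs are causal with effects
`beta ~ N(0, tau * w)`; `tau` defaults to 0.05 or 0.2 in the experiment
grids. MCAR and covariate-dependent MAR masking are available; analysis is
listwise (masked subjects are removed, their relatives keep their kinship
through the removed members).

What the generators do *not* emulate: ascertainment/selection bias (the
sampling rules for that scenario are not public), genotyping error,
recombination maps, population stratification, or empirical GRM relatedness
(the test requires block-diagonal family structure). Passing tests therefore
speak to the method's behaviour under clean family sampling, not to
robustness against those artefacts.

## Numerical choices

* **Bivariate normal CDF** (`pbvnorm()`): Genz's BVND algorithm —
  Drezner-Wesolowsky quadrature with a transformed high-correlation branch —
  with the Gauss-Legendre rule generated at run time by Golub-Welsch.
  Accuracy is near machine precision, comfortably below the `1e-7` the
  copula cells need.
* **Mixture-of-chi-square tails** (`imhof_tail()`): exact
  characteristic-function inversion (Imhof's formula) by adaptive quadrature
  after two transformations that matter in practice: the spectrum is
  rescaled by `max(theta)` (the tail is invariant; without this, kernels
  with large entries push all integrand features toward `u = 0` and the
  quadrature sees only zeros), and the half-line is mapped to `(0, 1)` so
  the slowly decaying oscillatory tail of small spectra is resolved. Single
  or equal eigenvalue spectra short-circuit to exact scaled chi-square
  forms. When the inversion does not converge, Liu's moment-matching
  approximation is used and reported (`pvalue_method` in results). P-values
  are clipped to `[1e-16, 1]`.
* **Spectrum of `Omega^{1/2} K Omega^{1/2}`**: `Omega` is exactly singular
  by construction (the score equations annihilate the covariate directions)
  and can be marginally indefinite at finite `I`; negative eigenvalues are
  clipped at zero (count and mass reported, warning if the clipped mass
  exceeds `1e-3` of the trace). Any factor `H` with `H'H = Omega_+` yields
  the same spectrum via `eig(H K H')`, so a Cholesky factor is used when it
  exists and the clipped eigen square root otherwise; kernels that carry a
  low-rank factor `C` (`K = CC'`, e.g. linear) use the `r x r` matrix
  `C' Omega_+ C` instead. Eigenvalues below `1e-10 * max(theta)` are
  dropped; an all-zero spectrum (monomorphic region) is an error.
* **Weights**: "MAF-based" is resolved as the Beta(1, 25) density
  (`25 (1 - maf)^24`), the de facto standard for rare-variant weighting;
  flat and custom vectors are accepted. Weight MAFs are computed from
  founders by default — the unbiased allele frequency in pedigree data —
  with a full-sample option. Variants monomorphic in the MAF source are
  dropped before weighting.
* **Null fit**: IRLS followed by Newton polishing to score norm `< 1e-8`;
  quasi-separation and rank deficiency are reported as errors with the
  offending condition named.

## Experiment design and problem sizes

`run_type1_experiment()` and `run_power_experiment()` reproduce the
validation designs at desk scale: 2000 null replicates (against 10,000 in
full-scale studies) and 200-1000 power replicates (against 1000), with one
master seed per experiment from which per-replicate seeds are drawn so any
single replicate can be reproduced in isolation. The package's own test
suite uses these sizes: 2000 replicates for the Setting-1 calibration check,
800 for the GLMM and chi-square-copula robustness checks, 200 per
variance-component value for the power-monotonicity check, 100 replicates of
300 octet families for heritability recovery, and 2 x 10^4 replicates for
the empirical-covariance keystones. At these sizes the binomial/Wilson
intervals quoted in the tests are the operative tolerance.

## Known limitations

* Families must be independent; empirical GRMs (non-block-diagonal) are out
  of scope by design.
* Asymptotics are in the number of families; a warning is raised below
  `I = 30`, and small-`I` corrections are not attempted.
* No inbreeding or monozygotic twins (`Psi` diagonal fixed at 1).
* The t-copula robustness scenario is known to inflate type-I error
  slightly — that is a property of the method being mis-specified, and the
  package reproduces it rather than corrects it.
* Continuous or mixed traits, functional variant effects, SKAT-O-style
  kernel combination and competitor methods are not implemented; external
  p-values can be summarized with `summarize_multiple_testing()`.
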