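---
title: "Additive and dominance animal models for eggshell color: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive and dominance animal models for eggshell color: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggherit)
```

## The problem

Eggshell color in crossbred laying hens — measured on the CIE L\*a\*b\*
scale (lightness, redness, yellowness) — is partly under dominance
control: in a White Leghorn × blue-shelled (Dongxiang) F2 cross, the blue
shell allele is dominant, so an additive-only genetic evaluation
misattributes part of the genetic variance. `eggherit` implements the
complete pedigree-based Bayesian workflow for such data: relationship
matrices from the pedigree, univariate animal models with and without a
dominance component fitted by Gibbs sampling, bivariate additive models
for genetic and phenotypic correlations, DIC model comparison, and an F2
cross simulator so every stage can be validated by parameter recovery.

## The model

For one trait, with one averaged record per hen,

$$ y = Xb + Z_a a + Z_d d + e, $$

where $X$ holds an intercept and the hen's inbreeding coefficient $F$
(inbreeding both depresses the trait mean and rescales genetic variances,
so it enters as a fixed covariate), $a \sim N(0, \sigma_a^2 A)$ are
breeding values with $A$ the numerator relationship matrix,
$d \sim N(0, \sigma_d^2 D)$ are dominance deviations with $D$ the
dominance relationship matrix, and $e \sim N(0, \sigma_e^2 I)$. The
bivariate model stacks two traits with additive covariance
$G_0 \otimes A$ and record-level residual covariance $R_0$ (2×2), from
which the genetic correlation $r_g = G_{0,12}/\sqrt{G_{0,11} G_{0,22}}$
and phenotypic correlation
$r_p = (G_{0,12}+R_{0,12})/\sqrt{(G_{0,11}+R_{0,11})(G_{0,22}+R_{0,22})}$
are computed per posterior draw.

### Relationship matrices

* `additive_matrix()` uses the tabular method:
  $a_{ij} = \tfrac12(a_{j,s_i} + a_{j,d_i})$ for $j<i$ and
  $a_{ii} = 1 + \tfrac12 a_{s_i d_i}$; unknown parents contribute zero.
  `compute_inbreeding()` is $F_i = \mathrm{diag}(A)_i - 1$.
* `additive_inverse()` applies Henderson's rules with the inbreeding
  adjustment (Mendelian-sampling variance
  $0.5 - 0.25(F_s + F_d)$, with the one-parent and founder variants), so
  the inverse is sparse with nonzeros confined to animal–sire–dam
  triples. It is validated against the dense inverse in the tests.
* `dominance_matrix()` uses the classical parent-pair formula
  $d_{ij} = 0.25\,(a_{s_i s_j} a_{d_i d_j} + a_{s_i d_j} a_{d_i s_j})$
  with $\mathrm{diag}(D) = 1$. For inbred animals this is an
  approximation: exact dominance relationships under inbreeding require
  condensed identity coefficients that standard pedigree software (and
  this package) does not compute. The simulator uses the same $D$, so
  recovery tests are internally consistent; results on real inbred data
  inherit the approximation.

Both $A$ and $D$ are checked against an independent gene-dropping oracle
(Monte-Carlo transmission of founder alleles) in the test suite.

### Priors and chain settings

Each free variance has the weakly informative inverse-Wishart prior with
scale $V_0 = 1$ and degrees of freedom $\nu_0 = 0.002$, which in one
dimension is exactly a scaled inverse-chi-square$(\nu_0, V_0)$ — the
long-standing default of the Bayesian animal-model software family this
package mirrors. Fixed effects get an improper flat prior. The default
chain (`chain_spec()`) runs 500,000 iterations, discards 20,000 as
burn-in and thins by 100, retaining 4,800 draws.

For the bivariate model the default prior is
$\mathrm{IW}(V_0 = I_2, \nu_0 = p - 1 + 0.002 = 1.002)$: under an
inverse-Wishart, the marginal distribution of a diagonal element has
degrees of freedom $\nu_0 - p + 1$, so this choice preserves exactly the
univariate $0.002$ marginal on each variance while being far less
singular at perfect correlation. With $\nu_0 = 0.002$ in two dimensions
the prior density grows like $(1-\rho^2)^{-5/2}$ near $|\rho| = 1$ and
can pile posterior mass onto a degenerate $G_0$ whenever the likelihood
is compatible with a strong correlation; $\nu_0 = 1.002$ reduces the
exponent while keeping the stated per-variance prior.

A residual variance can be pinned (`fix_residual_at`), the standard
device when dominance and residual variances mix poorly — as is typical
for shell lightness, where a dominance component is present; every
retained residual draw then equals the pinned value exactly.

## The samplers

`gibbs_univariate()` works in a reduced parameterization: the genetic
effects of animals without records are integrated out analytically (the
marginal of a multivariate normal is the corresponding submatrix of
$A$ or $D$), which leaves the posterior of every variance component,
heritability, correlation, DIC, and record-level effect unchanged while
shrinking the state to the phenotyped animals. Because each hen
contributes exactly one averaged record, $Z^\top Z = I$ and the full
conditional of the effects is *diagonal in the eigenbasis* of the
relationship submatrix — so all additive effects (and, separately, all
dominance deviations) are drawn as a single joint block at the cost of
two matrix–vector products. The sparse Henderson inverse remains
available for applications that need it (exported, tested), but the
sampler itself never forms mixed-model equations.

Variance components are *not* updated from their centered conjugate full
conditionals, which random-walk hopelessly when an effect and the
residual are weakly separated (one record per hen means $d_i$ and $e_i$
are confounded for every hen without phenotyped full sibs). Instead:

* each variance is slice-sampled from its marginal with its own effect
  integrated out — in the eigenbasis the projections are independent
  $N(0, \sigma^2\lambda_i + \sigma_e^2)$, so the marginal is $O(n)$ —
  and the effect is then redrawn from its conditional. This is a valid
  blocked draw of (variance, effect);
* every 25 iterations a joint Metropolis step updates
  $(\sigma_a^2, \sigma_d^2, \sigma_e^2)$ with *both* genetic effects
  integrated out exactly (one Cholesky of
  $\sigma_a^2 A_s + \sigma_d^2 D_s + \sigma_e^2 I$ per evaluation),
  which moves the chain along the additive/dominance/residual ridge in
  one step.

The bivariate sampler uses the analogous structure: in the eigenbasis
the data projections are independent bivariate normals with covariance
$\lambda_i G_0 + R_0$, so a collapsed slice-sampling sweep over a
log-variance/Fisher-z parameterization of $(G_0, R_0)$ costs $O(n)$ per
evaluation; breeding-value pairs are then drawn per eigen-coordinate from
2×2 conjugate normals, and conjugate inverse-Wishart refreshes follow.

All samplers draw their randomness from R's RNG, so a `chain_spec()`
seed makes every chain bit-reproducible. Correctness is established in
the tests against (i) the closed-form conjugate posterior for a single
founder record, (ii) the direct mixed-model-equations solution for all
location effects at pinned variances, (iii) exact one-dimensional
numerical integration of the variance posterior, and (iv) prior-only
sampling (zero records) against scaled inverse-chi-square quantiles.

### Initialization and numerical safeguards

Chains start with the sample phenotypic variance split equally over the
free components and location effects at zero; with seed control and the
collapsed updates, overdispersed multi-chain starts are unnecessary for
the documented single-chain workflow. Eigenvalues of relationship
submatrices are clamped at $10^{-10}$; a dominance matrix that is not
positive definite gets a $10^{-8}$ ridge with a warning. A collinear
fixed-effect column (e.g. the inbreeding covariate in a fully non-inbred
pedigree) is dropped with a message. DIC ties within a margin of 2 are
reported as equivalent and resolved toward the simpler (additive) model.

## Deviance and DIC

The per-draw deviance is conditional on the random effects,
$-2\log N(y \mid Xb + a + d, \sigma_e^2 I)$, matching the DIC convention
of the software family this package mirrors:
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$
evaluated at the posterior means of the location effects and the
residual (co)variance. Two caveats are documented rather than hidden.
First, $p_D$ can be negative when a variance posterior is strongly
skewed. Second, with the near-$1/\sigma^2$ prior the conditional-focus
DIC can *reward* a dominance model on data with no dominance variance:
posterior excursions into states where $\sigma_e^2$ is tiny and $d$
absorbs the residuals produce extreme negative deviances, and the effect
only disappears when the data pin the residual well. The DIC
model-selection checks in the tests therefore pin the residual at its
generative value in the no-dominance arm — the same identifiability
device as the lightness analysis — while the substantial-dominance arm
runs with all variances free.

## The F2 cross simulator

`generate_cross_pedigree()` emulates a two-line F2 design: two unrelated
founder lines (default 40 P0 per line, split 1:3 sires:dams), reciprocal
line crosses producing the F1 (round-robin parent assignment, so designs
with enough founders provably yield unrelated F1), and an F2 generation
organized into half-sib families (one cock over several hens) plus
randomly mated pairs. The default design is the study structure this
package targets: 49 F1 sires × 639 F1 dams, 25 half-sib + 24 randomly
mated families, 2,626 F2 hens. Inbreeding is induced by forcing a
fraction of matings (default `full_sib_mating_rate = 0.28`) to be
between F1 full sibs, which yields F2 inbreeding spanning 0–0.25 with a
cohort mean near 0.079 under the default design — chosen once to match
the study population's reported inbreeding distribution, with the small
remainder contributed by shared P0 grandparents.

`simulate_phenotypes()` draws breeding values by the forward
Mendelian-sampling recursion (so $\mathrm{cov}(a) = \sigma_a^2 A$
exactly, including inbred animals), dominance deviations jointly from
$N(0, \sigma_d^2 D)$, and per-hen records as the average of 2–3 eggs.
Per-egg measurement noise defaults to zero so that $\sigma_e^2$ is
exactly the residual variance the model estimates; a positive
`egg_noise_sd` inflates the apparent residual by roughly
`egg_noise_sd^2 / k` for `k` eggs, documented as a realism knob. All
latent effects are stored, so every record reconstructs exactly as
`mu + beta_f * F + a + d + e` in the tests.

What the simulator does *not* emulate: the discrete blue-shell locus
itself (a retrovirus insertion with a major dominant effect — the
simulator is polygenic), maternal and common-environment effects, age
and nutrition trends, repeated records, and selection. Passing recovery
tests therefore show that the estimation machinery inverts its own
generative model at realistic scale, not that real eggshell data meet
these assumptions.

## Recovery experiments and problem sizes

The recovery experiments in `scripts/acceptance.R` and the acceptance
tests use a desk-scale version of the design — 600 phenotyped hens from
49 F1 sires × 150 F1 dams in the same 25 + 24 family structure
(offspring per dam preserved) — with 50,000-iteration chains (10,000
burn-in, thin 10) and five replicate seeds:

* lightness: generative $h_a^2 = 0.65$, $h_d^2 = 0.23$ (total variance
  1), dominance model with the residual pinned at its generative value,
  mirroring the published lightness analysis where the residual was
  fixed for identifiability;
* yellowness: generative $h^2 = 0.60$, additive model;
* lightness–yellowness: bivariate additive model with $G_0$ built from
  the published additive variances and genetic correlation $-0.844$, and
  $R_0$ chosen to reproduce the published phenotypic correlation
  (non-additive lightness variance folded into the residual, since the
  bivariate model is additive-only — the published correlation tables
  likewise report only genetic and phenotypic correlations).

Two honest limitations of these experiments, measured during
development and left as found: at 600 hens the near-$1/\sigma^2$ prior
retains a plateau of posterior mass at $\sigma_d^2 \approx 0$, which
biases the *posterior-mean* dominance share downward (and the additive
share upward) by about 0.05 on average over replicate datasets — an
effect of the stated prior at this sample size, not of the sampler, as
verified against exact numerical integration; and the dataset-to-dataset
spread of posterior means (SD ≈ 0.09–0.13 for heritabilities) reflects
genuine founder and Mendelian sampling in a population with ~80 P0
founders and 49 families. Both shrink at the full study scale.

## Other documented conventions

* Effective population size: `pedigree_stats()` computes equivalent
  complete generations $t$, individual increases in inbreeding
  $\Delta F_i = 1 - (1-F_i)^{1/(t_i-1)}$, and
  $N_e = 1/(2\,\overline{\Delta F})$ over the reference cohort — the
  animals carrying the last generation label (all non-parents when
  labels are absent). Published $N_e$ values depend on this reference
  choice, which their source does not state; ours is a documented
  convention, not a claim about that computation.
* The inbreeding covariate is coded as a proportion (0–1), not percent.
* Heritability point estimates: the posterior mean of the per-draw
  ratio is the primary summary (`tidy()`); the ratio of posterior means
  can be recovered from the variance-component rows. The two differ in
  skewed posteriors, and published tables do not always say which was
  printed — both are therefore available.
* Reported intervals are 95% highest-posterior-density intervals.
* Outlier screening is a single pass at ±3 SD with mean and SD computed
  on the input data; it is deliberately not iterated.
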