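---
title: "Sire-dam DHGLM for harvest-weight mean and uniformity: models, design and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sire-dam DHGLM for harvest-weight mean and uniformity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwuni)
```

## The problem

Harvest weight (HW) in group-reared aquaculture species such as Pacific white
shrimp varies enormously even among full sibs. Part of that variation is
itself heritable: some genotypes produce consistently uniform offspring, some
produce erratic ones. Harvest-weight *uniformity* (HWU) is quantified as the
genetic variance in residual variance, and because animals grow in groups, a
second social layer matters: an animal's genes also affect its cage mates'
growth (indirect genetic effects, IGEs). This package implements the full
evaluation chain for both traits: a sire-dam double hierarchical generalized
linear model (DHGLM) fitted by iteratively reweighted average-information
REML, with optional IGEs, over pedigree (A) or single-step genomic (H)
relationship matrices, plus the derived genetic parameters and
cross-validated prediction accuracy.

## The model

The mean model and residual-variance model are fitted jointly on the stacked
responses $(y, \psi)$:

$$
\begin{pmatrix} y \\ \psi \end{pmatrix} =
\begin{pmatrix} X & 0 \\ 0 & X_v \end{pmatrix}
\begin{pmatrix} b \\ b_v \end{pmatrix} +
\begin{pmatrix} Z_{sire}+Z_{dam} & 0 \\ 0 & Z_{sire}+Z_{dam} \end{pmatrix}
\begin{pmatrix} a_u \\ a_{uv} \end{pmatrix} +
\begin{pmatrix} Z_s a_s \\ 0 \end{pmatrix} +
\begin{pmatrix} Z_t t \\ 0 \end{pmatrix} +
\begin{pmatrix} e \\ e_v \end{pmatrix}
$$

* $X$ carries intercept, sex and the sex-specific regression on initial
  (tagging) body weight; $X_v$ carries intercept and sex only.
* $a_u, a_{uv}$ are parental (sire-dam) effects for the mean and for the log
  residual variance, jointly normal over the relationship kernel (A or H)
  with a free $2\times2$ covariance.
* $a_s$ are parental indirect effects; each record's $Z_s$ row counts, per
  parent, how many of the focal animal's cage mates are that parent's
  offspring (11 on own-family parents and 12 on the others in a full
  3-families-of-12 cage). $a_s$ is correlated with $a_u$; the
  $a_{uv}$--$a_s$ covariance is fixed at zero (it is not identifiable from
  this design and is not part of the model).
* $t$ is an iid cage effect. A common full-sib environmental effect is
  deliberately not modeled: with one sire-dam pair per family it is
  confounded with the parental effects and breaks convergence.
* The dispersion response is the linearized log squared residual
  $\psi_i = \log\hat\sigma^2_{e,i} + (\hat e_i^2/(1-h_i) -
  \hat\sigma^2_{e,i})/\hat\sigma^2_{e,i}$, with $h_i$ the leverage of record
  $i$ in the mean model.
* Residuals are independent with known weights:
  $\mathrm{Var}(e_i) = \sigma^2_\epsilon\,\hat\sigma^2_{e,i}$ and
  $\mathrm{Var}(e_{v,i}) = \sigma^2_{\epsilon v}\,2/(1-h_i)$. The scales
  $\sigma^2_\epsilon, \sigma^2_{\epsilon v}$ are estimated and should sit
  near 1 when the model is well specified; their drift away from 1 is a
  useful misspecification diagnostic.

The outer loop alternates a bivariate weighted AI-REML fit with the
recomputation of residuals, leverages,
$\hat\sigma^2_{e,i} = \exp(X_v \hat b_v + (Z_{sire}+Z_{dam})\hat a_{uv})$,
$\psi$, and the weights, until the restricted log-likelihood stabilizes
(default `tol_outer = 1e-4`, at most 50 outer iterations; the inner REML uses
`tol_inner = 1e-6`, variances bounded below by `1e-8`). The per-observation
variance update is relaxed on the log scale; the relaxation factor starts at
1 and is reduced automatically when the outer log-likelihood oscillates,
which stabilizes small, weakly identified data sets without changing the
fixed point. AI steps are guarded by step-halving against the restricted
likelihood, with an EM step on the covariance blocks as fallback, so the
accepted trajectory is monotone.

## Scales: how components are reported

Sire-dam models carry a perennial scale ambiguity, and published tables mix
conventions. This package fits raw per-parent components and reports three
explicit scales in every fit:

* **raw**: per-parent variances and covariances exactly as fitted;
* **reported** (the convention of the published tables this package mirrors):
  direct variance left per-parent (`sigma_au_sq`), indirect variance and the
  dispersion variance multiplied by 4, covariances by 2 — on this scale the
  arithmetic identities
  $\sigma^2_{TBV} = 4\sigma^2_{a_u} + 4(n-1)\sigma_{a_u,a_s} +
  (n-1)^2\sigma^2_{a_s}$ and
  $h^2 = 4\sigma^2_{a_u}/\sigma^2_p$ with
  $\sigma^2_p = 2\sigma^2_{a_u} + [(n-1)\sigma^2_{a_s}] + \sigma^2_t +
  \sigma^2_e$ hold, and genetic correlations equal the raw correlations;
* **additive**: individual scale, direct variance $4\sigma^2_{a_u}$.

The derived-parameter functions (`tbv_variance()`, `heritability()`,
`uniformity_heritability()`, `gcv_uniformity()`, ...) take explicitly labeled
inputs, and `genetic_parameter_report()` prints all of them with a scale
note. `GCV_v` is computed as $\sqrt{\exp(\sigma^2_{a_v,exp})-1}$, which is
the $\sigma_{a_v}/\sigma^2_E$ definition after the exponential-to-additive
conversion $\sigma^2_{a_v} = \sigma_E^4(\exp(\sigma^2_{a_v,exp})-1)$,
$\sigma^2_E = \sigma^2_e - 2\sigma^2_{a_u}$.

## The 3FAM design

Each cage holds three families, each family is tested in three cages, and no
family pair meets twice — a partial Steiner triple system. `build_layout()`
constructs it from the cyclic starter triple $\{i, i+1, i+3\} \pmod n$
(exact for any $n \ge 7$; the Fano plane at $n = 7$), then repairs the
kinship and body-weight-CV content constraints by seeded stochastic swaps
that preserve the structure. Predicted per-cage CV uses the mixture
mean/variance of the three families' tagging-weight statistics, since the
design is made before phenotyping. Failure to satisfy content constraints
within the swap budget is reported as violations, never silently.

## What the synthetic-data generator emulates

`simulate_phenotypes()` generates the exact statistical structure the model
assumes: correlated direct, indirect and dispersion effects, iid cage
effects, and log-normal heteroscedastic residuals, over a pedigree of
full-sib families allocated by a 3FAM layout. Two generating scales are
supported, and the distinction matters:

* `"individual"` draws $(a_d, a_s, a_v)$ per individual from
  $\Sigma \otimes A$ (Mendelian sampling included). On this scale the
  population identities hold exactly — the Monte-Carlo variance of
  $TBV_i = a_{d,i} + (n-1)a_{s,i}$ matches `tbv_variance()` — but a sire-dam
  model sees the within-family half of the direct variance as homoscedastic
  residual, so the dispersion component it estimates is the genetic variance
  of the log *total* residual variance, attenuated relative to the
  generating $\sigma^2_{a_v,exp}$ by roughly the squared ratio of modulated
  to total residual variance. That attenuation is a property of the sire-dam
  DHGLM on such data, not an estimation error.
* `"sire_dam"` draws effects at the parent level and gives each offspring
  the sum of its parents' effects — exactly the data-generating process the
  fitted model assumes. This is the scale used to calibrate parameter
  recovery of the machinery itself.

Defaults mirror the trial the package is designed around: 40 families of 36,
cages of $3\times12$, tagging weight $\mathcal N(4.8, 0.5^2)$ g truncated
positive, survival 92.71% applied as non-informative thinning, truth
$\sigma^2_{a_u} = 0.14$, $\sigma_{a_u a_s} = 0.002$,
$\sigma^2_{a_s} = 0.00015$, $\sigma^2_t = 0.03$,
$\sigma^2_{a_v,exp} = 0.25$, and a dispersion intercept of $\log 0.52$ under
the sire-dam scale so that the residual and phenotypic variances land near
the published magnitudes (0.52 and 0.83 g²). Sex effects (0.9 g female
advantage, slopes 2.5/2.7 g/g on tagging weight, +0.1 on the female log
residual variance) are nuisance structure for the fixed-effect part.

Genetic effects can alternatively be built from gene-dropped SNP genotypes
(`genetic_basis = "markers"`): per-SNP effect vectors covariance-matched to
the same $\Sigma$, so realized rather than expected relationships structure
the effects. `simulate_pedigree(..., base_pop_size = )` can additionally
create an unrecorded base generation, giving the nominal founders cryptic
relatedness that the analysis pedigree (after `truncate_pedigree()`) cannot
see but genotypes can. This is the regime in which single-step genomic
evaluation has a genuine information advantage; with pedigree-drawn effects
and markers independent of them, ssGBLUP cannot beat pBLUP even in
principle, so passing cross-validation comparisons on such data would be
meaningless. What the passing tests do *not* show about real data: linkage
and LD (loci are unlinked), genotype-dependent survival, selection over
generations, or genotype-by-environment interaction.

## Relationship matrices

`build_A()` uses the tabular recursion (diagonal $1+F$). `qc_genotypes()`
applies the fixed filter order SNP missingness ($<0.10$) → MAF ($>0.05$) →
individual call rate (drop $\le 0.80$), with strict inequalities; the
`QCReport` records order and per-filter counts. `build_G()` is VanRaden
method 1 with observed allele frequencies and per-SNP mean imputation of
missing codes. `build_H()` rescales G so its mean diagonal and off-diagonal
match A22, blends 5% of A22 back in for invertibility, and propagates the
genomic update to ungenotyped individuals by the standard block formulas.
Blending and tuning constants are the de-facto single-step defaults; no
derived quantity in this package depends on their exact values, and
`build_H(..., blend_weight = 1, tune = FALSE)` recovers pure G.

In the sire-dam model the kernel that enters the likelihood is the parent
submatrix of A or H; genomic information on offspring reaches the parents
through the single-step construction.

## Cross-validation

`run_cv()` performs replicated k-fold cross-validation (default
$10 \times 20$) comparing pBLUP (A) and ssGBLUP (H) for HW and HWU.
Adjusted phenotypes $y^* = y - X\hat b$ and $\psi^* = \psi - X_v\hat b_v$
come from the pedigree no-IGE reference fit; both methods are evaluated on
identical folds. Variance components, weights and $\psi$ are fixed at their
full-data estimates during the fold refits — re-estimating them in every
fold would add per-fold REML instability without changing the comparison —
and masked animals lose both their mean and dispersion records. Predictions
for masked animals are the parental sums, so accuracy is family-level by
construction; IGE models are excluded by default (mirroring their
convergence fragility in this data regime) but can be opted in.

## Numerical choices and degenerate inputs

Tie-breaks in the layout search are lexicographic by family id. Variances
are clamped at $10^{-8}$; covariance updates that would leave a
non-positive-semidefinite block are rejected and replaced by step-halved or
EM steps. Leverages are clamped to $[0, 1-10^{-8}]$ before entering
$\psi$; the dispersion linear predictor is clamped to $\pm 30$ on the log
scale. Monomorphic-only genotype input (zero VanRaden denominator), singular
A22, cyclic pedigrees, leverage $\ge 1$ and non-positive per-observation
variances are hard errors. Non-convergence of the outer loop is a warning
with a partial fit returned and flagged, except in `adjust_phenotypes()`,
which refuses an unconverged reference fit.

## Problem sizes used in the test suite

The shipped tests calibrate the machinery at the trial geometry (40 families
× 36, survival 0.9271) with 10 seeded replicates for parameter recovery,
null calibration of the dispersion variance, and the directional effect of
omitting IGEs; structural unit tests run on a 9-family × 12 geometry. The
genomic cross-validation fixture uses 24 families × 24 with 3,000 unlinked
SNPs, a 12-animal unrecorded base generation and marker-based effects —
sizes chosen so the whole suite exercises every code path at meaningful
signal-to-noise on a single CPU.

## Known limitations

* The sire-dam parameterization predicts family means; Mendelian-sampling
  deviations are not in the model, which caps attainable CV accuracy and is
  why genomic gains here flow only through the parent-block of H.
* The dispersion side is a linearized (Taylor) approximation, not an exact
  likelihood; with few families its genetic variance is weakly identified
  and the adaptive relaxation mainly manages that regime. At the 40-family
  trial geometry the packaged calibration shows a modest *upward* bias of
  $\hat\sigma^2_{a_v,exp}$ (on the order of +20% of the generating value,
  vanishing at larger family numbers): the linearized response slightly
  amplifies family-level dispersion signal (convexity around the shrunken
  predictor) and squared residuals of relatives are correlated beyond the
  modeled $2/(1-h)$ noise. Dispersion-variance estimates from data sets of
  this size should be read with that in mind.
* Standard errors for $h_v^2$ and $GCV_v$ are not provided.
* The $a_{uv}$--$a_s$ covariance is fixed at zero, and exponential-scale
  conversions assume log-normal residual variances.
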