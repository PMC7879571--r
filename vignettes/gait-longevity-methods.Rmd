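---
title: "Methods: linking early gait traits to functional longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking early gait traits to functional longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gaitlong implements a complete quantitative-genetic pipeline for a question
that sport-horse breeders face: can objective gait measurements taken on
4-5-year-old jumping horses predict how long those horses' relatives will
stay in competition? The pipeline has five stages, each exposed as
package functions and each testable on synthetic data with known truth:

1. a discrete-time proportional-hazards model of years in competition with
   correlated sire and maternal-grandsire effects (`fit_survival()`);
2. deregression of the resulting breeding values into weighted
   pseudo-phenotypes (`deregress_ebv()` and friends);
3. pedigree and genomic relationship machinery combined by single-step
   GBLUP (`build_A_inverse()`, `build_G()`, `build_H_inverse()`);
4. constrained bivariate REML joining one gait principal component with the
   longevity pseudo-phenotypes (`reml_bitrait()`);
5. a GWAS of longevity by SNP-effect back-solution (`backsolve_snp_effects()`,
   `snp_pvalues()`).

This vignette records the models, the numerical choices, and what the
synthetic-data experiments do and do not demonstrate.

## The survival model

Functional longevity is the number of years a horse stays in jumping
competition, *net of its performance level*: the model conditions on how
well the horse scores, so that what remains is staying power rather than
sporting talent. Time is discrete (career years $j = 1, 2, \dots$). The
hazard of leaving competition in year $j$ for horse $i$ is

$$\lambda(t_j, z_i) = 1 - \alpha_j^{\exp(z_i'\beta + u_{s(i)} + \tfrac12 u_{mgs(i)})},$$

where $\alpha_j \in (0,1)$ is the baseline probability of surviving year
$j$, $z_i'\beta$ collects fixed class effects (region and month of birth,
calendar year, age at first start, and an 87-level performance class), and
$u$ holds sire effects with $\mathrm{Var}(u) = A\sigma_s^2$ over the
stallion pedigree. The maternal grandsire contributes half a transmitting
ability; the $\tfrac12$ coefficient is the standard convention that makes
the sire-model heritability
$$h^2 = \frac{4\sigma_s^2}{\sigma_s^2 + 1/p}$$
coherent, with $p$ the proportion of uncensored records
(`heritability_sire()`). At the study's estimates
($\sigma_s^2 = 0.03947$, $p = 0.78$) this gives $h^2 = 0.12$.

Writing $\alpha_j = \exp(-e^{\gamma_j})$, each horse-year is a Bernoulli
trial with a complementary-log-log link, so the joint mode in
$(\gamma, \beta, u)$ is found by penalised Newton iterations with sparse
linear algebra. The sire variance maximises the Laplace-approximate
marginal posterior, searched on a $\log\sigma_s^2$ grid and refined by
golden section. Prediction-error variances $t_i$ come from the diagonal of
the inverse negative Hessian at the mode. Newton failures, step-halving
exhaustion and grid-boundary solutions are all reported through the fit's
`converged` flag rather than silently.

The performance-level covariate deserves a note: year 1 is classed by
gender alone (3 classes); later years bin the z-score of the
log-transformed points earned the *previous* year (8 bins in year 2, with
a no-points class from year 3, and a wider $\pm 2$ range from year 4),
always crossed with gender, totalling $3 + 24 + 27 + 33 = 87$ classes.
Bins are right-closed, so a z-score of exactly 0 falls in $(-0.5, 0]$;
the choice is deterministic, documented, and asymptotically irrelevant.

## Deregression

Survival-model EBVs cannot enter a linear bivariate model directly: they
are shrunken, and they borrow information from relatives. The deregression
stage reverses both. Reliability is $R_i = 1 - t_i/\sigma_u^2$. Information
content is additive on the scale $T = \lambda R/(1-R)$ with
$\lambda = \sigma_\epsilon^2/\sigma_u^2$: pruning subtracts the
parent-average information implied by the *cleaned* parental reliabilities
($R_{PA} = (R'_{sire} + R'_{dam})/4$, missing parents contributing zero) in
a downward pedigree pass iterated to a fixed point. Progeny-derived
information is deliberately retained — it is the stallion's own evidence.
The weight implied by a cleaned reliability is $w = \lambda R'/(1-R')$, and
the pseudo-phenotypes are
$$y^* = D\,(D^{-1} + \sigma_u^{-2}A^{-1})\,\hat u, \qquad
  D = \mathrm{diag}(\sigma_\epsilon^2/w_i).$$
The central contract, tested to machine precision, is the exact BLUP
round-trip: re-estimating breeding values from $(y^*, w, A)$ returns
$\hat u$ for any positive weights. Stallions with cleaned reliability below
0.40 are dropped, not shrunk.

The variance ratio is set to $\lambda = (1-h^2)/h^2$ at the
survival-analysis heritability ($\approx 7.37$ at $h^2 = 0.1195$). This is
an inference, not a published fact, but it is the unique choice that
reproduces the published weight extremes (minimum 5.00 at $R' = 0.404$,
maximum $\approx 272$ at $R' = 0.974$), and the same ratio is used for the
fixed longevity components of the bivariate model
($\sigma_{u^*}^2 = \sigma_s^2$, $\sigma_{\epsilon^*}^2 = \lambda\sigma_s^2$)
so that weights and reliabilities stay coherent across stages. The genetic
correlation is invariant to the overall scale of the trait-2 components,
which is why this placement is safe.

## Relationship matrices

`build_A()` implements the tabular method; `build_A_inverse()` implements
Henderson's rules with Meuwissen-Luo inbreeding coefficients, validated
against dense inversion on pedigrees up to 500 animals.
`sire_mgs_matrix()` extracts the relationship block among a set of
stallions from the *full* pedigree via the $A = TDT'$ decomposition and
sparse triangular solves — never from a males-only pedigree.
`build_G()` is VanRaden method 1 with observed allele frequencies,
$G = MM'/(2\sum_k p_k(1-p_k))$. The single-step inverse is
$$H^{-1} = A^{-1} + \begin{pmatrix}0 & 0\\ 0 & G_w^{-1} - A_{22}^{-1}\end{pmatrix},$$
with $G_w = 0.95\,G^* + 0.05\,A_{22}$ after tuning $G$'s mean diagonal and
mean off-diagonal to the pedigree block — standard practice that guarantees
invertibility and puts the two information sources on the same scale.
Because the centring of $M$ makes the all-ones vector an exact null
direction of $G$, back-solution solves are regularised by a relative ridge
of $10^{-10}$; breeding values live in the row space, so the effect on the
solution is nil at double precision.

SNP quality control applies, in a fixed canonical order: unknown location,
sex chromosomes, duplicated (chromosome, position), MAF $< 0.05$,
Hardy-Weinberg disequilibrium ($\chi^2$, 1 df, $P < 10^{-6}$), call rate
$< 0.90$, and cross-chip MAF consistency (pairwise allele-count $\chi^2$,
flag at $P < 10^{-5}$ — the threshold is published, the statistic is this
package's choice and is labelled as such in the report). The `qc_report`
machinery enforces count conservation at every step and can replay a
published cascade from removal counts alone.

## The bivariate model

One gait principal component (individual level, up to two recordings per
horse) is joined with the longevity pseudo-phenotypes (sire level) by

$$y = X\beta + Zu + Wp + \epsilon, \qquad y^* = u^* + \epsilon^*,$$

with $\mathrm{Var}[u, u^*] = G_{2\times2} \otimes H$,
$\mathrm{Var}(\epsilon) = I\sigma_\epsilon^2$,
$\mathrm{Var}(\epsilon^*) = \mathrm{diag}(\sigma_{\epsilon^*}^2/w_i)$.
No animal has both kinds of records (longevity is sire-level by
construction), so the genetic covariance is identified purely through the
relationship matrix. The longevity components are fixed at their
survival-analysis values; the gait genetic, permanent-environment and
residual variances and the genetic covariance are free.

The implementation absorbs the permanent-environment effect into per-horse
compound-symmetry residual blocks (closed-form inverses and determinants),
evaluates the restricted log-likelihood exactly as
$-2\ell_R = \log|R| + \log|G_{2\times2}\otimes H| + \log|C| + y'Py$
from one supernodal sparse Cholesky factorisation of the mixed-model
equations per evaluation, and maximises it by quasi-Newton iterations on
transformed coordinates (log-variances, atanh of the genetic correlation,
so the parameter set stays inside the PSD cone by construction). Standard
errors come from the observed information — the numerical Hessian of the
restricted likelihood on the original coordinates — with delta-method SEs
for $h^2$, repeatability and $r_g$. This direct-maximisation design was
preferred over average-information updates because the exact likelihood is
cheap here (one sparse factorisation, reused symbolic analysis) while AI
first derivatives need trace terms that require selected sparse inversion;
at the optimum the observed information and the AI matrix estimate the
same asymptotic covariance. Convergence tolerance is a relative
log-likelihood change below $10^{-8}$ within 200 iterations; starting
values assign half the phenotypic variance to genetics and split the rest
equally.

Non-convergence is a first-class outcome. The fit is declared
non-converged when the optimiser fails, when the observed information is
singular or indefinite (reciprocal condition below $10^{-10}$), or when
the genetic variance collapses to the boundary (below $10^{-5}$ of the
phenotypic variance), where the genetic correlation is undefined. At a
simulated heritability of 0.04 with the study's family structure (about
1,500 horses from 486 sires), this is exactly what happens in most
replicates — reproducing the study's experience with its low-heritability
walk component — and when the optimiser does settle, the reported $r_g$
standard error is large enough to expose the non-identifiability. The
tests assert both halves: the declared-failure path triggers, and no
replicate fails silently.

Because longevity genetic values are on the culling-risk scale, a
*negative* genetic correlation means the gait trait favours longevity. The
derived-parameter table carries this interpretation flag so that reporting
layers can flip the sign for presentation without touching the estimates.

## The GWAS

The GWAS back-solves SNP effects from the genomic breeding values of a
weighted single-trait GBLUP of the pseudo-phenotypes:
$\hat a = M'G^{-1}\hat u_g / (2\sum_k p_k(1-p_k))$, with sampling variances
from the prediction-error covariance,
$\mathrm{Var}(\hat a_k) = m_k'G^{-1}(\sigma_u^2 G - C)G^{-1}m_k / (2\sum p(1-p))^2$
and two-sided normal p-values. The prediction-error covariance comes from
direct inversion of the coefficient matrix — exactness over scalability,
appropriate at the panel sizes this package targets. Under a polygenic
null the p-values are uniform (Kolmogorov-Smirnov checked in the tests);
a planted QTL rises to the top of the table; and the significance report
annotates each hit's MAF, since hits near the QC threshold deserve
scrutiny.

## What the simulators emulate

The generators are first-class, tested code, and their defaults are the
study's conditions: sire variance 0.03947 on the log-hazard scale; a ~0.8
per-year baseline survival with staggered cohort entry over 17 years and
censoring at the final data year, which yields roughly 22% censored
careers; gait traits with two recordings per horse, heritabilities and
repeatabilities in the published 0.11-0.44 and 0.45-0.74 ranges; and
genetic correlations imposed through a 2x2 genetic covariance transmitted
down the pedigree (parent average plus Mendelian sampling, inbreeding
adjusted). Genotypes are gene-dropped from founder frequencies drawn
uniformly on the configured MAF range, so the realised genomic
relationship tracks pedigree expectation entrywise at the $4/\sqrt{m}$
Monte-Carlo rate. Each generator draws from its own RNG stream derived
from the master seed and a stream name, so adding one simulator never
perturbs another's output.

Truth has two coherent routes. The default transmits breeding values down
the pedigree, which matches analyses that use pedigree relationships. When
the analysis includes a genomic or single-step relationship matrix, the
truth must instead be marker-based
(`simulate_breeding_values_from_markers()`): every simulated SNP receives
a true bivariate effect and breeding values are sums of marker effects, so
the realised $G$ describes them exactly. Mixing the two — pedigree-drawn
breeding values analysed with realised marker relationships — is a model
mis-specification that measurably attenuates the estimated genetic
variance and inflates the genetic correlation, which is why the
genomic recovery experiments use the marker route.

What the simulators do *not* model: linkage disequilibrium, selection
during the breeding program, genotyping error, chip-specific missingness,
and any biomechanical structure among the eight accelerometric variables
beyond a generic low-rank factor model. Passing recovery tests therefore
demonstrates that the estimation stages are correct under the assumed
models at the study's parameter values — not that those models capture
every feature of real accelerometer or federation data.

## Problem sizes of the reproduction experiments

The recovery experiments in `scripts/acceptance.R` use: 20 replicates of
1,000 sires x 30 progeny for the sire-variance recovery; twenty replicates of
1,500 gait horses (300 half-sib families of 5) and 2,000 pseudo-phenotyped
sires with a 5,000-SNP panel on 450 animals for each genetic-correlation
recovery, with replicate estimates averaged; and twelve replicates of 2,000
horses with two records each (200 half-sib families) for the
heritability/repeatability recovery. These sizes mirror the study's data
structure where it is printed (families of 3-5 progeny, reliabilities
spread 0.40-0.97 with mean ~0.63) and keep each experiment's Monte-Carlo
error comfortably inside the published standard errors (0.13-0.15 for the
genetic correlations, 0.06 and 0.01 for trot-PC1 heritability and
repeatability). The correlation experiments use marker-based truth (see
above) with a 5,000-marker panel, large enough that the finite-panel
noise in $G$ is negligible next to the family information. The
heritability experiment is pedigree-only with pedigree-transmitted truth,
the matching coherent pair.

## Known limitations

- The prediction-error covariance in the GWAS and the reliability
  computations invert dense matrices; both are desk-scale by design.
- The Laplace-approximate marginal posterior of the sire variance carries
  a small (about -2%) finite-sample bias at 30 progeny per sire, well
  inside the recovery tolerances; a fully Bayesian treatment would remove
  it at considerable cost.
- The Harris-Johnson-style pruning implements parent-average information
  subtraction only; explicit grand-progeny bookkeeping is not needed
  because progeny information is retained, and the BLUP/reliability
  round-trip properties are the acceptance surface for this choice.
- `estimate_horse_effects()` delegates the per-variable mixed models to
  lme4; the PCA uses the base eigendecomposition of the correlation
  matrix. Both are standard steps behind a thin, tested surface.
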