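---
title: "Models and methods: disentangling stunting, socioeconomic status and the gut microbiota in child neurodevelopment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stuntsem)
```

## The scientific problem

Chronic childhood undernutrition (stunting, height-for-age Z-score HAZ at
or below -2) is consistently associated with poorer neurodevelopmental
outcomes, but the association is entangled with socioeconomic conditions,
anemia, amino-acid status, enteric dysfunction and the composition of the
gut microbiota. Ordinary regression can quantify conditional associations
but cannot separate a *direct* effect of, say, socioeconomic status (SES)
on development from an *indirect* one operating through growth or through
the microbiome. Structural equation models (SEMs) can: they posit a
directed system of equations among observed and latent variables, derive
the covariance matrix this system implies, and judge the system by how
closely the implied covariance matches the sample covariance.

`stuntsem` implements that workflow end to end: derived clinical scores,
microbiome data reduction, mixed-type association screening that decides
which variable blocks may form latent constructs, a self-contained
covariance-structure engine, four pre-specified model topologies, and a
synthetic cohort generator with stored ground truth so that every stage is
testable without access-controlled cohort data.

## The covariance-structure engine

A model is written in RAM form over the joint vector of observed and
latent variables: a matrix $A$ of directed-edge coefficients (factor
loadings and structural paths), a symmetric $\Omega$ holding exogenous
(co)variances and residual variances, and a selector $F$ picking out the
observed rows. The implied covariance is

$$\Sigma(\theta) = F\,(I-A)^{-1}\,\Omega\,(I-A)^{-\top}F^{\top}.$$

Estimation minimizes the normal-theory maximum-likelihood discrepancy

$$F_{ML}(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}\!\left(S\Sigma(\theta)^{-1}\right) - \log|S| - p,$$

with $S$ the sample covariance on the listwise-complete rows (denominator
$n-1$) and $p$ the number of observed variables. $F_{ML}\ge 0$ with
equality iff $\Sigma = S$.

Numerical choices that matter:

* **Scaling.** Each latent variable has one loading fixed to 1 (its scale
  indicator). Internally the optimizer works on the unit-variance scale of
  the observed variables: $F_{ML}$ is invariant under per-variable
  rescaling, and every parameter maps back exactly through known scale
  factors, so convergence does not depend on whether a variable is a
  Z-score or a concentration in hundreds of µmol/L.
* **Optimization.** Deterministic starts (free loadings 1, paths 0,
  variances half the observed variance, covariances 0), BFGS with
  *analytic* gradients of $F_{ML}$ derived from the RAM form, with a PORT
  (`nlminb`) polish pass if the gradient infinity-norm has not reached
  `1e-6`. No randomness enters estimation.
* **Standard errors.** $\widehat{\mathrm{cov}}(\hat\theta) =
  \frac{2}{n-1}H^{-1}$ with $H$ the numerical Hessian of $F_{ML}$ at the
  optimum, computed on the well-conditioned standardized scale and mapped
  back.
* **Chi-square convention.** $\chi^2 = (n-1)\,F_{ML,\min}$ (Wishart
  convention, consistent with the $n-1$ denominator in $S$), used
  identically inside RMSEA. Conventions differ across software; this one
  is stated explicitly and used consistently.
* **Missing data.** Listwise deletion, with the retained $n$ reported per
  model. Full-information ML is out of scope.
* **Heywood cases.** Negative residual-variance estimates are not
  constrained away; they are flagged in the fit object, mirroring common
  practice, because silently bounding them hides misspecification.
* **Degenerate inputs.** A non-positive-definite sample covariance, a
  cyclic structural graph, duplicate edges, or fewer complete rows than
  free parameters are hard errors, not warnings.

Fit statistics follow the standard definitions: the baseline
(independence) model has the closed form $F_B = \sum_i \log s_{ii} -
\log|S|$; CFI $= 1 - \max(\chi^2_M-df_M,0)/\max(\chi^2_M-df_M,
\chi^2_B-df_B, 0)$; TLI from the ratio of per-df chi-squares; RMSEA
$=\sqrt{\max(\chi^2_M-df_M,0)/(df_M(n-1))}$; SRMR averages squared
residuals of the correlation-standardized covariances **including the
diagonal** (variants excluding it exist; the choice is stated because it
changes the value).

Effects are decomposed from the coefficient matrix: total effects are
$(I-A)^{-1}-I$, the direct effect is the $A$ entry, and the indirect
effect is their difference, so additivity is exact by construction.
Standard errors for all three use the delta method with the estimated
parameter covariance. Standardized estimates rescale every coefficient by
model-implied standard deviations of *all* variables (latent included), so
they are bounded by 1 in admissible solutions.

## The four model topologies

`build_model_catalog()` instantiates four structural topologies, each
crossed with one of four microbiota constructs:

1. **simplest** — direct effects only: SES (latent), HAZ and the
   microbiome each point at the neurodevelopment latent; the three sources
   covary freely.
2. **simple** — adds the mediated routes SES → HAZ, SES → microbiome and
   microbiome → HAZ. The microbiome → HAZ edge is required for the
   HAZ-mediated indirect effect of the microbiota on neurodevelopment to
   be estimable at all.
3. **complex** — adds hemoglobin → HAZ, a BCAA latent (alanine,
   citrulline, valine, leucine, isoleucine) with BCAA → HAZ and BCAA →
   microbiome, and fecal alpha-1-antitrypsin class, age and reported birth
   size as direct covariates of neurodevelopment. There is deliberately no
   direct BCAA → neurodevelopment or hemoglobin → neurodevelopment edge:
   their influence is modelled as mediated through growth.
4. **complex_path** — the complex topology with every latent replaced by
   an observed proxy: household rooms and maternal age at first pregnancy
   for SES, leucine for BCAA, and the overall developmental score (the sum
   of the five domains) for the neurodevelopment latent.

The neurodevelopment latent loads on the five ASQ-3 domains
(communication, problem-solving, personal-social, fine motor, gross
motor); the SES latent on socioeconomic score category, maternal
education, maternal age at first pregnancy, treated drinking water and
rooms. Reported birth size enters as numeric 1/2/3
(smaller/same/bigger) and AAT as a normal/elevated binary — single
coefficients rather than dummy sets, keeping the parameter count workable
at cohort-scale $n$. Exogenous variables covary freely (the standard SEM
convention); hand-verified degrees of freedom for the four topologies (50,
50, 168, 9 with the Shannon construct) are frozen in the test suite.

## Microbiota data reduction

Four per-sample constructs stand in for the high-dimensional count table:

* **Shannon diversity** (nats, unrarefied counts; inverse Simpson and
  richness are also computed), via `vegan`.
* **Streptococcaceae relative abundance**, family-aggregated — a family
  repeatedly linked to stunting.
* **Cluster membership** from Ward.D2 hierarchical clustering of
  Euclidean distances on relative abundances, cut at $k=2$.
* **PCoA axis 1** of the Euclidean-distance ordination (classical scaling:
  double-center $-\tfrac12 D^2$, eigendecompose, keep positive
  eigenvalues; axis signs fixed so the largest-magnitude coordinate is
  positive, making output deterministic).

The number of clusters is chosen by an automated surrogate for the visual
elbow on the Calinski-Harabasz curve: with $CH(1)\equiv 0$ (the
between-cluster sum of squares vanishes at one cluster), the chosen $k$
maximizes the discrete curvature $[CH(k)-CH(k-1)] - [CH(k+1)-CH(k)]$ over
candidates $k=2..10$, ties to the smaller $k$. On clearly two-cluster data
this selects $k=2$; the rule is configurable because any automated elbow
is a judgement call.

Taxon screening correlates family- or genus-level *relative abundances*
(not CLR; a CLR route exists behind `clr_transform()`) with each
developmental score using Pearson's r, adjusting within each score across
taxa by Benjamini-Hochberg. Zero-variance taxa are reported as missing and
excluded from the BH family size. Samples with zero family abundance are
retained. The CLR pseudocount defaults to +1 on counts. Quartile
contrasts (first vs last quartile of a score, middle half dropped) use
linear-interpolation (type 7) quantiles. Bray-Curtis distances are bounded
in [0,1] on compositions but do not satisfy the triangle inequality — they
are used for ordination only, never for algorithms that assume metricity.

## Association screening and eligibility for latent constructs

Pairwise association within a candidate variable block uses Spearman's r
for continuous pairs, bias-uncorrected Cramér's V for categorical pairs,
and $\sqrt{R^2}$ of a one-way ANOVA for mixed pairs, so every value lies
in [0,1] (Spearman in [-1,1]). A block may form a latent construct iff it
has at least 4 indicators (needed for an identified, testable measurement
model) **and** its median absolute off-diagonal association reaches 0.2.
The 0.2 figure is the screening cut-off; the *median* aggregation is this
package's explicit operationalization of what is otherwise a visual
judgement on a correlation plot, and both are configurable.

Regression contrasts (e.g. adjusted mean differences in developmental
score between stunting categories, reference `normal`) run through an
in-package OLS with classical standard errors, t-based 95% CIs, the
Breusch-Pagan statistic $nR^2_{aux}$ for homoskedasticity, and numeric
influence summaries (max |standardized residual|, max Cook's distance)
instead of diagnostic plots.

## What the synthetic cohort emulates — and what it does not

The generator draws standard-normal latent SES and BCAA factors, a
hemoglobin deviate, and a latent microbiota "diversity driver"; HAZ is a
linear combination of SES, hemoglobin and BCAA (intercept -1.7, residual
SD 1.1, giving a stunting mix near the oversampled case-control
composition of the motivating design); the neurodevelopment latent
combines SES, HAZ and the driver; and every indicator is loading × latent
+ noise, discretized to its declared scale (ASQ-3 domains on the 0-60
grid in steps of 5, ordinal SES categories, integer rooms and ages).
Default sizes are a cohort of 349 children, 1626 taxa in 25 family blocks
and a mean library size of 22039 reads. Default structural coefficients
are moderate (SES → neuro 0.35, HAZ → neuro 0.30, diversity → neuro 0.10,
BCAA → diversity -0.30) — plausible effect sizes for this literature,
with microbiome-to-growth coupling zero by default.

Count tables are Dirichlet-multinomial: a geometric family-level base
composition (decay 0.7) with geometric within-family taxon weights (decay
0.9), whose log-concentration profile is flattened or sharpened by the
child's diversity driver (tilt 0.6), at Poisson library sizes. ASQ-3 item
mechanics are not modelled — domain scores are generated directly on
their printed scale, because the analysis only ever consumes domain
scores. Two HAZ modes exist: the default continuous-linear mode above,
and direct category sampling for tests that need exact category
proportions. Missingness is MCAR-only and off by default, present solely
to exercise the listwise-deletion policy.

What passing tests on this cohort do **not** show: the generator is
multivariate-normal-with-discretization; real cohort data have floor
effects, informative missingness, matched case-control sampling
(age/sex/neighborhood/season), batch structure beyond a binary run label,
and taxa dynamics far richer than a tilted Dirichlet. Parameter-recovery
results therefore validate the *estimator and pipeline*, not the
substantive conclusions one would draw from real data.

## Problem sizes and reproducibility

Simulation studies shipped with the package use sizes chosen to make
Monte-Carlo error small relative to the tolerances tested: parameter
recovery at $n=2000$ over 100 seeds per topology, mediation chains at
$n=5000$ over 200 replicates, Breusch-Pagan size over 1000 replicates at
$n=200$, and null-microbiome calibration over 100 seeds at $n=400$.
Every stochastic step is seed-determined; `scripts/acceptance.R` re-runs
the whole battery from a single `--seed`.

## Known limitations

Only normal-theory ML is implemented (no robust/WLS estimators, no
polychoric treatment of ordinal indicators, no multiple-group models, no
FIML for missingness). Ordinal and binary indicators are treated as
numeric, as is common in applied SEM at these scales, which attenuates
loadings relative to a latent-response formulation. Differential-abundance
model fitting (beyond the quartile-contrast utility that feeds it) and
phylogenetic distances are out of scope. The elbow rule and the median
aggregation of block associations are reproducible surrogates for visual
judgements and should be treated as such.
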