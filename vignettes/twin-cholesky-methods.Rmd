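---
title: "Liability-threshold Cholesky twin models with polygenic scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold Cholesky twin models with polygenic scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
```

## The model

`twinpath` fits the classical twin design (CTD) to mixed
continuous/binary phenotypes measured on MZ and DZ twin pairs. For p
variables, each variance component X in {A, C, E} carries a
lower-triangular path matrix L_X; the within-member covariance is
L_A L_A' + L_C L_C' + L_E L_E' and the cross-twin covariance is
rA_z L_A L_A' + L_C L_C', with the factor sharing fixed by the design:
additive-genetic factors correlate rA = 1 across MZ members and 0.5
across DZ members (MZ pairs are genetically identical, DZ pairs share
half their segregating genes on average), shared-environment factors
correlate 1 in both zygosities under the equal-environments assumption,
and unique-environment factors (which absorb measurement error) are
uncorrelated. The CTD further assumes random mating and no
gene-environment interaction or correlation; dominance is not modelled,
because C and D cannot be estimated simultaneously from twin pairs
alone and C is retained.

Binary phenotypes follow the liability-threshold model: the observed
response is the indicator that a standard-normal latent liability
exceeds a threshold τ. This fixes the liability scale, so each binary
variable's model-implied total variance must equal 1. Rather than a
penalty or an explicit nonlinear constraint, the package enforces this
exactly by reparameterization: the diagonal path of the variable's E
row (or of the surviving component in CE/E submodels) is computed as
sqrt(1 − s), where s is the sum of the variable's other squared paths;
parameter vectors with s > 1 − 1e−6 are treated as outside the valid
region. This keeps the constraint exact for every optimizer iterate at
no cost in degrees of freedom.

Polygenic scores enter as ordinary model variables whose variance is
entirely additive-genetic (components = "A"): their single free path is
the score's own loading, and their cross-loadings on downstream
variables estimate the genetic covariance between the score and each
phenotype. Because such a score has no E component, MZ co-twins'
model-implied scores are perfectly correlated; the observed MZ score
block is singular, and the FIML evaluator therefore uses the
degenerate-Gaussian density on the support (eigendecomposition of the
continuous block, density over positive-eigenvalue directions, with the
null-direction residual required to vanish). This is exact, not an
approximation, whenever the data satisfy the model's support — which MZ
pairs' identical scores do by construction.

Covariates are handled as definition variables: per-person values shift
the expected liability mean while thresholds are held fixed, which is
algebraically identical to shifting the person's threshold. The default
attachments are sex on the diagnosis threshold and age on the planning
and attempt thresholds.

## FIML over families

Each family contributes the likelihood of exactly its observed data.
Continuous observed coordinates contribute their (possibly degenerate)
multivariate-normal density; binary observed coordinates contribute the
rectangle probability of the response pattern under the conditional
Gaussian given the continuous observations; missing coordinates are
marginalized by deletion. A fully unphenotyped family contributes
exactly zero.

Because a binary response pattern bounds each coordinate on one side
only, the rectangle is an orthant; flipping affected coordinates turns
it into a single lower-CDF evaluation. The evaluator is deterministic
throughout (no quasi-Monte-Carlo noise), so the objective is smooth for
quasi-Newton optimization: dimension 1 uses `pnorm`, dimension 2 a
vectorized Drezner-Wesolowsky Gauss-Legendre quadrature (32 nodes,
machine-precision agreement with `mnormt::biv.nt.prob`, which it falls
back to for |ρ| ≥ 0.925), dimension 3 `mnormt::ptriv.nt`, and
dimensions 4-8 `mnormt::sadmvn` (adaptive deterministic integration,
absolute tolerance 1e−5 inside the optimizer — which perturbs fitted
paths by well under 1e−3, far below their sampling error — and 1e−8 in
the exported `mvn_rectangle_probability`). Dimensions above 8 are
rejected.
Probabilities are floored at 1e−300 with a warning so that optimizer
excursions cannot produce an infinite objective.

For speed, families are compiled once per model into observation
groups: families identical in zygosity, observed pattern, binary
responses, continuous values, and model-relevant covariate values
collapse into one weighted group, and groups sharing a pattern
structure share the per-iteration linear algebra. All-binary cohorts
without continuous covariates therefore evaluate in a handful of
orthant probabilities regardless of sample size, which is what makes
the replicate-heavy calibration checks (coverage, selection
consistency) feasible.

## Optimization, selection, intervals

`fit_cholesky` runs `nlminb` from a data-driven start (thresholds at
qnorm of one minus the observed prevalence, diagonals splitting unit
variance equally, off-diagonals at 0.1) plus `restarts − 1` perturbed
starts (SD 0.2 on the path scale), keeping the best optimum; diagonal
paths are bounded at zero for sign identifiability and solutions at a
box bound are flagged "boundary". No attempt is made to mimic any
particular SEM engine's optimizer — only the estimator it maximizes.

Nested ladders (ACE → AE, CE, E) are compared by Δ−2LL referred to
χ² with df equal to the parameter-count difference, and by AIC.
`select_model` keeps, among models whose χ² change versus the full
model is non-significant at α = 0.05, the one with lowest AIC, ties
going to fewer parameters; reduced models are warm-started from the
full solution. The asymptotic χ² reference is used as-is even when a
component sits on its boundary (no chi-bar-squared mixture correction);
this matches common twin-modelling practice and is recorded as a known
caveat. Dropping every genetic path of a trivariate score/diagnosis/
item model except the score's own loading removes five free parameters
(the two score cross-loadings and the 2×2 genetic triangle of the
other variables), hence a 5-df test.

Profile-likelihood intervals locate the points where the profiled −2LL
rises by the χ²(1) quantile (3.841 at 95%), by bracketed bisection
with warm-started refits; free parameters are profiled by fixing them,
derived quantities (standardized proportions, component correlations)
by a quadratic-penalty constrained refit (λ = 1e6, which distorts the
located bound by far less than the 5e−4 bisection tolerance). Profiles
reaching a natural boundary (0 or 1 for proportions) report the
boundary value flagged one-sided. The bootstrap resamples families
with replacement within zygosity strata — the family is the
exchangeable unit and stratification preserves the MZ/DZ design —
refits from the full-data solution, and reports percentile intervals
(type-1 quantiles, so a 2-replicate smoke run yields min/max); failed
replicates are dropped, counted, and flagged above 20%.

Both interval methods are provided because published twin analyses
often do not state which construction their 95% CIs use.

## The synthetic-cohort generator

No cohort of this kind is redistributable, so `twinsim` generates one
with the statistical structure the analysis assumes. Latent factor
scores follow the CTD construction (DZ additive factors are
sqrt(0.5)·pair-common + sqrt(0.5)·member-unique standard normals; in
locus mode the additive factor of a pure-A score variable is replaced
by a standardized, effect-weighted allele sum from simulated parental
genotypes and independent meiosis, so the DZ sharing of 0.5 arises
mechanistically rather than by construction and can be checked against
exhaustive enumeration of transmissions at a single locus). Observed
liabilities add covariate effects linearly (no interactions); binary
variables threshold the liability; item gating then blanks dependent
items for members not endorsing the screen; incomplete pairs blank one
member's phenotypes while keeping the family row, mirroring FIML's use
of incomplete pairs. A truth sidecar records every family's latent
component values for parameter-recovery and sharing checks; it is never
written into the analysis-facing table.

The default cohort (`default_cohort_config`) fixes the study conditions:
530 MZ and 720 DZ pairs with 28% incomplete pairs (≈900 complete
diagnosis pairs), ages uniform over 19-39 whole years shared within a
pair, sex Bernoulli(0.67 female) with MZ pairs same-sex, per-member
score missingness of 15%/10%, and an AE generating truth with
standardized additive components of 0.40 (diagnosis), 0.52 (ideation),
0.60 (plan), 0.80 (attempt), genetic correlations of 0.65/0.48/0.52
between the diagnosis and the three items, 0.85-0.97 among the items,
and 0.14-0.25 between the scores and the phenotypes. Two generating
quantities have no external anchor and were chosen once: the
score-score genetic correlation (0.10) and the attempt item's unique-
environment correlation with the diagnosis (−0.20, moderately
negative). Thresholds are a calibration, not free
choices: τ = (1.164, 0.755, 0.612, 0.957) for diagnosis/ideation/plan/
attempt were solved numerically (iterated normal-quantile updates on a
120,000-member simulation) so that the diagnosis prevalence is 18% and
the items' endorsement rates among diagnosed members are 38%, 14% and
6.5% — the midpoints of the ranges the generator targets — after
accounting for the covariate mean shifts (sex +0.35 on the diagnosis;
age −0.03/year on plan and attempt, i.e. odds of planning or attempt
roughly halving per decade of age in young adulthood).

One structural simplification: gating is keyed on the diagnosis
variable itself, whereas real assessments typically screen on a
broader item than the full diagnosis. Consequently the default cohort
yields fewer complete item pairs (~50) than a screen-based design of
the same size would (~150); the rare-item uncertainty checks therefore
construct their item-scale cohorts directly at the intended informative
sample sizes.

What passing simulation checks does and does not show: the generator
satisfies the CTD's assumptions exactly (no assortative mating, no
gene-environment interplay, no linkage disequilibrium, MCAR
missingness beyond gating), so recovery and coverage results validate
the estimator under the model, not robustness of the model to real
cohorts' violations of it.

## Numerical choices and problem sizes

Tolerances: optimizer `rel.tol` defaults (1e−10, nlminb), valid-region
floor 1e−6 on the derived-diagonal radicand, rectangle floor 1e−300,
profile bisection tolerance 5e−4, LRT negative-Δ tolerance 1e−4 (a
negative change triggers a warm-started refit of the reduced model and
errors only if it persists). Ties in AIC selection break toward fewer
parameters after rounding at 1e−8.

The replicate-based checks run at sizes chosen to make their Monte
Carlo error small relative to the tolerance being asserted: sharing
constants at 20,000-50,000 pairs (3 binomial/Monte-Carlo SEs), bias
over the heritability-by-prevalence grid at 2,000 pairs per zygosity
with 12 replicates per cell, profile coverage at 500 replicates of 250
pairs per zygosity, selection consistency at 100 replicates of 800
pairs per zygosity, and the end-to-end pipeline smoke at 90-140
families with capped optimizer iterations. The acceptance script uses
the full stated sizes throughout.

## Known limitations

No sex-limitation models (sexes are pooled with a mean adjustment
only); no dominance; no families beyond two members (non-twin siblings
are outside the pair record); no chi-bar-squared boundary corrections;
no analytic gradients; binary patterns above dimension 8 (more than
four binary variables on a complete pair) are unsupported; the
two-step polyserial/tetrachoric estimators in the descriptive
correlation matrix trade a small efficiency loss for speed relative to
joint one-step ML.
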