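#' Default generating model for the synthetic twin cohort
#'
#' An AE Cholesky truth over six variables — two polygenic scores
#' (continuous, pure additive-genetic), a depression diagnosis and three
#' conditionally assessed suicidal-behavior items (ideation, plan,
#' attempt; all binary on the liability scale) — with standardized
#' additive-genetic proportions, genetic and unique-environment
#' correlations, covariate effects (sex on the diagnosis threshold,
#' age on the plan and attempt thresholds) and thresholds calibrated so
#' the diagnosis prevalence is about 18% and the items' endorsement rates
#' among diagnosed members fall in realistic conditional ranges (ideation
#' about 38%, plan about 14%, attempt about 7%).
#'
#' @return A \code{\link{cholesky_model}} with generating values set.
#' @export
default_generating_model <- function() {
  vars <- list(
    variable_spec("prs_md", "continuous", components = "A"),
    variable_spec("prs_sb", "continuous", components = "A"),
    variable_spec("mdd", "binary_liability", covariates = "sex"),
    variable_spec("si", "binary_liability"),
    variable_spec("sp", "binary_liability", covariates = "age"),
    variable_spec("sa", "binary_liability", covariates = "age"))
  nm <- c("prs_md", "prs_sb", "mdd", "si", "sp", "sa")
  pr <- cbind(A = c(1, 1, 0.40, 0.52, 0.60, 0.80),
              C = rep(0, 6),
              E = c(0, 0, 0.60, 0.48, 0.40, 0.20))
  rownames(pr) <- nm
  rA <- matrix(c(
    1.00, 0.10, 0.25, 0.18, 0.22, 0.14,
    0.10, 1.00, 0.12, 0.20, 0.16, 0.14,
    0.25, 0.12, 1.00, 0.65, 0.48, 0.52,
    0.18, 0.20, 0.65, 1.00, 0.91, 0.85,
    0.22, 0.16, 0.48, 0.91, 1.00, 0.97,
    0.14, 0.14, 0.52, 0.85, 0.97, 1.00), 6, 6,
    dimnames = list(nm, nm))
  rE <- matrix(c(
    1.00, 0.00, 0.00, 0.00, 0.00, 0.00,
    0.00, 1.00, 0.00, 0.00, 0.00, 0.00,
    0.00, 0.00, 1.00, 0.06, 0.12, -0.20,
    0.00, 0.00, 0.06, 1.00, 0.75, 0.64,
    0.00, 0.00, 0.12, 0.75, 1.00, 0.64,
    0.00, 0.00, -0.20, 0.64, 0.64, 1.00), 6, 6,
    dimnames = list(nm, nm))
  m <- cholesky_from_components(vars, pr, corr = list(A = rA, E = rE),
                                components = c("A", "E"))
  th <- model_get_params(m)
  # thresholds on the covariate-shifted liability scale (see the methods
  # vignette for the calibration)
  th["tau_mdd"] <- 1.164
  th["tau_si"] <- 0.755
  th["tau_sp"] <- 0.612
  th["tau_sa"] <- 0.957
  th["b_mdd_sex"] <- 0.35
  th["b_sp_age"] <- -0.03
  th["b_sa_age"] <- -0.03
  th["mu_prs_md"] <- 0
  th["mu_prs_sb"] <- 0
  model_set_params(m, th)
}

#' Default synthetic-cohort configuration
#'
#' Simulation settings emulating a young-adult twin cohort in which a
#' depression diagnosis is assessed on most pairs and suicidal-behavior
#' items only conditionally on the diagnosis screen: 530 MZ and 720 DZ
#' pairs, 28% incomplete pairs, per-member polygenic-score missingness of
#' 15% / 10%, sex Bernoulli(0.67 female; MZ pairs same-sex), ages uniform
#' over 19-39 whole years, and gating of the ideation/plan/attempt items
#' on the diagnosis.
#'
#' @param seed Integer seed (mandatory).
#' @param n_mz_pairs,n_dz_pairs Pair counts.
#' @param ... Further overrides passed to \code{\link{sim_config}}.
#' @return A \code{\link{sim_config}}.
#' @export
default_cohort_config <- function(seed, n_mz_pairs = 530, n_dz_pairs = 720, ...) {
  args <- utils::modifyList(
    list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
         model = default_generating_model(), seed = seed,
         gating = list(screen = "mdd", dependents = c("si", "sp", "sa")),
         singleton_fraction = 0.28,
         prs_missing = c(prs_md = 0.15, prs_sb = 0.10),
         sex_prob = 0.67, age_range = c(19, 39)),
    list(...))
  do.call(sim_config, args)
}
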