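test_that("null cross-paths are recovered near zero on null-generated data", {
  truth <- bivariate_ae(h2 = c(0.5, 0.5), rA = 0, rE = 0,
                        tau = c(0.8, 0.8), names = c("v1", "v2"))
  ds <- sim_ds(truth, 1500, 1500, seed = 501)
  mod <- cholesky_model(list(spec_binary("v1"), spec_binary("v2")),
                        components = c("A", "E"))
  f <- fit_cholesky(mod, ds, restarts = 3, seed = 1)
  expect_equal(f$convergence, "converged")
  # cross paths small (joint liability correlations ~ 1/sqrt(n pairs))
  est <- coef(f)
  expect_lt(abs(est[["a21"]]), 0.12)
  expect_lt(abs(est[["e21"]]), 0.12)
  expect_equal(f$aic, f$m2ll + 2 * f$n_free_params)
})

test_that("standardized A of a binary AE trait is recovered at scale", {
  truth <- univariate_ae(h2 = 0.4, tau = qnorm(1 - 0.18))
  ds <- sim_ds(truth, 2000, 2000, seed = 502)
  f <- fit_cholesky(cholesky_model(list(spec_binary("mdd")),
                                   components = c("A", "E")),
                    ds, restarts = 3, seed = 2)
  expect_lt(abs(f$summary$proportions["mdd", "A"] - 0.4), 0.05)
})

test_that("the trivariate score/diagnosis/item fit recovers the generating loading", {
  cfg <- default_cohort_config(seed = 503, n_mz_pairs = 260, n_dz_pairs = 340)
  ds <- simulate_ace_cohort(cfg)$dataset
  mod <- cholesky_model(ds$variables[c("prs_md", "mdd", "si")],
                        components = c("A", "E"))
  f <- fit_cholesky(mod, ds, restarts = 1, seed = 3,
                    control = list(rel.tol = 1e-7))
  expect_true(f$convergence %in% c("converged", "boundary"))
  # the score loading (its SD) is tightly estimable: truth 1
  expect_lt(abs(coef(f)[["a11"]] - 1), 3 * 1 / sqrt(2 * 600))
  # the score is assigned pure additive variance
  expect_equal(unname(f$summary$proportions["prs_md", ]), c(1, 0, 0),
               tolerance = 1e-8)
})

test_that("mean bias of standardized A is small across the generating grid", {
  grid <- expand.grid(h2 = c(0.2, 0.5, 0.8), prev = c(0.05, 0.2))
  mod <- cholesky_model(list(spec_binary("v")), components = c("A", "E"))
  for (g in seq_len(nrow(grid))) {
    truth <- univariate_ae(h2 = grid$h2[g],
                           tau = qnorm(1 - grid$prev[g]), name = "v")
    est <- vapply(1:12, function(r) {
      ds <- sim_ds(truth, 2000, 2000, seed = 5100 + 20 * g + r)
      f <- fit_cholesky(mod, ds, restarts = 1, seed = r)
      f$summary$proportions["v", "A"]
    }, 0)
    expect_lt(abs(mean(est) - grid$h2[g]), 0.03)
  }
})

test_that("likelihood-ratio bookkeeping: self-comparison and the 5-df genetic-path test", {
  cfg <- default_cohort_config(seed = 504, n_mz_pairs = 80, n_dz_pairs = 100)
  ds <- simulate_ace_cohort(cfg)$dataset
  full <- cholesky_model(ds$variables[c("prs_md", "mdd", "sa")],
                         components = c("A", "E"))
  fa <- fit_cholesky(full, ds, restarts = 1, seed = 4,
                     control = list(rel.tol = 1e-6, iter.max = 60))
  row0 <- likelihood_ratio_test(fa, fa)
  expect_equal(row0$delta_m2ll, 0)
  expect_equal(row0$p, 1)

  # dropping every genetic path except the score's own loading: 5 df
  reduced <- model_ladder(full)$E
  expect_equal(length(model_param_names(full)) -
                 length(model_param_names(reduced)), 5L)
  fr <- fit_cholesky(reduced, ds, restarts = 1, seed = 5,
                     start = coef(fa)[intersect(names(coef(fa)),
                                                model_param_names(reduced))],
                     control = list(rel.tol = 1e-6, iter.max = 60))
  row <- likelihood_ratio_test(fa, fr)
  expect_equal(row$delta_df, 5L)
  expect_gte(row$delta_m2ll, 0)
  expect_error(likelihood_ratio_test(fr, fa), "more free parameters")
})

test_that("interior-null likelihood-ratio p-values are approximately uniform", {
  # truth: bivariate AE with zero genetic covariance path (interior null)
  truth <- bivariate_ae(h2 = c(0.5, 0.5), rA = 0, rE = 0.25,
                        tau = c(0.7, 0.9), names = c("v1", "v2"))
  full <- cholesky_model(list(spec_binary("v1"), spec_binary("v2")),
                         components = c("A", "E"))
  reduced <- fix_paths(full, "A", list(c(2, 1)))
  pvals <- vapply(1:60, function(r) {
    ds <- sim_ds(truth, 400, 400, seed = 5200 + r)
    ff <- fit_cholesky(full, ds, restarts = 1, seed = r)
    fr <- fit_cholesky(reduced, ds, restarts = 1, seed = r,
                       start = coef(ff)[model_param_names(reduced)])
    likelihood_ratio_test(ff, fr)$p
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("threshold-homogeneity test has 3 df, holds its size, and detects shifted thresholds", {
  truth <- univariate_ae(h2 = 0.4, tau = 0.9, name = "v")
  ds <- sim_ds(truth, 600, 600, seed = 506)
  row <- test_threshold_homogeneity(ds, "v")
  expect_equal(row$delta_df, 3L)
  expect_gte(row$delta_m2ll, 0)

  # size under homogeneous truth
  rej <- vapply(1:60, function(r) {
    dsr <- sim_ds(truth, 400, 400, seed = 5300 + r)
    test_threshold_homogeneity(dsr, "v")$p < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.15)

  # power: twin 2 re-thresholded half a liability SD higher, using the
  # latent component values recorded in the truth sidecar
  rej2 <- vapply(1:20, function(r) {
    out <- simulate_ace_cohort(sim_config(1000, 1000, truth,
                                          seed = 5400 + r))
    tr <- out$truth$components
    lat2 <- c(tr$MZ$A[[2]][, 1] + tr$MZ$E[[2]][, 1],
              tr$DZ$A[[2]][, 1] + tr$DZ$E[[2]][, 1])
    out$dataset$data$v_t2 <- as.integer(lat2 > 0.9 + 0.5)
    test_threshold_homogeneity(out$dataset, "v")$p < 0.05
  }, TRUE)
  expect_gt(mean(rej2), 0.5)

  # empty-cell error
  dse <- ds; dse$data$v_t2[dse$data$zygosity == "MZ"] <- NA
  expect_error(test_threshold_homogeneity(dse, "v"), "MZ twin 2")
})

test_that("model selection recovers the generating component structure", {
  vars <- list(spec_binary("v"))
  ladder_of <- function() model_ladder(cholesky_model(vars))
  pick <- function(truth_pr, corrs, seed) {
    truth <- cholesky_from_components(vars, truth_pr)
    th <- model_get_params(truth); th["tau_v"] <- 0.85
    truth <- model_set_params(truth, th)
    vapply(1:40, function(r) {
      ds <- sim_ds(truth, 800, 800, seed = seed + r)
      sel <- select_model(ladder_of(), ds, restarts = 1, seed = r)
      sel$best$label
    }, "")
  }
  ae <- pick(cbind(A = 0.55, C = 0, E = 0.45), NULL, 6000)
  expect_gt(mean(ae == "AE"), 0.5)
  ce <- pick(cbind(A = 0, C = 0.55, E = 0.45), NULL, 7000)
  expect_gt(mean(ce == "CE"), 0.5)

  # degenerate one-model ladder returns that model with no comparisons
  truth <- univariate_ae(0.5, 0.9, name = "v")
  ds <- sim_ds(truth, 200, 200, seed = 77)
  one <- select_model(list(AE = cholesky_model(vars, c("A", "E"))), ds,
                      restarts = 1, seed = 1)
  expect_equal(one$best$label, "AE")
  expect_equal(nrow(one$comparisons), 0L)
})

test_that("profile intervals contain the estimate, respect bounds, and flag boundaries", {
  truth <- univariate_ae(h2 = 0.45, tau = 0.9)
  ds <- sim_ds(truth, 800, 800, seed = 508)
  f <- fit_cholesky(cholesky_model(list(spec_binary("mdd")),
                                   components = c("A", "E")),
                    ds, restarts = 2, seed = 8)
  ci <- profile_ci(f, "A[mdd]")
  expect_lt(ci$lower, ci$estimate)
  expect_gt(ci$upper, ci$estimate)
  expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)

  # profiling the path and squaring agrees with profiling the proportion
  ci_a <- profile_ci(f, "a11")
  expect_equal(ci$lower, ci_a$lower^2, tolerance = 5e-3)
  expect_equal(ci$upper, ci_a$upper^2, tolerance = 5e-3)

  # C truly absent: its lower bound sits on the 0 boundary, flagged
  fc <- fit_cholesky(cholesky_model(list(spec_binary("mdd"))), ds,
                     restarts = 2, seed = 9)
  ci_c <- profile_ci(fc, "C[mdd]")
  expect_equal(ci_c$lower, 0)
  expect_true(ci_c$boundary[["lower"]])
})

test_that("bootstrap intervals: degenerate B equals min/max and seeds reproduce exactly", {
  truth <- univariate_ae(h2 = 0.5, tau = 0.9)
  ds <- sim_ds(truth, 150, 150, seed = 509)
  f <- fit_cholesky(cholesky_model(list(spec_binary("mdd")),
                                   components = c("A", "E")),
                    ds, restarts = 1, seed = 10)
  b2 <- bootstrap_ci(f, B = 2, seed = 42, quantities = "A[mdd]")
  expect_equal(nrow(b2$draws), 2L)
  expect_equal(b2$ci$lower, min(b2$draws))
  expect_equal(b2$ci$upper, max(b2$draws))
  b2b <- bootstrap_ci(f, B = 2, seed = 42, quantities = "A[mdd]")
  expect_identical(b2$ci, b2b$ci)
})

test_that("optimized -2LL is monotone along the nesting ladder and AIC identities hold", {
  cfg <- default_cohort_config(seed = 510, n_mz_pairs = 150, n_dz_pairs = 150)
  ds <- simulate_ace_cohort(cfg)$dataset
  lad <- model_ladder(cholesky_model(ds$variables["mdd"]))
  sel <- select_model(lad, ds, restarts = 1, seed = 11)
  m2 <- vapply(sel$fits, `[[`, 0, "m2ll")
  expect_gte(m2[["AE"]] - m2[["ACE"]], -1e-4)
  expect_gte(m2[["CE"]] - m2[["ACE"]], -1e-4)
  expect_gte(m2[["E"]] - m2[["AE"]], -1e-4)
  for (f in sel$fits)
    expect_equal(f$aic, f$m2ll + 2 * f$n_free_params)
})
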