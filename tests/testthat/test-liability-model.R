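test_that("E-only model implies identity within-member covariance and zero cross-twin block", {
  vars <- list(spec_prs("x"), variable_spec("y", "continuous"))
  m <- cholesky_model(vars, components = "E")
  # x allows only A, so an E-only model cannot host it
  expect_error(cholesky_model(list(spec_binary("b")), components = "X"))

  m2 <- cholesky_model(list(variable_spec("y1", "continuous"),
                            variable_spec("y2", "continuous")),
                       components = "E")
  th <- model_get_params(m2)
  th[c("e11", "e22")] <- 1; th["e21"] <- 0
  m2 <- model_set_params(m2, th)
  mom_mz <- expected_moments(m2, "MZ")
  expect_equal(unname(mom_mz$cov), diag(4))
  expect_equal(unname(mom_mz$Sx), matrix(0, 2, 2))
  expect_error(expected_moments(m2, "XX"), "zygosity")
})

test_that("A-only cross-twin blocks scale by the DZ genetic sharing of one half", {
  vars <- list(spec_prs("p1"), spec_prs("p2"))
  m <- cholesky_model(vars, components = "A")
  th <- model_get_params(m)
  th["a11"] <- 1; th["a21"] <- 0.4; th["a22"] <- 0.8
  m <- model_set_params(m, th)
  mz <- expected_moments(m, "MZ")
  dz <- expected_moments(m, "DZ")
  expect_equal(dz$Sx, 0.5 * mz$Sx)
  expect_equal(mz$Sx, mz$Sw)  # pure A: MZ cross block equals within block
})

test_that("expected moments match the brute-force path-tracing oracle", {
  m <- random_binary_model(p = 3, seed = 101)
  L <- m$L
  for (z in c("MZ", "DZ")) {
    oracle <- path_tracing_moments(L, z)
    mom <- expected_moments(m, z)
    expect_equal(unname(mom$Sw), oracle$Sw, tolerance = 1e-10)
    expect_equal(unname(mom$Sx), oracle$Sx, tolerance = 1e-10)
    # assembled 2p x 2p matrix is symmetric PSD with unit binary diagonal
    expect_equal(mom$cov, t(mom$cov))
    expect_gte(min(eigen(mom$cov, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
    expect_equal(unname(diag(mom$cov)), rep(1, 6), tolerance = 1e-10)
  }
})

test_that("covariate effects shift per-member means as definition variables", {
  m <- cholesky_model(list(spec_binary("mdd", covariates = "sex")),
                      components = c("A", "E"))
  th <- model_get_params(m)
  th["a11"] <- sqrt(0.4); th["tau_mdd"] <- 1; th["b_mdd_sex"] <- 0.5
  m <- model_set_params(m, th)
  mom <- expected_moments(m, "DZ",
                          covariates = list(t1 = c(sex = 1), t2 = c(sex = 0)))
  expect_equal(unname(mom$mean), c(0.5, 0))
  expect_equal(unname(mom$thresholds), c(1, 1))
})

test_that("standardized components sum to one and match the covariance-based oracle", {
  m <- random_binary_model(p = 3, components = c("A", "E"), seed = 202)
  cs <- standardized_components(m)
  expect_equal(unname(rowSums(cs$proportions)), rep(1, 3), tolerance = 1e-10)
  # oracle: proportions from the assembled component covariances
  o <- path_tracing_moments(m$L["A"], "MZ")$Sw
  v <- diag(path_tracing_moments(m$L, "MZ")$Sw)
  expect_equal(unname(cs$proportions[, "A"]), unname(diag(o) / v),
               tolerance = 1e-10)

  # degenerate single-variable pure-A case
  m1 <- cholesky_model(list(spec_prs("p")), components = "A")
  expect_equal(unname(standardized_components(m1)$proportions["p", ]),
               c(1, 0, 0))
})

test_that("component correlations have unit diagonal, collapse to ±1 for single factors, and match the oracle", {
  # two variables loading on one genetic factor only
  m <- cholesky_model(list(spec_binary("v1"), spec_binary("v2")),
                      components = c("A", "E"))
  th <- model_get_params(m)
  th["a11"] <- 0.6; th["a21"] <- -0.5; th["a22"] <- 0; th["e21"] <- 0
  m <- model_set_params(m, th)
  rA <- component_correlations(m)$A
  expect_equal(diag(rA), c(v1 = 1, v2 = 1))
  expect_equal(rA[2, 1], -1, tolerance = 1e-10)

  m3 <- random_binary_model(p = 3, seed = 303)
  rr <- component_correlations(m3)
  SA <- path_tracing_moments(m3$L["A"], "MZ")$Sw
  expect_equal(unname(rr$A), unname(stats::cov2cor(SA)), tolerance = 1e-8)
  expect_equal(rr$A, t(rr$A))
})

test_that("undefined component correlations are reported absent, not zero", {
  m <- cholesky_model(list(spec_prs("prs"), spec_binary("mdd")),
                      components = c("A", "E"))
  rE <- component_correlations(m)$E
  expect_true(is.na(rE["prs", "mdd"]))
  expect_true(is.na(rE["prs", "prs"]))
  expect_equal(rE["mdd", "mdd"], 1)
})

test_that("moment symmetry and MZ-dominance hold over random same-sign draws", {
  for (s in 1:8) {
    m <- random_binary_model(p = 3, seed = 400 + s)
    # force all A paths non-negative so MZ >= DZ elementwise is implied
    m$L$A <- abs(m$L$A)
    m <- model_set_params(m, model_get_params(m))
    mz <- expected_moments(m, "MZ")
    dz <- expected_moments(m, "DZ")
    expect_equal(mz$cov, t(mz$cov))
    expect_true(all(mz$Sx - dz$Sx > -1e-12))
    expect_gte(min(eigen(dz$cov, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("rescaling a continuous variable's paths leaves standardized quantities invariant", {
  vars <- list(spec_prs("prs"), spec_binary("mdd"))
  m <- cholesky_model(vars, components = c("A", "E"))
  th <- model_get_params(m)
  th["a11"] <- 1; th["a21"] <- 0.3; th["a22"] <- 0.5
  m1 <- model_set_params(m, th)
  th2 <- th; th2["a11"] <- 3 * th["a11"]
  m2 <- model_set_params(m, th2)
  expect_equal(standardized_components(m1)$proportions["prs", ],
               standardized_components(m2)$proportions["prs", ])
  expect_equal(component_correlations(m1)$A["prs", "mdd"],
               component_correlations(m2)$A["prs", "mdd"], tolerance = 1e-12)
})

test_that("derived diagonals keep binary liability variance at one across the ladder", {
  full <- cholesky_model(list(spec_prs("prs"), spec_binary("mdd"),
                              spec_binary("si")),
                         components = c("A", "C", "E"))
  lad <- model_ladder(full)
  expect_named(lad, c("ACE", "AE", "CE", "E"))
  for (m in lad) {
    th <- model_get_params(m)
    th[grepl("^[ace]\\d\\d$", names(th))] <- 0.3
    m2 <- model_set_params(m, th)
    v <- diag(twinpath:::model_implied(m2)$Sw)
    expect_equal(unname(v[2:3]), c(1, 1), tolerance = 1e-10)
  }
  # the CE model retains the score's own loading but no other A paths
  expect_true("a11" %in% model_param_names(lad$CE))
  expect_false(any(c("a21", "a22", "a31", "a32", "a33") %in%
                     model_param_names(lad$CE)))
})
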