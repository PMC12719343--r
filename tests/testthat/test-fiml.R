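test_that("rectangle probabilities handle total mass, symmetry and the arcsine orthant", {
  expect_equal(mvn_rectangle_probability(0, matrix(1), -Inf, Inf), 1)
  expect_equal(mvn_rectangle_probability(0, matrix(1), -Inf, 0), 0.5)
  # bivariate orthant with correlation 0.5: 1/4 + asin(0.5)/(2 pi) = 1/3
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(mvn_rectangle_probability(c(0, 0), S, c(0, 0), c(Inf, Inf)),
               1 / 4 + asin(0.5) / (2 * pi), tolerance = 1e-6)
  expect_equal(mvn_rectangle_probability(c(0, 0), S, c(0, 0), c(Inf, Inf)),
               1 / 3, tolerance = 1e-6)
  expect_error(mvn_rectangle_probability(c(0, 0), S, c(1, 0), c(0, Inf)),
               "bounds")
  expect_error(mvn_rectangle_probability(rep(0, 9), diag(9), rep(-1, 9),
                                         rep(1, 9)), "unsupported")
})

test_that("rectangle probabilities agree with Monte Carlo within 3 SEs across random draws", {
  set.seed(77)
  for (rep in 1:40) {
    k <- sample(2:4, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(k)
    mu <- rnorm(k, 0, 0.5)
    lo <- mu - runif(k, 0.3, 2) * sqrt(diag(S))
    hi <- lo + runif(k, 0.5, 3) * sqrt(diag(S))
    p <- mvn_rectangle_probability(mu, S, lo, hi)
    mc <- mc_rectangle(mu, S, lo, hi, n = 1e5, seed = 1000 + rep)
    expect_lt(abs(p - mc$p), 3 * mc$se)
  }
})

test_that("Gaussian conditioning reproduces textbook identities and the matrix-inversion oracle", {
  # independence: conditioning changes nothing
  S <- diag(c(2, 3))
  cm <- conditional_ordinal_moments(c(1, -1), S, list(index = 1, value = 5))
  expect_equal(cm$mean, -1)
  expect_equal(unname(cm$cov), matrix(3))

  # bivariate textbook case
  r <- 0.6
  S2 <- matrix(c(1, r, r, 1), 2)
  cm2 <- conditional_ordinal_moments(c(0, 0), S2, list(index = 1, value = 1))
  expect_equal(unname(cm2$mean), r)
  expect_equal(unname(cm2$cov), matrix(1 - r^2))

  # 6-dimensional random case vs explicit solve()
  set.seed(8)
  A <- matrix(rnorm(36), 6)
  S6 <- crossprod(A) + diag(6)
  mu <- rnorm(6)
  idx <- c(2, 5); x <- c(0.3, -1.2)
  cm6 <- conditional_ordinal_moments(mu, S6, list(index = idx, value = x))
  inv <- solve(S6[idx, idx])
  rest <- setdiff(1:6, idx)
  expect_equal(cm6$mean,
               mu[rest] + drop(S6[rest, idx] %*% inv %*% (x - mu[idx])),
               tolerance = 1e-10)
  expect_equal(cm6$cov,
               S6[rest, rest] - S6[rest, idx] %*% inv %*% S6[idx, rest],
               tolerance = 1e-10)
  expect_error(conditional_ordinal_moments(c(0, 0), matrix(c(1, 1, 1, 1), 2),
                                           list(index = 1:2, value = c(1, 2))),
               "singular")
})

test_that("family contributions: all-missing zero, continuous matches the closed form, symmetric threshold gives log(1/2)", {
  m <- bivariate_ae(names = c("v1", "v2"))
  fam <- list(zygosity = "MZ", v1_t1 = NA, v1_t2 = NA, v2_t1 = NA,
              v2_t2 = NA)
  expect_equal(family_loglik(fam, m)$loglik, 0)

  # complete continuous pair: exact multivariate normal log-density
  vars <- list(variable_spec("y1", "continuous"),
               variable_spec("y2", "continuous"))
  mc <- cholesky_model(vars, components = c("A", "E"))
  th <- model_get_params(mc)
  th[c("a11", "a21", "a22")] <- c(0.8, 0.3, 0.6)
  th[c("e11", "e21", "e22")] <- c(0.6, -0.2, 0.5)
  th[c("mu_y1", "mu_y2")] <- c(0.1, -0.4)
  mc <- model_set_params(mc, th)
  fam2 <- list(zygosity = "DZ", y1_t1 = 0.5, y1_t2 = -0.3, y2_t1 = 1.1,
               y2_t2 = 0.2)
  mom <- expected_moments(mc, "DZ")
  y <- c(0.5, 1.1, -0.3, 0.2)  # member-1 variables then member-2
  R <- chol(mom$cov)
  z <- backsolve(R, y - mom$mean, transpose = TRUE)
  ld <- -0.5 * (4 * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
  expect_equal(family_loglik(fam2, mc)$loglik, ld, tolerance = 1e-10)

  # affected singleton at threshold zero
  m0 <- univariate_ae(h2 = 0.4, tau = 0)
  fam3 <- list(zygosity = "MZ", mdd_t1 = 1, mdd_t2 = NA)
  expect_equal(family_loglik(fam3, m0)$loglik, log(0.5), tolerance = 1e-8)
})

test_that("dataset -2LL doubles under duplication and ignores family order", {
  m <- bivariate_ae(names = c("v1", "v2"))
  ds <- sim_ds(m, 40, 40, seed = 90)
  v <- dataset_m2ll(m, ds)
  ds2 <- ds
  d2 <- ds$data
  d2$family_id <- paste0(d2$family_id, "b")
  ds2$data <- rbind(ds$data, d2)
  expect_equal(dataset_m2ll(m, ds2), 2 * v, tolerance = 1e-8)

  ds3 <- ds
  ds3$data <- ds$data[rev(seq_len(nrow(ds$data))), ]
  expect_equal(dataset_m2ll(m, ds3), v, tolerance = 1e-10)
})

test_that("complete-pair response-pattern probabilities sum to one", {
  m <- bivariate_ae(h2 = c(0.5, 0.3), rA = 0.6, rE = 0.3,
                    names = c("v1", "v2"))
  for (z in c("MZ", "DZ")) {
    tot <- 0
    for (p1 in 0:1) for (p2 in 0:1) for (p3 in 0:1) for (p4 in 0:1) {
      fam <- list(zygosity = z, v1_t1 = p1, v2_t1 = p2, v1_t2 = p3,
                  v2_t2 = p4)
      tot <- tot + exp(family_loglik(fam, m)$loglik)
    }
    expect_equal(tot, 1, tolerance = 1e-6)
  }
})

test_that("dataset -2LL matches a Monte-Carlo likelihood oracle on a small cohort", {
  m <- bivariate_ae(h2 = c(0.4, 0.6), rA = 0.5, rE = 0.2,
                    tau = c(0.6, 0.9), names = c("v1", "v2"))
  ds <- sim_ds(m, 2, 1, seed = 55)
  ll_mc <- 0; var_mc <- 0
  ndraw <- 2e6
  for (i in seq_len(nrow(ds$data))) {
    fam <- ds$data[i, ]
    mom <- expected_moments(m, fam$zygosity)
    set.seed(7000 + i)
    L <- t(chol(mom$cov + diag(1e-10, 4)))
    X <- L %*% matrix(rnorm(4 * ndraw), 4)
    y <- unlist(fam[c("v1_t1", "v2_t1", "v1_t2", "v2_t2")])
    hit <- rep(TRUE, ndraw)
    for (j in 1:4) {
      if (is.na(y[j])) next
      hit <- hit & (if (y[j] == 1) X[j, ] > mom$thresholds[j]
                    else X[j, ] <= mom$thresholds[j])
    }
    p <- mean(hit)
    ll_mc <- ll_mc + log(p)
    var_mc <- var_mc + (1 - p) / (p * ndraw)  # delta-method var of log(p)
  }
  expect_lt(abs(dataset_m2ll(m, ds) - (-2 * ll_mc)),
            3 * 2 * sqrt(var_mc))
})

test_that("the generating parameters beat perturbed parameters in likelihood", {
  m <- bivariate_ae(h2 = c(0.4, 0.6), rA = 0.5, rE = 0.2,
                    names = c("v1", "v2"))
  ds <- sim_ds(m, 1500, 1500, seed = 66)
  base <- dataset_m2ll(m, ds)
  set.seed(11)
  worse <- 0
  for (r in 1:10) {
    th <- model_get_params(m)
    th <- th + rnorm(length(th), 0, 0.15)
    m2 <- model_set_params(m, th)
    if (!m2$valid) next
    if (dataset_m2ll(m2, ds) > base) worse <- worse + 1 else worse <- worse - 1
  }
  expect_gt(worse, 0)  # perturbations are stochastically worse
})
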