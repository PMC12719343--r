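# Shared fixtures and independent oracles used across the test files.

# -- tiny variable-spec fixtures --------------------------------------------

spec_binary <- function(name = "mdd", covariates = character())
  variable_spec(name, "binary_liability", covariates = covariates)

spec_prs <- function(name = "prs")
  variable_spec(name, "continuous", components = "A")

# univariate binary AE generating model with standardized A = h2 and
# threshold tau
univariate_ae <- function(h2 = 0.4, tau = stats::qnorm(1 - 0.18),
                          name = "mdd") {
  m <- cholesky_from_components(list(spec_binary(name)),
                                cbind(A = h2, C = 0, E = 1 - h2),
                                components = c("A", "E"))
  th <- model_get_params(m)
  th[paste0("tau_", name)] <- tau
  model_set_params(m, th)
}

# bivariate binary AE truth with chosen genetic/environment correlations
bivariate_ae <- function(h2 = c(0.4, 0.6), rA = 0.5, rE = 0.2,
                         tau = c(0.9, 1.1), names = c("v1", "v2")) {
  RA <- matrix(c(1, rA, rA, 1), 2)
  RE <- matrix(c(1, rE, rE, 1), 2)
  m <- cholesky_from_components(
    list(spec_binary(names[1L]), spec_binary(names[2L])),
    cbind(A = h2, C = 0, E = 1 - h2),
    corr = list(A = RA, E = RE), components = c("A", "E"))
  th <- model_get_params(m)
  th[paste0("tau_", names)] <- tau
  model_set_params(m, th)
}

sim_ds <- function(model, n_mz, n_dz, seed, ...) {
  simulate_ace_cohort(sim_config(n_mz, n_dz, model, seed = seed,
                                 ...))$dataset
}

# -- independent oracles ----------------------------------------------------

# Monte-Carlo rectangle probability with its standard error
mc_rectangle <- function(mean, cov, lower, upper, n = 2e5, seed = 1) {
  set.seed(seed)
  L <- t(chol(cov + diag(1e-12, nrow(cov))))
  Z <- matrix(stats::rnorm(n * length(mean)), length(mean), n)
  X <- mean + L %*% Z
  inside <- colSums(X > lower & X < upper) == length(mean)
  p <- mean(inside)
  list(p = p, se = sqrt(max(p * (1 - p), 1 / n) / n))
}

# brute-force path-tracing oracle for the model-implied twin covariance:
# sums over all chains variable_i <- factor_k -> variable_j with the
# component's cross-twin factor correlation
path_tracing_moments <- function(L_list, zygosity) {
  share <- c(A = if (zygosity == "MZ") 1 else 0.5, C = 1, E = 0)
  p <- nrow(L_list[[1L]])
  Sw <- Sx <- matrix(0, p, p)
  for (X in names(L_list)) {
    L <- L_list[[X]]
    for (i in seq_len(p)) for (j in seq_len(p)) for (k in seq_len(p)) {
      Sw[i, j] <- Sw[i, j] + L[i, k] * L[j, k]
      Sx[i, j] <- Sx[i, j] + share[[X]] * L[i, k] * L[j, k]
    }
  }
  list(Sw = Sw, Sx = Sx)
}

# exhaustive enumeration of full-sibling allele-count covariance at one
# biallelic locus with allele frequency q: enumerate both parents'
# genotypes and all four transmission patterns
sibling_allele_correlation <- function(q) {
  gprob <- stats::dbinom(0:2, 2, q)
  tot <- 0; m1 <- 0; m2 <- 0; e12 <- 0; v1 <- 0
  for (gm in 0:2) for (gf in 0:2) {
    pg <- gprob[gm + 1] * gprob[gf + 1]
    # transmitted allele from a parent with count g is Bernoulli(g/2)
    for (am1 in 0:1) for (af1 in 0:1) for (am2 in 0:1) for (af2 in 0:1) {
      pt <- stats::dbinom(am1, 1, gm / 2) * stats::dbinom(af1, 1, gf / 2) *
        stats::dbinom(am2, 1, gm / 2) * stats::dbinom(af2, 1, gf / 2)
      pr <- pg * pt
      c1 <- am1 + af1; c2 <- am2 + af2
      tot <- tot + pr
      m1 <- m1 + pr * c1; m2 <- m2 + pr * c2
      e12 <- e12 + pr * c1 * c2
      v1 <- v1 + pr * c1^2
    }
  }
  (e12 - m1 * m2) / (v1 - m1^2)
}

# random valid Cholesky AE/ACE model over p binary variables (unit
# liability variances), for property tests
random_binary_model <- function(p = 3, components = c("A", "C", "E"),
                                seed = 1) {
  set.seed(seed)
  k <- length(components)
  pr <- matrix(stats::runif(p * k, 0.1, 1), p, k)
  pr <- pr / rowSums(pr)
  colnames(pr) <- components
  pr3 <- matrix(0, p, 3, dimnames = list(NULL, c("A", "C", "E")))
  pr3[, components] <- pr
  corr <- lapply(components, function(X) {
    R <- stats::cov2cor(crossprod(matrix(stats::rnorm(p * p), p, p)) +
                          diag(p))
    R
  })
  names(corr) <- components
  vars <- lapply(paste0("v", seq_len(p)), spec_binary)
  m <- cholesky_from_components(vars, pr3, corr = corr,
                                components = components)
  th <- model_get_params(m)
  th[startsWith(names(th), "tau_")] <- stats::runif(p, -1, 1.2)
  model_set_params(m, th)
}
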