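#' Multivariate normal rectangle probability
#'
#' P(lower < X < upper) for X ~ Normal(mean, cov), evaluated by
#' deterministic adaptive quadrature (no Monte-Carlo noise, so the FIML
#' objective stays smooth for gradient-free optimizers). Absolute accuracy
#' is targeted at 1e-6 or better for up to 4 dimensions; dimensions above
#' 8 are not supported.
#'
#' @param mean Mean vector.
#' @param cov Positive semi-definite covariance matrix.
#' @param lower,upper Bound vectors; \code{-Inf}/\code{Inf} allowed.
#' @return A probability in [0, 1].
#' @export
mvn_rectangle_probability <- function(mean, cov, lower, upper) {
  k <- length(mean)
  cov <- as.matrix(cov)
  if (k == 0L) return(1)
  if (length(lower) != k || length(upper) != k || any(dim(cov) != k))
    stop("dimension mismatch between mean, cov and bounds")
  if (any(lower >= upper)) stop("invalid bounds: need lower < upper elementwise")
  if (k > 8L) stop("rectangle probabilities above dimension 8 are unsupported")
  if (k == 1L) {
    s <- sqrt(cov[1L, 1L])
    return(stats::pnorm(upper, mean, s) - stats::pnorm(lower, mean, s))
  }
  val <- if (k == 2L)
    mnormt::biv.nt.prob(0, lower, upper, mean, cov)
  else
    mnormt::sadmvn(lower, upper, mean, cov, maxpts = 50000 * k,
                   abseps = 1e-8)
  min(max(as.numeric(val), 0), 1)
}

#' Gaussian conditional moments given observed continuous coordinates
#'
#' Standard multivariate-normal conditioning: partition the joint
#' distribution into observed continuous coordinates and the rest, and
#' return the conditional mean and covariance of the rest. The
#' conditional covariance does not depend on the observed values.
#'
#' @param mean Joint mean vector.
#' @param cov Joint covariance matrix.
#' @param observed Named list or two-column structure of indices and
#'   values: \code{list(index =, value =)}.
#' @return List with \code{mean} and \code{cov} of the remaining
#'   coordinates (in their original order), and \code{remaining} indices.
#' @export
conditional_ordinal_moments <- function(mean, cov, observed) {
  idx <- observed$index
  x <- observed$value
  stopifnot(length(idx) == length(x), !anyDuplicated(idx))
  rest <- setdiff(seq_along(mean), idx)
  Scc <- cov[idx, idx, drop = FALSE]
  R <- tryCatch(chol(Scc),
                error = function(e) stop("singular continuous block"))
  Sbc <- cov[rest, idx, drop = FALSE]
  W <- backsolve(R, backsolve(R, t(Sbc), transpose = TRUE))  # Scc^{-1} Scb
  list(mean = mean[rest] + drop(crossprod(W, x - mean[idx])),
       cov = cov[rest, rest, drop = FALSE] - Sbc %*% W,
       remaining = rest)
}

# log-density of x under N(mu, S) via Cholesky; returns -Inf on failure
mvn_logdens <- function(x, mu, S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z))
}

# degenerate-Gaussian log-density on the support of a PSD covariance.
# MZ pairs of a pure additive-genetic score have identical values and a
# singular 2x2 block; the density is taken over the positive-eigenvalue
# subspace, requiring the residual in null directions to vanish.
mvn_logdens_psd <- function(x, mu, S, tol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE)
  lam <- ev$values
  keep <- lam > tol * max(lam, 1)
  z <- drop(crossprod(ev$vectors, x - mu))
  if (any(abs(z[!keep]) > 1e-6)) return(-Inf)
  if (!any(keep)) return(0)
  -0.5 * (sum(keep) * log(2 * pi) + sum(log(lam[keep])) +
            sum(z[keep]^2 / lam[keep]))
}

# conditional moments of the remaining coordinates given continuous
# observations, via the pseudo-inverse of the (possibly singular)
# continuous block
conditional_moments_psd <- function(mu_b, S_bb, S_bc, mu_c, x_c,
                                    S_cc, tol = 1e-10) {
  ev <- eigen(S_cc, symmetric = TRUE)
  lam <- ev$values
  keep <- lam > tol * max(lam, 1)
  Vk <- ev$vectors[, keep, drop = FALSE]
  W <- Vk %*% (t(Vk) / lam[keep])        # pseudo-inverse of S_cc
  list(mean = mu_b + drop(S_bc %*% W %*% (x_c - mu_c)),
       cov = S_bb - S_bc %*% W %*% t(S_bc))
}

#' Log-likelihood contribution of one family
#'
#' Full-information maximum likelihood for mixed continuous/binary twin
#' data: the contribution is the log of [density of the observed
#' continuous values] x [rectangle probability of the observed binary
#' response pattern under the conditional liability distribution given the
#' continuous values]. Missing coordinates are marginalized by deletion; a
#' family with every phenotype missing contributes exactly 0.
#'
#' @param family One-row data.frame in the wide cohort layout (or a list
#'   with the same named fields).
#' @param model A \code{\link{cholesky_model}}.
#' @return List with \code{loglik}, \code{n_obs_continuous},
#'   \code{n_obs_binary}.
#' @export
family_loglik <- function(family, model) {
  p <- model$p
  vars <- model$vars
  y <- unlist(family[paste0(rep(vars, 2), "_t", rep(1:2, each = p))],
              use.names = FALSE)
  covs <- unique(model$beta$covariate)
  cx <- lapply(1:2, function(mm) {
    out <- lapply(covs, function(cv) {
      val <- family[[paste0(cv, "_t", mm)]]
      if (is.null(val)) NA_real_ else as.numeric(val)
    })
    stats::setNames(unlist(out, use.names = FALSE) %||% numeric(), covs)
  })
  mom <- expected_moments(model, family$zygosity,
                          covariates = list(t1 = cx[[1L]], t2 = cx[[2L]]))
  ll <- pattern_loglik(y, mom, model$scale)
  list(loglik = ll$loglik,
       n_obs_continuous = ll$n_cont, n_obs_binary = ll$n_bin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# core FIML evaluation for one observed pattern; y is the length-2p value
# vector (NA = missing), mom the expected_moments() output
pattern_loglik <- function(y, mom, scale) {
  scl <- rep(scale, 2L)
  obs <- !is.na(y)
  if (!any(obs)) return(list(loglik = 0, n_cont = 0L, n_bin = 0L))
  ic <- which(obs & scl == "continuous")
  ib <- which(obs & scl == "binary_liability")
  ll <- 0
  if (length(ic)) {
    ll <- mvn_logdens_psd(y[ic], mom$mean[ic],
                          mom$cov[ic, ic, drop = FALSE])
    if (!is.finite(ll)) return(list(loglik = -Inf, n_cont = length(ic),
                                    n_bin = length(ib)))
  }
  if (length(ib)) {
    if (length(ic)) {
      cm <- conditional_moments_psd(
        mom$mean[ib], mom$cov[ib, ib, drop = FALSE],
        mom$cov[ib, ic, drop = FALSE], mom$mean[ic], y[ic],
        mom$cov[ic, ic, drop = FALSE])
      mu_b <- cm$mean
      S_b <- cm$cov
    } else {
      mu_b <- mom$mean[ib]
      S_b <- mom$cov[ib, ib, drop = FALSE]
    }
    tau <- mom$thresholds[ib]
    lo <- ifelse(y[ib] == 1, tau, -Inf)
    hi <- ifelse(y[ib] == 1, Inf, tau)
    pr <- tryCatch(mvn_rectangle_probability(mu_b, S_b, lo, hi),
                   error = function(e) NA_real_)
    if (!is.finite(pr)) return(list(loglik = -Inf, n_cont = length(ic),
                                    n_bin = length(ib)))
    if (pr < 1e-300) {
      warn_underflow()
      pr <- 1e-300
    }
    ll <- ll + log(pr)
  }
  list(loglik = ll, n_cont = length(ic), n_bin = length(ib))
}

# vectorized standard bivariate normal lower CDF Phi2(z1, z2; rho) for a
# scalar correlation and vectors of limits: Drezner-Wesolowsky quadrature
# over [0, asin(rho)] with fixed Gauss-Legendre nodes (used in the FIML
# hot loop where the correlation is constant within a pattern structure;
# |rho| >= 0.925 falls back to the scalar routine)
pbinorm_vec <- function(z1, z2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(z1) * stats::pnorm(z2))
  if (abs(rho) >= 0.925) {
    return(vapply(seq_along(z1), function(i)
      mnormt::biv.nt.prob(0, c(-Inf, -Inf), c(z1[i], z2[i]), c(0, 0),
                          matrix(c(1, rho, rho, 1), 2)), 0))
  }
  gl <- .twinpath_gl32
  a <- asin(rho)
  theta <- a / 2 * (gl$x + 1)
  w <- gl$w * a / 2
  s <- sin(theta)
  c2 <- cos(theta)^2
  acc <- 0
  for (q in seq_along(theta))
    acc <- acc + w[q] * exp(-(z1^2 + z2^2 - 2 * s[q] * z1 * z2) /
                              (2 * c2[q]))
  stats::pnorm(z1) * stats::pnorm(z2) + acc / (2 * pi)
}

.twinpath_gl32 <- local({
  gl <- function(n) {
    # Golub-Welsch: nodes/weights of Gauss-Legendre on [-1, 1]
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    list(x = e$values, w = 2 * e$vectors[1, ]^2)
  }
  gl(32L)
})

.twinpath_env <- new.env(parent = emptyenv())

warn_underflow <- function() {
  if (!isTRUE(.twinpath_env$underflow_warned)) {
    .twinpath_env$underflow_warned <- TRUE
    warning("rectangle probability underflow floored at 1e-300",
            call. = FALSE)
  }
  invisible(NULL)
}

reset_underflow_flag <- function() {
  .twinpath_env$underflow_warned <- FALSE
  invisible(NULL)
}

# ---- prepared-data representation -----------------------------------------
#
# Families are compiled once per (dataset, model) into observation groups.
# Families sharing zygosity, observed-coordinate pattern, binary responses,
# continuous values and model-relevant covariate values collapse into one
# weighted group, which makes all-binary no-covariate datasets (the common
# univariate twin-modelling case) evaluate in a handful of rectangle
# probabilities regardless of sample size. Groups are further clustered by
# observation-pattern *structure* (zygosity + observed coordinates), so the
# per-evaluation linear algebra (eigendecomposition of the continuous
# block, conditional covariance of the binary block) is done once per
# structure and only means and rectangle bounds vary within it.
prepare_fiml_data <- function(ds, model) {
  p <- model$p
  vars <- model$vars
  d <- ds$data
  n <- nrow(d)
  ymat <- as.matrix(d[, paste0(rep(vars, 2), "_t", rep(1:2, each = p))])
  covs <- unique(model$beta$covariate)
  covmat <- if (length(covs))
    as.matrix(d[, paste0(rep(covs, 2), "_t", rep(1:2, each = length(covs)))])
  else matrix(numeric(), n, 0L)

  # covariate signature: only covariate values attached to observed
  # variables affect the likelihood
  scl <- rep(model$scale, 2L)
  keys <- character(n)
  for (i in seq_len(n)) {
    yi <- ymat[i, ]
    obs <- which(!is.na(yi))
    sig <- ""
    if (nrow(model$beta)) {
      rel <- character()
      for (r in seq_len(nrow(model$beta))) {
        vi <- match(model$beta$variable[r], vars)
        for (mm in 1:2) {
          coord <- (mm - 1L) * p + vi
          if (coord %in% obs)
            rel <- c(rel, sprintf("%d.%d=%s", r, mm,
                                  format(covmat[i, paste0(model$beta$covariate[r],
                                                          "_t", mm)])))
        }
      }
      sig <- paste(rel, collapse = ";")
    }
    keys[i] <- paste(d$zygosity[i], paste(obs, collapse = ","),
                     paste(format(yi[obs], digits = 12), collapse = ","),
                     sig, sep = "|")
  }
  ugrp <- !duplicated(keys)
  gid <- match(keys, keys[ugrp])
  w <- tabulate(gid, nbins = sum(ugrp))
  rows <- which(ugrp)

  # structure key: zygosity + observed coordinate pattern
  obs_list <- lapply(rows, function(i) which(!is.na(ymat[i, ])))
  skey <- vapply(seq_along(rows), function(g)
    paste(d$zygosity[rows[g]], paste(obs_list[[g]], collapse = ","),
          sep = "|"), "")
  structures <- lapply(split(seq_along(rows), skey), function(gs) {
    i0 <- rows[gs[1L]]
    obs <- obs_list[[gs[1L]]]
    ic <- obs[scl[obs] == "continuous"]
    ib <- obs[scl[obs] == "binary_liability"]
    fam <- rows[gs]
    nb <- nrow(model$beta)
    # per-family covariate contribution to the mean of each observed coord
    B <- array(0, dim = c(length(gs), length(obs), max(nb, 1L)))
    if (nb) for (r in seq_len(nb)) {
      vi <- match(model$beta$variable[r], vars)
      for (mm in 1:2) {
        coord <- (mm - 1L) * p + vi
        k <- match(coord, obs)
        if (!is.na(k))
          B[, k, r] <- covmat[fam, paste0(model$beta$covariate[r],
                                          "_t", mm)]
      }
    }
    list(zygosity = d$zygosity[i0], obs = obs, ic = ic, ib = ib,
         icol = match(ic, obs), bcol = match(ib, obs),
         X = ymat[fam, ic, drop = FALSE],
         Y = ymat[fam, ib, drop = FALSE],
         B = B, weight = w[gs], n = length(gs))
  })
  list(structures = structures, n_families = n, n_beta = nrow(model$beta))
}

# evaluate -2LL over prepared structures for a model with parameters set;
# returns big value if the parameter vector leaves the valid region
fiml_m2ll_prepared <- function(model, prep) {
  if (!model$valid) return(1e10)
  imp <- model_implied(model)
  p <- model$p
  Sfull <- list(
    MZ = rbind(cbind(imp$Sw, imp$Sx_MZ), cbind(imp$Sx_MZ, imp$Sw)),
    DZ = rbind(cbind(imp$Sw, imp$Sx_DZ), cbind(imp$Sx_DZ, imp$Sw)))
  thr <- rep(NA_real_, p)
  thr[match(names(model$tau), model$vars)] <- model$tau
  thr2 <- c(thr, thr)
  mu_base_full <- rep(0, p)
  mu_base_full[match(names(model$mu), model$vars)] <- model$mu
  mu_base_full <- rep(mu_base_full, 2L)
  beta <- model$beta$value
  total <- 0
  for (st in prep$structures) {
    S <- Sfull[[st$zygosity]]
    nobs <- length(st$obs)
    # per-family mean at observed coordinates
    Mu <- matrix(mu_base_full[st$obs], st$n, nobs, byrow = TRUE)
    if (length(beta)) for (r in seq_along(beta))
      Mu <- Mu + beta[r] * st$B[, , r]
    ll <- numeric(st$n)
    ic <- st$ic; ib <- st$ib
    if (length(ic)) {
      Scc <- S[ic, ic, drop = FALSE]
      ev <- eigen(Scc, symmetric = TRUE)
      lam <- ev$values
      keep <- lam > 1e-10 * max(lam, 1)
      Z <- st$X - Mu[, st$icol, drop = FALSE]
      if (any(!keep)) {
        resid <- Z %*% ev$vectors[, !keep, drop = FALSE]
        if (max(abs(resid)) > 1e-6) return(1e10)
      }
      Vk <- ev$vectors[, keep, drop = FALSE]
      Q <- Z %*% sweep(Vk, 2L, sqrt(lam[keep]), "/")
      ll <- ll - 0.5 * (sum(keep) * log(2 * pi) + sum(log(lam[keep])) +
                          rowSums(Q * Q))
    }
    if (length(ib)) {
      if (length(ic)) {
        W <- Vk %*% (t(Vk) / lam[keep])
        Sbc <- S[ib, ic, drop = FALSE]
        K <- Sbc %*% W
        S_b <- S[ib, ib, drop = FALSE] - K %*% t(Sbc)
        MuB <- Mu[, st$bcol, drop = FALSE] +
          (st$X - Mu[, st$icol, drop = FALSE]) %*% t(K)
      } else {
        S_b <- S[ib, ib, drop = FALSE]
        MuB <- Mu[, st$bcol, drop = FALSE]
      }
      tau <- thr2[ib]
      kb <- length(ib)
      # a binary response pattern is an orthant: flipping affected
      # coordinates turns it into a single lower-CDF evaluation
      if (kb <= 2L) {
        sdb <- sqrt(diag(S_b))
        D <- 1 - 2 * st$Y                       # +1 if y=0, -1 if y=1
        Zb <- D * sweep(-sweep(MuB, 2L, tau), 2L, sdb, "/")
        pr <- if (kb == 1L) {
          stats::pnorm(Zb[, 1L])
        } else {
          rho <- S_b[1L, 2L] / (sdb[1L] * sdb[2L])
          sgn <- D[, 1L] * D[, 2L]
          out <- numeric(st$n)
          for (sg in c(1, -1)) {
            sel <- sgn == sg
            if (any(sel))
              out[sel] <- pbinorm_vec(Zb[sel, 1L], Zb[sel, 2L], sg * rho)
          }
          out
        }
        if (any(!is.finite(pr))) return(1e10)
        small <- pr < 1e-300
        if (any(small)) { warn_underflow(); pr[small] <- 1e-300 }
        ll <- ll + log(pr)
      } else {
        for (f in seq_len(st$n)) {
          yb <- st$Y[f, ]
          mu_b <- MuB[f, ]
          pr <- if (kb == 3L) {
            dsg <- 1 - 2 * yb
            tryCatch(mnormt::ptriv.nt(0, dsg * tau, dsg * mu_b,
                                      S_b * tcrossprod(dsg)),
                     error = function(e) NA_real_)
          } else {
            lo <- ifelse(yb == 1, tau, -Inf)
            hi <- ifelse(yb == 1, Inf, tau)
            tryCatch(mnormt::sadmvn(lo, hi, mu_b, S_b,
                                    maxpts = 20000 * kb, abseps = 1e-5),
                     error = function(e) NA_real_)
          }
          pr <- as.numeric(pr)
          if (!is.finite(pr)) return(1e10)
          if (pr < 1e-300) { warn_underflow(); pr <- 1e-300 }
          ll[f] <- ll[f] + log(pr)
        }
      }
    }
    total <- total + sum(st$weight * ll)
  }
  -2 * total
}

#' Minus twice the FIML log-likelihood of a dataset
#'
#' Sum of \code{-2 *} family contributions; invariant to family ordering,
#' and additive over dataset replication.
#'
#' @param model A \code{\link{cholesky_model}} with parameter values set.
#' @param ds A \code{\link{twin_dataset}}.
#' @return Numeric -2 log-likelihood.
#' @export
dataset_m2ll <- function(model, ds) {
  prep <- prepare_fiml_data(ds, model)
  fiml_m2ll_prepared(model, prep)
}
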