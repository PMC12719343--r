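# quantity evaluators: a profiled quantity is either a free parameter name
# ("a21", "tau_mdd"), a standardized proportion ("A[mdd]"), or a component
# correlation ("rA[mdd,si]")
parse_quantity <- function(fit_or_model, quantity) {
  m <- if (inherits(fit_or_model, "twin_fit")) fit_or_model$model else fit_or_model
  nm <- model_param_names(m)
  if (quantity %in% nm) {
    return(list(type = "param", name = quantity,
                g = function(mod) model_get_params(mod)[[quantity]],
                domain = c(-Inf, Inf)))
  }
  mt <- regmatches(quantity, regexec("^([ACE])\\[([^]]+)\\]$", quantity))[[1L]]
  if (length(mt)) {
    X <- mt[2L]; v <- mt[3L]
    if (!v %in% m$vars) stop("unknown variable in quantity: ", v)
    return(list(type = "std", name = quantity,
                g = function(mod) standardized_components(mod)$proportions[v, X],
                domain = c(0, 1)))
  }
  mt <- regmatches(quantity,
                   regexec("^r([ACE])\\[([^,]+),([^]]+)\\]$", quantity))[[1L]]
  if (length(mt)) {
    X <- mt[2L]; v1 <- trimws(mt[3L]); v2 <- trimws(mt[4L])
    return(list(type = "corr", name = quantity,
                g = function(mod) component_correlations(mod)[[X]][v1, v2],
                domain = c(-1, 1)))
  }
  stop("cannot parse quantity '", quantity, "': expected a parameter name, ",
       "'A[var]'-style standardized proportion, or 'rA[v1,v2]'-style ",
       "component correlation")
}

#' Profile-likelihood confidence interval
#'
#' Bounds are the values of the quantity at which the profiled -2
#' log-likelihood (re-optimizing all other free parameters) rises by the
#' chi-squared(1) quantile above the minimum (3.841 at the 95% level),
#' located by bracketed bisection. Free parameters are profiled by fixing
#' them; derived quantities (standardized proportions, component
#' correlations) by a quadratic-penalty constrained refit. If the profile
#' reaches the quantity's natural boundary (e.g. 0 for a proportion)
#' before crossing the cutoff, the bound is reported at the boundary and
#' flagged one-sided.
#'
#' @param fit A converged \code{\link{twin_fit}}.
#' @param quantity A free-parameter name (\code{"a21"}), a standardized
#'   proportion (\code{"A[mdd]"}), or a component correlation
#'   (\code{"rA[mdd,si]"}).
#' @param level Confidence level.
#' @param tol Absolute bisection tolerance on the quantity scale.
#' @return List with \code{estimate}, \code{lower}, \code{upper},
#'   \code{level}, and \code{boundary} (logical pair flagging one-sided
#'   boundary bounds).
#' @export
profile_ci <- function(fit, quantity, level = 0.95, tol = 5e-4) {
  stopifnot(inherits(fit, "twin_fit"))
  if (fit$convergence == "failed") stop("cannot profile a failed fit")
  q <- parse_quantity(fit, quantity)
  model <- fit$model
  prep <- prepare_fiml_data(fit$ds, model)
  theta_hat <- model_get_params(model)
  b <- model_param_bounds(model)
  cutoff <- fit$m2ll + stats::qchisq(level, 1)
  ghat <- q$g(model)

  if (q$type == "param") {
    i <- match(q$name, names(theta_hat))
    dom <- c(b$lower[[i]], b$upper[[i]])
    warm <- theta_hat[-i]
    prof <- function(g0) {
      if (length(warm) == 0L) {
        th <- theta_hat; th[i] <- g0
        return(fiml_m2ll_prepared(model_set_params(model, th), prep))
      }
      obj <- function(rest) {
        th <- theta_hat
        th[-i] <- rest
        th[i] <- g0
        fiml_m2ll_prepared(model_set_params(model, th), prep)
      }
      ans <- tryCatch(stats::nlminb(warm, obj, lower = b$lower[-i],
                                    upper = b$upper[-i]),
                      error = function(e) NULL)
      if (is.null(ans)) return(Inf)
      warm <<- ans$par
      ans$objective
    }
  } else {
    dom <- q$domain
    warm <- theta_hat
    lambda <- 1e6
    prof <- function(g0) {
      obj <- function(th) {
        mod <- model_set_params(model, th)
        fiml_m2ll_prepared(mod, prep) + lambda * (q$g(mod) - g0)^2
      }
      ans <- tryCatch(stats::nlminb(warm, obj, lower = b$lower,
                                    upper = b$upper),
                      error = function(e) NULL)
      if (is.null(ans)) return(Inf)
      warm <<- ans$par
      mod <- model_set_params(model, ans$par)
      fiml_m2ll_prepared(mod, prep)
    }
  }

  bound_search <- function(direction) {
    lim <- if (direction < 0) dom[1L] else dom[2L]
    if (!is.finite(lim)) lim <- ghat + direction * max(5, 10 * abs(ghat))
    g_in <- ghat
    step <- max(abs(lim - ghat) / 16, tol)
    g0 <- ghat
    boundary <- FALSE
    repeat {
      g0 <- g0 + direction * step
      if ((direction < 0 && g0 <= lim) || (direction > 0 && g0 >= lim)) {
        g0 <- lim
        if (prof(g0) <= cutoff) { boundary <- TRUE; break }
      }
      if (prof(g0) > cutoff) break
      g_in <- g0
      step <- step * 2
      if (g0 == lim) { boundary <- TRUE; break }
    }
    if (boundary) return(list(bound = lim, boundary = TRUE))
    g_out <- g0
    while (abs(g_out - g_in) > tol) {
      mid <- (g_in + g_out) / 2
      if (prof(mid) > cutoff) g_out <- mid else g_in <- mid
    }
    list(bound = (g_in + g_out) / 2, boundary = FALSE)
  }

  lo <- bound_search(-1)
  hi <- bound_search(+1)
  list(quantity = quantity, estimate = ghat,
       lower = lo$bound, upper = hi$bound, level = level,
       boundary = c(lower = lo$boundary, upper = hi$boundary))
}

#' Non-parametric bootstrap confidence intervals
#'
#' Families are resampled with replacement within zygosity strata
#' (preserving the twin dependence structure and the MZ/DZ balance), the
#' model is refit to each replicate from the original solution, and
#' percentile intervals of the requested standardized quantities are
#' returned. Failed replicates are dropped and counted; a warning is
#' attached if more than 20% fail.
#'
#' @param fit A \code{\link{twin_fit}} (or a \code{cholesky_model}, in
#'   which case \code{ds} must be supplied and the model is first fit).
#' @param ds Dataset (taken from the fit if omitted).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed (required for reproducibility).
#' @param quantities Character vector of quantities (default: standardized
#'   proportions of every component for every variable, e.g.
#'   \code{"A[mdd]"}).
#' @param level Confidence level for the percentile interval.
#' @param restarts Restarts per replicate refit.
#' @return List of class \code{"bootstrap_ci"}: \code{ci} (data.frame with
#'   quantity, estimate, lower, upper), \code{B}, \code{n_failed},
#'   \code{draws}.
#' @export
bootstrap_ci <- function(fit, ds = NULL, B = 1000, seed, quantities = NULL,
                         level = 0.95, restarts = 1) {
  if (missing(seed)) stop("a seed is required")
  if (inherits(fit, "cholesky_model")) {
    stopifnot(!is.null(ds))
    fit <- fit_cholesky(fit, ds, seed = seed)
  }
  ds <- ds %||% fit$ds
  stopifnot(B >= 2)
  if (is.null(quantities)) {
    quantities <- unlist(lapply(fit$model$comp, function(X)
      paste0(X, "[", fit$model$vars, "]")))
  }
  qs <- lapply(quantities, parse_quantity, fit_or_model = fit)
  set.seed(seed)
  zyg <- ds$data$zygosity
  idx_mz <- which(zyg == "MZ")
  idx_dz <- which(zyg == "DZ")
  draws <- matrix(NA_real_, B, length(quantities),
                  dimnames = list(NULL, quantities))
  st <- coef(fit)
  for (b in seq_len(B)) {
    take <- c(sample(idx_mz, length(idx_mz), replace = TRUE),
              sample(idx_dz, length(idx_dz), replace = TRUE))
    dsb <- ds
    dsb$data <- ds$data[take, , drop = FALSE]
    dsb$data$family_id <- sprintf("bs%06d", seq_along(take))
    rownames(dsb$data) <- NULL
    fb <- tryCatch(
      fit_cholesky(fit$model, dsb, restarts = restarts, start = st,
                   label = fit$label),
      error = function(e) NULL)
    if (is.null(fb) || fb$convergence == "failed") next
    draws[b, ] <- vapply(qs, function(q) q$g(fb$model), 0)
  }
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * B)
    warning(sprintf("%d of %d bootstrap replicates failed", n_failed, B))
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- data.frame(
    quantity = quantities,
    estimate = vapply(qs, function(q) q$g(fit$model), 0),
    lower = apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                  probs = pr[1L], type = 1),
    upper = apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                  probs = pr[2L], type = 1),
    stringsAsFactors = FALSE)
  rownames(ci) <- NULL
  structure(list(ci = ci, B = B, n_failed = n_failed, level = level,
                 draws = draws[ok, , drop = FALSE]),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap percentile CIs (%d replicates, %d failed, level %.2f):\n",
              x$B, x$n_failed, x$level))
  print(format(x$ci, digits = digits), row.names = FALSE)
  invisible(x)
}
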