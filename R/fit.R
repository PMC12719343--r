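#' Fit a Cholesky liability model by FIML
#'
#' Maximizes the full-information likelihood over families with a
#' box-constrained quasi-Newton local search (\code{\link[stats]{nlminb}})
#' from multiple perturbed starts; the best objective is kept. Diagonal
#' paths are bounded below at zero for sign identifiability, and binary
#' variables' unit liability variance is enforced exactly by the derived-
#' diagonal reparameterization (see \code{\link{cholesky_model}}).
#'
#' @param model A \code{\link{cholesky_model}} defining free and fixed
#'   parameters.
#' @param ds A \code{\link{twin_dataset}}.
#' @param restarts Number of starts (first from data-driven values, the
#'   rest perturbed by \code{perturb_sd}).
#' @param start Optional named numeric vector overriding the data-driven
#'   starting values.
#' @param seed Optional seed for the start perturbations.
#' @param perturb_sd SD of start perturbations on the path scale.
#' @param control Passed to \code{nlminb} (e.g. \code{eval.max},
#'   \code{rel.tol}).
#' @param label Model label used in comparison tables (default the
#'   component string, e.g. \code{"AE"}).
#' @return An object of class \code{"twin_fit"}: the model with estimates
#'   substituted, \code{m2ll}, \code{n_free_params}, \code{aic} (=
#'   m2ll + 2k), the standardized-component summary, convergence status
#'   (\code{converged}, \code{boundary} or \code{failed}) and the number
#'   of restarts used.
#' @export
fit_cholesky <- function(model, ds, restarts = 10, start = NULL,
                         seed = NULL, perturb_sd = 0.2, control = list(),
                         label = NULL) {
  stopifnot(inherits(model, "cholesky_model"), inherits(ds, "twin_dataset"))
  if (!is.null(seed)) set.seed(seed)
  prep <- prepare_fiml_data(ds, model)
  reset_underflow_flag()
  nm <- model_param_names(model)
  b <- model_param_bounds(model)
  s0 <- start_values(model, ds)
  if (!is.null(start)) s0[names(start)] <- start
  s0 <- pmin(pmax(s0, b$lower), b$upper)

  obj <- function(theta) fiml_m2ll_prepared(model_set_params(model, theta), prep)

  best <- NULL
  n_used <- 0L
  for (r in seq_len(max(1L, restarts))) {
    th <- s0
    if (r > 1L) {
      th <- th + stats::rnorm(length(th), 0, perturb_sd)
      th <- pmin(pmax(th, b$lower), b$upper)
    }
    ans <- tryCatch(
      stats::nlminb(th, obj, lower = b$lower, upper = b$upper,
                    control = utils::modifyList(
                      list(eval.max = 2000L, iter.max = 500L), control)),
      error = function(e) NULL)
    n_used <- n_used + 1L
    if (is.null(ans) || !is.finite(ans$objective) || ans$objective >= 1e10)
      next
    if (is.null(best) || ans$objective < best$objective - 1e-9) best <- ans
  }
  if (is.null(best)) {
    return(structure(list(model = model, ds = ds, m2ll = NA_real_,
                          n_free_params = length(nm), aic = NA_real_,
                          summary = NULL, convergence = "failed",
                          n_restarts_used = n_used,
                          label = label %||% paste(model$comp, collapse = "")),
                     class = "twin_fit"))
  }
  fitted <- model_set_params(model, stats::setNames(best$par, nm))
  on_bound <- any(abs(best$par - b$lower) < 1e-5 & b$lower > -10 + 1e-8) ||
    any(abs(best$par - b$upper) < 1e-5)
  status <- if (on_bound) "boundary" else "converged"
  structure(
    list(model = fitted, ds = ds, m2ll = best$objective,
         n_free_params = length(nm),
         aic = best$objective + 2 * length(nm),
         summary = standardized_components(fitted),
         convergence = status, n_restarts_used = n_used,
         label = label %||% paste(model$comp, collapse = "")),
    class = "twin_fit")
}

# data-driven starting values: thresholds at qnorm(1 - prevalence), means
# and PRS loadings from sample moments, equal-split diagonals, small
# positive off-diagonals
start_values <- function(model, ds) {
  th <- default_start(model)
  nm <- names(th)
  d <- ds$data
  for (v in names(model$tau)) {
    x <- unlist(d[member_cols(v)], use.names = FALSE)
    prev <- mean(x, na.rm = TRUE)
    prev <- min(max(prev, 0.02), 0.98)
    th[paste0("tau_", v)] <- stats::qnorm(1 - prev)
  }
  for (v in names(model$mu)) {
    x <- unlist(d[member_cols(v)], use.names = FALSE)
    i <- match(v, model$vars)
    th[paste0("mu_", v)] <- mean(x, na.rm = TRUE)
    sdv <- stats::sd(x, na.rm = TRUE)
    if (is.finite(sdv) && sdv > 0) {
      k <- sum(vapply(model$comp, function(X) model$free[[X]][i, i], TRUE))
      for (X in model$comp) {
        pn <- paste0(tolower(X), i, i)
        if (pn %in% nm) th[pn] <- sdv / sqrt(max(k, 1))
      }
    }
  }
  offd <- grepl("^[ace][0-9]+$", nm) &
    !nm %in% unlist(lapply(c("a", "c", "e"), function(l)
      paste0(l, seq_len(model$p), seq_len(model$p))))
  th[offd] <- 0.1
  # keep binary rows inside the unit-variance constraint
  m2 <- model_set_params(model, th)
  if (!m2$valid) {
    th[offd] <- 0.01
    sq <- sqrt(1 / max(length(model$comp), 1)) * 0.9
    for (i in which(model$scale == "binary_liability"))
      for (X in model$comp) {
        pn <- paste0(tolower(X), i, i)
        if (pn %in% nm) th[pn] <- sq
      }
  }
  th
}

#' @export
print.twin_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<twin_fit> %s model (%s), -2LL = %s, AIC = %s, k = %d [%s]\n",
              x$label, paste(x$model$vars, collapse = ", "),
              format(x$m2ll, digits = 8), format(x$aic, digits = 8),
              x$n_free_params, x$convergence))
  invisible(x)
}

#' @export
summary.twin_fit <- function(object, digits = 3, ...) {
  print(object)
  if (!is.null(object$summary)) {
    cat("\n")
    print(object$summary, digits = digits)
  }
  cat("\nEstimates:\n")
  print(round(coef(object), digits))
  invisible(object)
}

#' @export
coef.twin_fit <- function(object, ...) model_get_params(object$model)

#' @export
logLik.twin_fit <- function(object, ...) {
  structure(-object$m2ll / 2, df = object$n_free_params,
            class = "logLik")
}

#' @export
confint.twin_fit <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) parm <- names(coef(object))
  out <- t(vapply(parm, function(q) {
    ci <- profile_ci(object, q, level = level)
    c(ci$lower, ci$upper)
  }, numeric(2)))
  colnames(out) <- paste0(format(100 * c((1 - level) / 2,
                                         1 - (1 - level) / 2)), " %")
  out
}

#' @export
simulate.twin_fit <- function(object, nsim = 1, seed = NULL, ...) {
  zc <- zygosity_counts(object$ds)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(n_mz_pairs = zc[["MZ"]], n_dz_pairs = zc[["DZ"]],
                      model = object$model, seed = seed + i - 1L, ...)
    simulate_ace_cohort(cfg)$dataset
  })
}

#' Likelihood-ratio test between nested fits
#'
#' The change in -2 log-likelihood between a full and a nested reduced
#' model is referred to a chi-squared distribution with degrees of freedom
#' equal to the difference in free-parameter counts. A negative change
#' beyond numerical tolerance triggers a refit of the reduced model from
#' the full solution; if it persists, an error is raised.
#'
#' @param full,reduced \code{twin_fit} objects, reduced nested in full.
#' @return One-row data.frame: labels, \code{delta_m2ll}, \code{delta_df},
#'   \code{p}, \code{delta_aic}.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "twin_fit"), inherits(reduced, "twin_fit"))
  if (reduced$n_free_params > full$n_free_params)
    stop("'reduced' has more free parameters than 'full'")
  d <- reduced$m2ll - full$m2ll
  if (is.finite(d) && d < -1e-4) {
    nm_r <- names(coef(reduced))
    st <- coef(full)[intersect(names(coef(full)), nm_r)]
    refit <- fit_cholesky(reduced$model, reduced$ds, restarts = 1,
                          start = st, label = reduced$label)
    if (refit$m2ll - full$m2ll < -1e-4)
      stop("reduced model fits better than full beyond tolerance; ",
           "models are not nested or the full fit failed")
    reduced <- refit
    d <- reduced$m2ll - full$m2ll
  }
  d <- max(d, 0)
  df <- full$n_free_params - reduced$n_free_params
  p <- if (df == 0) 1 else stats::pchisq(d, df, lower.tail = FALSE)
  data.frame(full = full$label, reduced = reduced$label,
             delta_m2ll = d, delta_df = df, p = p,
             delta_aic = reduced$aic - full$aic,
             stringsAsFactors = FALSE)
}

#' Fit a nested model ladder and select the preferred model
#'
#' Fits every model in the ladder (full model first), compares each
#' reduced model to the full by likelihood-ratio test, and selects, among
#' models whose chi-squared change versus the full model is
#' non-significant at \code{alpha}, the one with the lowest AIC; ties are
#' broken toward fewer parameters.
#'
#' @param ladder Named list of nested \code{\link{cholesky_model}}s, full
#'   model first (see \code{\link{model_ladder}}).
#' @param ds A \code{\link{twin_dataset}}.
#' @param alpha Significance level for the chi-squared screen.
#' @param ... Passed to \code{\link{fit_cholesky}}.
#' @return List of class \code{"model_selection"}: \code{best} (a
#'   \code{twin_fit}), \code{comparisons} (data.frame), \code{fits}.
#' @export
select_model <- function(ladder, ds, alpha = 0.05, ...) {
  stopifnot(length(ladder) >= 1L)
  if (is.null(names(ladder)))
    names(ladder) <- vapply(ladder, function(m)
      paste(m$comp, collapse = ""), "")
  fits <- vector("list", length(ladder))
  names(fits) <- names(ladder)
  fits[[1L]] <- fit_cholesky(ladder[[1L]], ds, label = names(ladder)[1L], ...)
  full_par <- if (fits[[1L]]$convergence != "failed") coef(fits[[1L]])
  for (lb in names(ladder)[-1L]) {
    # warm-start nested models from the full solution
    st <- if (!is.null(full_par))
      full_par[intersect(names(full_par), model_param_names(ladder[[lb]]))]
    fits[[lb]] <- fit_cholesky(ladder[[lb]], ds, label = lb, start = st, ...)
  }
  ok <- vapply(fits, function(f) f$convergence != "failed", TRUE)
  if (!any(ok)) stop("no model in the ladder converged")
  fits <- fits[ok]
  full <- fits[[1L]]
  # under tight iteration caps the full model can stall above a nested
  # optimum; re-polish it from the best nested solution (which embeds
  # into the full parameter space with dropped paths at zero)
  if (length(fits) > 1L) {
    m2s <- vapply(fits, `[[`, 0, "m2ll")
    if (min(m2s[-1L]) < full$m2ll - 1e-4) {
      bst <- fits[[which.min(m2s)]]
      st <- coef(full)
      st[] <- 0
      emb <- intersect(names(coef(bst)), names(st))
      st[emb] <- coef(bst)[emb]
      refit <- fit_cholesky(ladder[[1L]], ds, start = st,
                            label = full$label, ...)
      if (!is.na(refit$m2ll) && refit$m2ll < full$m2ll)
        full <- fits[[1L]] <- refit
    }
  }
  comparisons <- if (length(fits) > 1L)
    do.call(rbind, lapply(fits[-1L], function(f)
      likelihood_ratio_test(full, f)))
  else
    data.frame(full = character(), reduced = character(),
               delta_m2ll = numeric(), delta_df = integer(),
               p = numeric(), delta_aic = numeric())
  rownames(comparisons) <- NULL
  pvals <- c(1, if (nrow(comparisons)) comparisons$p)
  elig <- which(pvals >= alpha)
  if (!length(elig)) elig <- 1L
  cand <- fits[elig]
  aics <- vapply(cand, `[[`, 0, "aic")
  kpar <- vapply(cand, `[[`, 0L, "n_free_params")
  best <- cand[[order(round(aics, 8), kpar)[1L]]]
  structure(list(best = best, comparisons = comparisons, fits = fits),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, digits = 3, ...) {
  cat("Model comparison (vs full", x$fits[[1L]]$label, "model):\n")
  tab <- data.frame(model = vapply(x$fits, `[[`, "", "label"),
                    m2ll = vapply(x$fits, `[[`, 0, "m2ll"),
                    k = vapply(x$fits, `[[`, 0L, "n_free_params"),
                    aic = vapply(x$fits, `[[`, 0, "aic"))
    if (nrow(x$comparisons)) {
      tab$delta_m2ll <- c(NA, x$comparisons$delta_m2ll)
      tab$delta_df <- c(NA, x$comparisons$delta_df)
      tab$p <- c(NA, x$comparisons$p)
    }
  print(format(tab, digits = digits), row.names = FALSE)
  cat("Selected:", x$best$label, "\n")
  invisible(x)
}
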