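#' Specify a multivariate Cholesky ACE liability model
#'
#' Each variance component X in {A, C, E} is parameterized by a lower-
#' triangular path matrix L_X, so its contribution to the within-member
#' covariance is L_X L_X'. Cross-twin sharing is fixed by the classical
#' twin design: additive-genetic factors correlate 1.0 across MZ members
#' and 0.5 across DZ members, shared-environment factors correlate 1.0 in
#' both zygosities, and unique-environment factors are uncorrelated.
#'
#' Structural zeros follow from the variable specs: a variable only loads
#' on components it allows, and a latent factor X_j exists only if
#' variable j itself loads on X (its column is removed otherwise). A
#' polygenic score declared \code{components = "A"} therefore has one free
#' path, its own additive diagonal loading.
#'
#' Scale identification for binary (liability-threshold) variables is
#' enforced by reparameterization: the diagonal path of the variable's
#' unique-environment row (or, if E is absent, the last surviving
#' component) is computed as \code{sqrt(1 - s)} where s is the sum of the
#' variable's other squared paths, so the model-implied liability variance
#' is exactly 1. Covariate (definition-variable) effects enter the
#' liability mean with thresholds held fixed, algebraically identical to
#' per-person threshold adjustment.
#'
#' @param variables List of \code{\link{variable_spec}} in model order.
#' @param components Components present in this model (e.g. \code{c("A","E")}
#'   for an AE model). Order is canonicalized to A, C, E.
#' @param start Optional named list of starting values for free parameters
#'   (by parameter name, e.g. \code{a21}, \code{tau_mdd}).
#' @return An object of class \code{"cholesky_model"}.
#' @seealso \code{\link{cholesky_from_components}} to build a model from
#'   target standardized components and component correlations;
#'   \code{\link{fit_cholesky}} to estimate it.
#' @export
cholesky_model <- function(variables, components = c("A", "C", "E"),
                           start = NULL) {
  if (inherits(variables, "variable_spec")) variables <- list(variables)
  names(variables) <- vapply(variables, `[[`, "", "name")
  p <- length(variables)
  comp <- intersect(c("A", "C", "E"), components)
  if (length(comp) == 0L) stop("model must contain at least one component")
  vars <- names(variables)
  scale <- vapply(variables, `[[`, "", "scale")
  allowed <- lapply(variables, `[[`, "components")

  L <- free <- list()
  loads <- sapply(comp, function(X)
    vapply(allowed, function(a) X %in% a, TRUE), simplify = FALSE)
  for (X in comp) {
    Lx <- matrix(0, p, p, dimnames = list(vars, vars))
    fx <- matrix(FALSE, p, p, dimnames = list(vars, vars))
    for (i in seq_len(p)) for (j in seq_len(i))
      if (loads[[X]][i] && loads[[X]][j]) fx[i, j] <- TRUE
    L[[X]] <- Lx
    free[[X]] <- fx
  }

  # derived diagonal for each binary variable: prefer E, then C, then A
  derived <- stats::setNames(rep(NA_character_, p), vars)
  for (i in seq_len(p)) {
    if (scale[i] != "binary_liability") next
    for (X in c("E", "C", "A")) {
      if (X %in% comp && loads[[X]][i]) { derived[i] <- X; break }
    }
    if (is.na(derived[i]))
      stop("binary variable '", vars[i], "' loads on no component in the model")
    free[[derived[i]]][i, i] <- FALSE
  }

  binary <- scale == "binary_liability"
  tau <- stats::setNames(rep(0, sum(binary)), vars[binary])
  mu <- stats::setNames(rep(0, sum(!binary)), vars[!binary])

  covs <- unlist(lapply(variables, function(v)
    if (length(v$covariates)) paste(v$name, v$covariates, sep = ".") else NULL))
  beta <- if (length(covs)) {
    parts <- strsplit(covs, ".", fixed = TRUE)
    data.frame(variable = vapply(parts, `[[`, "", 1L),
               covariate = vapply(parts, `[[`, "", 2L),
               value = 0, stringsAsFactors = FALSE)
  } else {
    data.frame(variable = character(), covariate = character(),
               value = numeric(), stringsAsFactors = FALSE)
  }

  m <- structure(
    list(variables = variables, vars = vars, p = p, scale = scale,
         allowed = allowed, comp = comp, L = L, free = free,
         derived = derived, tau = tau, mu = mu, beta = beta,
         sharing = c(rA_MZ = 1, rA_DZ = 0.5, rC = 1, rE = 0),
         valid = TRUE),
    class = "cholesky_model")
  m <- model_set_params(m, default_start(m))
  if (!is.null(start)) {
    th <- model_get_params(m)
    th[names(start)] <- unlist(start)
    m <- model_set_params(m, th)
  }
  m
}

# reasonable interior defaults: equal split of unit variance over loading
# components for binary variables, unit diagonal for continuous
default_start <- function(m) {
  nm <- model_param_names(m)
  th <- stats::setNames(rep(0, length(nm)), nm)
  for (i in seq_len(m$p)) {
    k <- sum(vapply(m$comp, function(X) m$free[[X]][i, i] ||
                      identical(m$derived[[i]], X), TRUE))
    val <- if (m$scale[i] == "binary_liability") sqrt(1 / max(k, 1)) else 1
    for (X in m$comp) {
      pn <- paste0(tolower(X), i, i)
      if (pn %in% nm) th[pn] <- val
    }
  }
  th
}

#' @export
print.cholesky_model <- function(x, ...) {
  cat(sprintf("<cholesky_model> %s model, %d variables (%s), %d free parameters\n",
              paste(x$comp, collapse = ""), x$p,
              paste(x$vars, collapse = ", "), length(model_param_names(x))))
  invisible(x)
}

#' Free-parameter names of a Cholesky model
#'
#' Path entries are named by component and variable indices (\code{a21} is
#' the additive path from factor 1 to variable 2), thresholds
#' \code{tau_<variable>}, continuous means \code{mu_<variable>}, covariate
#' coefficients \code{b_<variable>_<covariate>}.
#'
#' @param m A \code{cholesky_model}.
#' @return Character vector in packing order.
#' @export
model_param_names <- function(m) {
  out <- character()
  for (X in m$comp) {
    idx <- which(m$free[[X]], arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
      out <- c(out, paste0(tolower(X), idx[, 1L], idx[, 2L]))
    }
  }
  c(out,
    if (length(m$tau)) paste0("tau_", names(m$tau)),
    if (length(m$mu)) paste0("mu_", names(m$mu)),
    if (nrow(m$beta)) paste0("b_", m$beta$variable, "_", m$beta$covariate))
}

#' Extract the free-parameter vector
#' @param m A \code{cholesky_model}.
#' @return Named numeric vector.
#' @export
model_get_params <- function(m) {
  out <- numeric()
  for (X in m$comp) {
    idx <- which(m$free[[X]], arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
      out <- c(out, m$L[[X]][idx])
    }
  }
  out <- c(out, unname(m$tau), unname(m$mu), m$beta$value)
  stats::setNames(out, model_param_names(m))
}

#' Substitute a free-parameter vector into a model
#'
#' Derived diagonals for binary variables are recomputed so their total
#' liability variance is 1; if a variable's other squared paths exceed
#' 1 - 1e-6 the model is marked invalid (\code{m$valid = FALSE}), which the
#' fitting objective treats as an excluded region.
#'
#' @param m A \code{cholesky_model}.
#' @param theta Numeric vector in \code{\link{model_param_names}} order.
#' @return The updated model.
#' @export
model_set_params <- function(m, theta) {
  nm <- model_param_names(m)
  stopifnot(length(theta) == length(nm))
  k <- 0L
  for (X in m$comp) {
    idx <- which(m$free[[X]], arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
      m$L[[X]][idx] <- theta[k + seq_len(nrow(idx))]
      k <- k + nrow(idx)
    }
  }
  if (length(m$tau)) { m$tau[] <- theta[k + seq_along(m$tau)]; k <- k + length(m$tau) }
  if (length(m$mu)) { m$mu[] <- theta[k + seq_along(m$mu)]; k <- k + length(m$mu) }
  if (nrow(m$beta)) { m$beta$value <- theta[k + seq_len(nrow(m$beta))] }
  m$valid <- TRUE
  for (i in seq_len(m$p)) {
    X <- m$derived[[i]]
    if (is.na(X)) next
    s <- 0
    for (Y in m$comp) {
      row2 <- m$L[[Y]][i, ]^2
      if (Y == X) row2[i] <- 0
      s <- s + sum(row2)
    }
    rad <- 1 - s
    if (rad < 1e-6) { rad <- 1e-6; m$valid <- FALSE }
    m$L[[X]][i, i] <- sqrt(rad)
  }
  m
}

# box bounds for the packed parameter vector (diagonal paths >= 0 for sign
# identifiability)
model_param_bounds <- function(m) {
  nm <- model_param_names(m)
  lo <- stats::setNames(rep(-10, length(nm)), nm)
  hi <- stats::setNames(rep(10, length(nm)), nm)
  for (X in m$comp) {
    dn <- paste0(tolower(X), seq_len(m$p), seq_len(m$p))
    lo[nm %in% dn] <- 0
  }
  lo[startsWith(nm, "tau_")] <- -6
  hi[startsWith(nm, "tau_")] <- 6
  lo[startsWith(nm, "mu_")] <- -30
  hi[startsWith(nm, "mu_")] <- 30
  list(lower = lo, upper = hi)
}

# within-member and cross-twin covariance blocks implied by the paths
model_implied <- function(m) {
  p <- m$p
  SA <- if ("A" %in% m$comp) tcrossprod(m$L[["A"]]) else matrix(0, p, p)
  SC <- if ("C" %in% m$comp) tcrossprod(m$L[["C"]]) else matrix(0, p, p)
  SE <- if ("E" %in% m$comp) tcrossprod(m$L[["E"]]) else matrix(0, p, p)
  list(SA = SA, SC = SC, SE = SE,
       Sw = SA + SC + SE,
       Sx_MZ = m$sharing[["rA_MZ"]] * SA + m$sharing[["rC"]] * SC,
       Sx_DZ = m$sharing[["rA_DZ"]] * SA + m$sharing[["rC"]] * SC)
}

#' Model-implied moments for a twin pair
#'
#' Assembles the 2p-dimensional mean vector and covariance matrix of the
#' two members' liabilities/values: within-member covariance
#' L_A L_A' + L_C L_C' + L_E L_E', cross-twin covariance
#' rA_z L_A L_A' + L_C L_C' with rA_z = 1 (MZ) or 0.5 (DZ). Means are the
#' covariate shifts (plus the free mean for continuous variables);
#' thresholds are reported separately.
#'
#' @param m A \code{cholesky_model}.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @param covariates Optional list with elements \code{t1} and \code{t2},
#'   each a named numeric vector of covariate values for that member.
#' @return List with \code{mean} (length 2p), \code{cov} (2p x 2p),
#'   \code{thresholds} (length 2p, NA for continuous coordinates), and the
#'   within/cross blocks \code{Sw}, \code{Sx}. Coordinate order is member 1
#'   variables then member 2 variables.
#' @export
expected_moments <- function(m, zygosity, covariates = NULL) {
  if (!zygosity %in% c("MZ", "DZ")) stop("unknown zygosity: ", zygosity)
  imp <- model_implied(m)
  Sx <- if (zygosity == "MZ") imp$Sx_MZ else imp$Sx_DZ
  cov <- rbind(cbind(imp$Sw, Sx), cbind(Sx, imp$Sw))
  mu1 <- member_mean(m, if (is.null(covariates)) NULL else covariates$t1)
  mu2 <- member_mean(m, if (is.null(covariates)) NULL else covariates$t2)
  thr <- rep(NA_real_, m$p)
  thr[match(names(m$tau), m$vars)] <- m$tau
  nm <- c(paste0(m$vars, "_t1"), paste0(m$vars, "_t2"))
  dimnames(cov) <- list(nm, nm)
  list(mean = stats::setNames(c(mu1, mu2), nm), cov = cov,
       thresholds = stats::setNames(c(thr, thr), nm),
       Sw = imp$Sw, Sx = Sx)
}

member_mean <- function(m, x) {
  mu <- rep(0, m$p)
  mu[match(names(m$mu), m$vars)] <- m$mu
  if (nrow(m$beta)) {
    for (r in seq_len(nrow(m$beta))) {
      i <- match(m$beta$variable[r], m$vars)
      xv <- if (is.null(x)) 0 else x[[m$beta$covariate[r]]]
      if (is.null(xv) || is.na(xv)) xv <- 0
      mu[i] <- mu[i] + m$beta$value[r] * xv
    }
  }
  mu
}

#' Standardized variance components
#'
#' For variable i the standardized component is the sum of its squared
#' paths in that component divided by its total model-implied variance, so
#' per variable A + C + E = 1.
#'
#' @param m A \code{cholesky_model}.
#' @return A \code{"component_summary"}: matrix \code{proportions} (p x 3,
#'   columns A, C, E; components absent from the model contribute 0) plus
#'   the total variances.
#' @export
standardized_components <- function(m) {
  imp <- model_implied(m)
  v <- diag(imp$Sw)
  if (any(v <= 0)) stop("zero total variance for variable(s): ",
                        paste(m$vars[v <= 0], collapse = ", "))
  pr <- cbind(A = diag(imp$SA) / v, C = diag(imp$SC) / v, E = diag(imp$SE) / v)
  rownames(pr) <- m$vars
  structure(list(proportions = pr, total_variance = v,
                 correlations = component_correlations(m)),
            class = "component_summary")
}

#' Component (genetic/environmental) correlation matrices
#'
#' rA_ij = (L_A L_A')_ij / sqrt((L_A L_A')_ii (L_A L_A')_jj), and
#' analogously rC, rE. Entries involving a variable with no variance in
#' the component are undefined and reported as NA (not zero); defined
#' diagonal entries are exactly 1.
#'
#' @param m A \code{cholesky_model}.
#' @return Named list of p x p matrices for each component in the model.
#' @export
component_correlations <- function(m) {
  imp <- model_implied(m)
  out <- list()
  for (X in m$comp) {
    S <- imp[[paste0("S", X)]]
    d <- diag(S)
    R <- matrix(NA_real_, m$p, m$p, dimnames = list(m$vars, m$vars))
    ok <- d > 1e-12
    if (any(ok)) {
      sub <- S[ok, ok, drop = FALSE]
      R[ok, ok] <- sub / tcrossprod(sqrt(d[ok]))
      diag(R)[ok] <- 1
    }
    out[[X]] <- R
  }
  out
}

#' @export
print.component_summary <- function(x, digits = 3, ...) {
  cat("Standardized variance components:\n")
  print(round(x$proportions, digits))
  for (X in names(x$correlations)) {
    cat(sprintf("\nr%s (component correlations):\n", X))
    print(round(x$correlations[[X]], digits))
  }
  invisible(x)
}

#' Build a Cholesky model from target components and correlations
#'
#' Convenience constructor (used notably to define generating truths for
#' simulation): given each variable's standardized variance decomposition
#' and the component correlation matrices, the implied component
#' covariance matrices are assembled and factored into lower-triangular
#' paths. Variables with zero variance in a component get zero rows and
#' columns in that factor.
#'
#' @param variables List of \code{\link{variable_spec}}.
#' @param proportions p x 3 matrix (columns A, C, E) of standardized
#'   components; each row must sum to 1 for binary variables.
#' @param corr Named list of component correlation matrices (entries
#'   ignored where a variable has zero variance in the component; identity
#'   assumed if a component's matrix is missing).
#' @param total_variance Per-variable total variance (default 1).
#' @param components Components of the resulting model (default those with
#'   any nonzero proportion).
#' @return A \code{cholesky_model} whose current values reproduce the
#'   targets.
#' @export
cholesky_from_components <- function(variables, proportions, corr = list(),
                                     total_variance = 1,
                                     components = NULL) {
  if (inherits(variables, "variable_spec")) variables <- list(variables)
  p <- length(variables)
  stopifnot(nrow(proportions) == p)
  colnames(proportions) <- toupper(colnames(proportions))
  if (is.null(components))
    components <- c("A", "C", "E")[colSums(abs(proportions)) > 0]
  total_variance <- rep_len(total_variance, p)
  m <- cholesky_model(variables, components = components)
  for (X in components) {
    vx <- proportions[, X] * total_variance
    R <- corr[[X]]
    if (is.null(R)) R <- diag(p)
    S <- tcrossprod(sqrt(vx)) * R
    S[vx == 0, ] <- 0
    S[, vx == 0] <- 0
    diag(S) <- vx
    m$L[[X]] <- chol_psd(S)
    dimnames(m$L[[X]]) <- list(m$vars, m$vars)
  }
  # re-pack so derived diagonals and validity flags are consistent
  model_set_params(m, model_get_params(m))
}

# lower-triangular factor of a PSD matrix that may have zero rows/columns
chol_psd <- function(S, tol = 1e-10) {
  p <- nrow(S)
  L <- matrix(0, p, p)
  act <- which(diag(S) > tol)
  if (length(act)) {
    sub <- S[act, act, drop = FALSE]
    ev <- eigen(sub, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("component covariance matrix is not positive semi-definite ",
           "(min eigenvalue ", format(min(ev)), ")")
    sub <- sub + diag(1e-10, nrow(sub))
    L[act, act] <- t(chol(sub))
  }
  L
}

#' Drop a variance component from a model
#'
#' Fixes every path of the component to zero for variables that allow an
#' alternative component (variables whose only allowed component is the
#' dropped one, such as a polygenic score with components = "A" when
#' dropping A, retain their loadings).
#'
#' @param m A \code{cholesky_model}.
#' @param component \code{"A"}, \code{"C"} or \code{"E"}.
#' @return The reduced model (free parameters removed, values zeroed).
#' @export
drop_component <- function(m, component) {
  stopifnot(component %in% c("A", "C", "E"))
  if (!component %in% m$comp) return(m)
  keep <- vapply(seq_len(m$p), function(i)
    identical(m$allowed[[i]], component) ||
      (length(m$allowed[[i]]) == 1L && m$allowed[[i]] == component), TRUE)
  drop_idx <- which(!keep)
  m$free[[component]][drop_idx, ] <- FALSE
  m$free[[component]][, drop_idx] <- FALSE
  m$L[[component]][drop_idx, ] <- 0
  m$L[[component]][, drop_idx] <- 0
  # a dropped derived diagonal must migrate to a surviving component
  for (i in drop_idx) {
    if (identical(m$derived[[i]], component)) {
      alt <- intersect(c("E", "C", "A"), setdiff(m$comp, component))
      alt <- alt[vapply(alt, function(X) X %in% m$allowed[[i]], TRUE)]
      if (!length(alt))
        stop("variable '", m$vars[i], "' would retain no component")
      m$derived[i] <- alt[1L]
      m$free[[alt[1L]]][i, i] <- FALSE
    }
  }
  if (all(!m$free[[component]]) && all(m$L[[component]] == 0) &&
      !any(m$derived == component, na.rm = TRUE)) {
    m$comp <- setdiff(m$comp, component)
    m$L[[component]] <- NULL
    m$free[[component]] <- NULL
  }
  model_set_params(m, model_get_params(m))
}

#' Fix individual paths to a value
#'
#' @param m A \code{cholesky_model}.
#' @param component Component letter.
#' @param entries List of integer pairs \code{c(i, j)} (row = variable,
#'   column = factor).
#' @param value Fixed value (default 0).
#' @return The updated model.
#' @export
fix_paths <- function(m, component, entries, value = 0) {
  for (e in entries) {
    m$free[[component]][e[1L], e[2L]] <- FALSE
    m$L[[component]][e[1L], e[2L]] <- value
  }
  model_set_params(m, model_get_params(m))
}

#' Standard nested model ladder
#'
#' From a full model, builds the classical-twin-design comparison ladder:
#' ACE, AE, CE, E (whichever are reachable from the full model's
#' components). Dropping A retains the loadings of pure-A variables
#' (polygenic scores), so e.g. the CE model for a trivariate
#' PRS/diagnosis/item analysis removes the five free genetic paths other
#' than the PRS's own loading.
#'
#' @param full A \code{cholesky_model}.
#' @return Named list of nested models, full model first.
#' @export
model_ladder <- function(full) {
  out <- list()
  lab <- paste(full$comp, collapse = "")
  out[[lab]] <- full
  if (all(c("A", "C") %in% full$comp)) {
    out[["AE"]] <- drop_component(full, "C")
    out[["CE"]] <- drop_component(full, "A")
    out[["E"]] <- drop_component(out[["AE"]], "A")
  } else if ("A" %in% full$comp) {
    out[["E"]] <- drop_component(full, "A")
  } else if ("C" %in% full$comp) {
    out[["E"]] <- drop_component(full, "C")
  }
  out
}
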