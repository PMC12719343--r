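# ---- pairwise mixed-type correlations over individuals --------------------

# two-step polyserial: threshold from the binary margin, correlation by ML
# of the conditional response probability given the standardized score
polyserial_ml <- function(x, y, level = 0.95) {
  z <- (x - mean(x)) / stats::sd(x)
  tau <- stats::qnorm(1 - mean(y))
  ll <- function(r) {
    p1 <- stats::pnorm((r * z - tau) / sqrt(1 - r^2))
    sum(y * log(pmax(p1, 1e-300)) + (1 - y) * log(pmax(1 - p1, 1e-300)))
  }
  opt <- stats::optimize(ll, c(-0.999, 0.999), maximum = TRUE)
  ci <- profile_ci_1d(ll, opt$maximum, opt$objective, level)
  list(r = opt$maximum, ci = ci)
}

# two-step tetrachoric: thresholds from the margins, correlation by ML on
# the 2x2 pattern counts
tetrachoric_ml <- function(y1, y2, level = 0.95) {
  t1 <- stats::qnorm(1 - mean(y1))
  t2 <- stats::qnorm(1 - mean(y2))
  n <- table(factor(y1, 0:1), factor(y2, 0:1))
  ll <- function(r) {
    S <- matrix(c(1, r, r, 1), 2)
    s <- 0
    for (a in 0:1) for (b in 0:1) {
      if (n[a + 1L, b + 1L] == 0) next
      lo <- c(if (a == 1) t1 else -Inf, if (b == 1) t2 else -Inf)
      hi <- c(if (a == 1) Inf else t1, if (b == 1) Inf else t2)
      s <- s + n[a + 1L, b + 1L] *
        log(max(mnormt::biv.nt.prob(0, lo, hi, c(0, 0), S), 1e-300))
    }
    s
  }
  opt <- stats::optimize(ll, c(-0.999, 0.999), maximum = TRUE)
  ci <- profile_ci_1d(ll, opt$maximum, opt$objective, level)
  list(r = opt$maximum, ci = ci)
}

# one-parameter profile interval: where 2*(llmax - ll) crosses chisq(1)
profile_ci_1d <- function(ll, rhat, llmax, level) {
  cut <- stats::qchisq(level, 1) / 2
  h <- function(r) llmax - ll(r) - cut
  vapply(c(-1, 1), function(dir) {
    lim <- dir * 0.999
    if (h(lim) < 0) return(dir)  # boundary
    tryCatch(stats::uniroot(h, sort(c(rhat, lim)), tol = 1e-4)$root,
             error = function(e) NA_real_)
  }, 0)
}

#' FIML mixed-type correlation matrix
#'
#' Pairwise correlations over individuals (twin members stacked), each
#' computed from all individuals with both values available: Pearson for
#' continuous-continuous, polyserial (two-step ML) for continuous-binary,
#' tetrachoric (two-step ML) for binary-binary, so binary variables are
#' correlated on the liability scale. Entries with fewer than 10 joint
#' observations are flagged and left NA.
#'
#' @param ds A \code{\link{twin_dataset}}.
#' @param variables Variables to include (default: all phenotypes plus
#'   covariates, sex treated as binary and age as continuous).
#' @param level Confidence level for the per-entry intervals.
#' @return An object of class \code{"fiml_cormat"}: matrices \code{r},
#'   \code{lower}, \code{upper}, \code{method}, \code{n}.
#' @export
fiml_correlation_matrix <- function(ds, variables = NULL, level = 0.95) {
  scales <- vapply(ds$variables, `[[`, "", "scale")
  if (is.null(variables)) {
    variables <- names(ds$variables)
    if ("sex" %in% ds$covariates) {
      variables <- c(variables, "sex")
      scales <- c(scales, sex = "binary_liability")
    }
    if ("age" %in% ds$covariates) {
      variables <- c(variables, "age")
      scales <- c(scales, age = "continuous")
    }
  } else {
    extra <- setdiff(variables, names(scales))
    for (v in extra)
      scales[v] <- if (v == "sex") "binary_liability" else "continuous"
  }
  if (length(variables) < 2L) stop("need at least 2 variables")
  # stack members into an individual-level matrix
  long <- sapply(variables, function(v)
    unlist(ds$data[member_cols(v)], use.names = FALSE))
  p <- length(variables)
  r <- lo <- hi <- nmat <- matrix(NA_real_, p, p,
                                  dimnames = list(variables, variables))
  meth <- matrix(NA_character_, p, p, dimnames = list(variables, variables))
  diag(r) <- 1; diag(lo) <- 1; diag(hi) <- 1
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    xi <- long[, i]; xj <- long[, j]
    ok <- !is.na(xi) & !is.na(xj)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    bi <- scales[[variables[i]]] == "binary_liability"
    bj <- scales[[variables[j]]] == "binary_liability"
    meth[i, j] <- meth[j, i] <-
      if (bi && bj) "tetrachoric" else if (bi || bj) "polyserial" else "pearson"
    if (sum(ok) < 10) next  # low-n entry left NA
    xi <- xi[ok]; xj <- xj[ok]
    est <- if (!bi && !bj) {
      rr <- stats::cor(xi, xj)
      z <- atanh(min(max(rr, -0.9999), 0.9999))
      se <- 1 / sqrt(sum(ok) - 3)
      q <- stats::qnorm(1 - (1 - level) / 2)
      list(r = rr, ci = tanh(c(z - q * se, z + q * se)))
    } else if (bi && bj) {
      if (length(unique(xi)) < 2 || length(unique(xj)) < 2) next
      tetrachoric_ml(xi, xj, level)
    } else {
      y <- if (bi) xi else xj
      x <- if (bi) xj else xi
      if (length(unique(y)) < 2 || stats::sd(x) == 0) next
      polyserial_ml(x, y, level)
    }
    r[i, j] <- r[j, i] <- est$r
    lo[i, j] <- lo[j, i] <- est$ci[1L]
    hi[i, j] <- hi[j, i] <- est$ci[2L]
  }
  structure(list(r = r, lower = lo, upper = hi, method = meth, n = nmat),
            class = "fiml_cormat")
}

#' @export
print.fiml_cormat <- function(x, digits = 2, ...) {
  cat("FIML pairwise correlations (Pearson / polyserial / tetrachoric):\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Yates-corrected chi-squared test for a 2x2 table
#'
#' statistic = n (max(|ad - bc| - n/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d)),
#' the continuity-corrected Pearson chi-squared with the correction
#' clamped at zero (the conservative convention), df = 1.
#'
#' @param t 2x2 matrix of counts (rows = group, columns = outcome).
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
yates_chi_square <- function(t) {
  t <- as.matrix(t)
  stopifnot(all(dim(t) == 2L), all(t >= 0), sum(t) >= 1)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("zero marginal: chi-squared undefined")
  n <- sum(t)
  stat <- n * max(abs(a * d - b * c) - n / 2, 0)^2 / prod(marg)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Cramer's V effect size
#'
#' V = sqrt(statistic / (n min(r-1, c-1))), in [0, 1]. Labels follow the
#' conventional anchors 0.1 / 0.3 / 0.5 for small / medium / large with
#' half-open bins; values below 0.1 are labelled "negligible".
#'
#' @param statistic Chi-squared statistic (uncorrected or corrected).
#' @param n Total count.
#' @param dims Table dimensions (default 2x2).
#' @return List with \code{v} and \code{label}.
#' @export
cramers_v <- function(statistic, n, dims = c(2L, 2L)) {
  stopifnot(statistic >= 0, n >= 1)
  v <- sqrt(statistic / (n * min(dims - 1L)))
  v <- min(v, 1)
  label <- if (v < 0.1) "negligible" else if (v < 0.3) "small"
           else if (v < 0.5) "medium" else "large"
  list(v = v, label = label)
}
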