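# sufficient statistics for one binary variable: complete-pair pattern
# counts per zygosity plus singleton counts per (zygosity, member, value)
pair_pattern_counts <- function(ds, variable) {
  y1 <- ds$data[[paste0(variable, "_t1")]]
  y2 <- ds$data[[paste0(variable, "_t2")]]
  zyg <- ds$data$zygosity
  out <- list()
  for (z in c("MZ", "DZ")) {
    sel <- zyg == z
    cc <- sel & !is.na(y1) & !is.na(y2)
    pairs <- matrix(0, 2, 2, dimnames = list(y1 = 0:1, y2 = 0:1))
    for (a in 0:1) for (b in 0:1)
      pairs[a + 1L, b + 1L] <- sum(cc & y1 == a & y2 == b)
    s1 <- sel & !is.na(y1) & is.na(y2)
    s2 <- sel & is.na(y1) & !is.na(y2)
    out[[z]] <- list(
      pairs = pairs,
      single = list(t1 = c(`0` = sum(s1 & y1 == 0), `1` = sum(s1 & y1 == 1)),
                    t2 = c(`0` = sum(s2 & y2 == 0), `1` = sum(s2 & y2 == 1))))
  }
  out
}

# -2LL of the bivariate-probit pair model; taus is a 2x2 matrix
# [zygosity x member], rho a length-2 vector (MZ, DZ)
pair_model_m2ll <- function(counts, taus, rho) {
  ll <- 0
  for (zi in 1:2) {
    z <- c("MZ", "DZ")[zi]
    r <- rho[zi]
    if (abs(r) > 0.9999) r <- sign(r) * 0.9999
    S <- matrix(c(1, r, r, 1), 2, 2)
    cp <- counts[[z]]$pairs
    for (a in 0:1) for (b in 0:1) {
      n <- cp[a + 1L, b + 1L]
      if (n == 0) next
      lo <- c(if (a == 1) taus[zi, 1L] else -Inf,
              if (b == 1) taus[zi, 2L] else -Inf)
      hi <- c(if (a == 1) Inf else taus[zi, 1L],
              if (b == 1) Inf else taus[zi, 2L])
      p <- mnormt::biv.nt.prob(0, lo, hi, c(0, 0), S)
      ll <- ll + n * log(max(p, 1e-300))
    }
    for (mi in 1:2) {
      s <- counts[[z]]$single[[mi]]
      p1 <- stats::pnorm(taus[zi, mi], lower.tail = FALSE)
      ll <- ll + s[["1"]] * log(max(p1, 1e-300)) +
        s[["0"]] * log(max(1 - p1, 1e-300))
    }
  }
  -2 * ll
}

fit_pair_model <- function(counts, homogeneous) {
  prev <- local({
    tot <- n1 <- 0
    for (z in c("MZ", "DZ")) {
      tot <- tot + sum(counts[[z]]$pairs) * 2 +
        sum(unlist(counts[[z]]$single))
      n1 <- n1 + sum(counts[[z]]$pairs[2L, ]) +
        sum(counts[[z]]$pairs[, 2L]) +
        counts[[z]]$single$t1[["1"]] + counts[[z]]$single$t2[["1"]]
    }
    min(max(n1 / tot, 0.02), 0.98)
  })
  tau0 <- stats::qnorm(1 - prev)
  if (homogeneous) {
    par0 <- c(tau0, 0.3, 0.3)
    obj <- function(p) pair_model_m2ll(counts,
                                       matrix(p[1L], 2, 2), p[2:3])
    lower <- c(-4, -0.999, -0.999); upper <- c(4, 0.999, 0.999)
  } else {
    par0 <- c(rep(tau0, 4), 0.3, 0.3)
    obj <- function(p) pair_model_m2ll(counts,
                                       matrix(p[1:4], 2, 2, byrow = TRUE),
                                       p[5:6])
    lower <- c(rep(-4, 4), -0.999, -0.999)
    upper <- c(rep(4, 4), 0.999, 0.999)
  }
  ans <- stats::nlminb(par0, obj, lower = lower, upper = upper)
  list(par = ans$par, m2ll = ans$objective, k = length(par0),
       objective_fn = obj, lower = lower, upper = upper)
}

#' Test threshold homogeneity of a binary variable
#'
#' Twin models predict the same threshold (prevalence on the liability
#' scale) for all four measurement cells: MZ twin 1, MZ twin 2, DZ twin 1
#' and DZ twin 2. The saturated model frees one threshold per cell plus a
#' pairwise liability correlation per zygosity; the homogeneity model
#' constrains a single shared threshold, giving a 3-degree-of-freedom
#' likelihood-ratio test.
#'
#' @param ds A \code{\link{twin_dataset}}.
#' @param variable A binary variable name; both zygosities and all four
#'   cells must have observations.
#' @return One-row comparison data.frame (as
#'   \code{\link{likelihood_ratio_test}}), with the two fitted -2LLs as
#'   attributes.
#' @export
test_threshold_homogeneity <- function(ds, variable) {
  v <- ds$variables[[variable]]
  if (is.null(v) || v$scale != "binary_liability")
    stop("'", variable, "' is not a binary variable in the dataset")
  counts <- pair_pattern_counts(ds, variable)
  for (z in c("MZ", "DZ")) for (mi in 1:2) {
    n_cell <- sum(counts[[z]]$pairs) + sum(counts[[z]]$single[[mi]])
    if (n_cell == 0)
      stop("no observations for cell ", z, " twin ", mi,
           " of variable '", variable, "'")
  }
  sat <- fit_pair_model(counts, homogeneous = FALSE)
  hom <- fit_pair_model(counts, homogeneous = TRUE)
  d <- max(hom$m2ll - sat$m2ll, 0)
  df <- sat$k - hom$k
  structure(
    data.frame(full = "saturated thresholds",
               reduced = "threshold homogeneity",
               delta_m2ll = d, delta_df = df,
               p = stats::pchisq(d, df, lower.tail = FALSE),
               delta_aic = (hom$m2ll + 2 * hom$k) - (sat$m2ll + 2 * sat$k),
               stringsAsFactors = FALSE),
    m2ll_saturated = sat$m2ll, m2ll_homogeneous = hom$m2ll)
}

#' Twin-pair correlation of one variable
#'
#' For binary variables, the tetrachoric twin-pair correlation is
#' estimated by FIML under threshold homogeneity (one threshold shared by
#' all four zygosity-by-member cells; separate pair correlations per
#' zygosity), with a profile-likelihood confidence interval. Incomplete
#' pairs contribute to the threshold. For continuous variables, the
#' Pearson correlation over complete pairs with a Fisher-z interval.
#'
#' @param ds A \code{\link{twin_dataset}}.
#' @param variable Variable name.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @param level Confidence level.
#' @return A \code{"correlation_estimate"}: value, ci, method,
#'   n_effective (informative pairs), flags.
#' @export
twin_pair_correlation <- function(ds, variable, zygosity, level = 0.95) {
  stopifnot(zygosity %in% c("MZ", "DZ"))
  v <- ds$variables[[variable]]
  if (is.null(v)) stop("unknown variable: ", variable)
  y1 <- ds$data[[paste0(variable, "_t1")]]
  y2 <- ds$data[[paste0(variable, "_t2")]]
  sel <- ds$data$zygosity == zygosity & !is.na(y1) & !is.na(y2)
  n_eff <- sum(sel)
  flags <- character()
  if (n_eff < 10) flags <- c(flags, "low_n")

  if (v$scale == "continuous") {
    if (n_eff < 3)
      return(correlation_estimate(NA, c(NA, NA), "pearson", n_eff,
                                  c(flags, "undefined")))
    r <- stats::cor(y1[sel], y2[sel])
    z <- atanh(r)
    se <- 1 / sqrt(n_eff - 3)
    q <- stats::qnorm(1 - (1 - level) / 2)
    return(correlation_estimate(r, tanh(c(z - q * se, z + q * se)),
                                "pearson", n_eff, flags))
  }

  for (mi in 1:2) {
    ym <- if (mi == 1) y1 else y2
    obs <- ym[ds$data$zygosity == zygosity & !is.na(ym)]
    if (length(unique(obs)) < 2)
      return(correlation_estimate(NA, c(NA, NA), "tetrachoric", n_eff,
                                  c(flags, "undefined")))
  }
  counts <- pair_pattern_counts(ds, variable)
  hom <- fit_pair_model(counts, homogeneous = TRUE)
  zi <- if (zygosity == "MZ") 2L else 3L
  est <- hom$par[zi]
  if (abs(est) > 0.995) flags <- c(flags, "boundary")
  # profile the zygosity's correlation, re-optimizing threshold + other rho
  prof <- function(r0) {
    obj <- function(p) {
      full <- hom$par
      full[-zi] <- p
      full[zi] <- r0
      pair_model_m2ll(counts, matrix(full[1L], 2, 2), full[2:3])
    }
    stats::nlminb(hom$par[-zi], obj, lower = hom$lower[-zi],
                  upper = hom$upper[-zi])$objective
  }
  cut <- hom$m2ll + stats::qchisq(level, 1)
  ci <- vapply(c(-1, 1), function(dir) {
    g_in <- est
    g_out <- if (dir < 0) -0.999 else 0.999
    if (prof(g_out) <= cut) return(sign(dir))
    while (abs(g_out - g_in) > 1e-3) {
      mid <- (g_in + g_out) / 2
      if (prof(mid) > cut) g_out <- mid else g_in <- mid
    }
    (g_in + g_out) / 2
  }, 0)
  correlation_estimate(est, ci, "tetrachoric", n_eff, flags)
}

correlation_estimate <- function(value, ci, method, n_effective,
                                 flags = character()) {
  value <- as.numeric(value)
  ci <- as.numeric(ci)
  structure(list(value = value, ci = ci, method = method,
                 n_effective = n_effective, flags = flags),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s correlation: %s (%s, %s), n = %d%s\n", x$method,
              format(x$value, digits = digits),
              format(x$ci[1L], digits = digits),
              format(x$ci[2L], digits = digits),
              x$n_effective,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
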