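#' Configuration for a synthetic twin cohort
#'
#' Bundles the generating Cholesky model, the sample-size and missingness
#' structure, and the polygenic-score generation mode. A seed is
#' mandatory: identical configs with identical seeds produce
#' byte-identical cohorts.
#'
#' @param n_mz_pairs,n_dz_pairs Numbers of MZ and DZ twin pairs.
#' @param model The generating \code{\link{cholesky_model}} (paths,
#'   thresholds, covariate effects). Binary variables must have
#'   model-implied liability variance 1.
#' @param seed Integer seed (required).
#' @param prs_mode \code{"latent"}: additive-genetic factor scores of
#'   pure-A variables are standard-normal latents with the usual MZ/DZ
#'   sharing construction. \code{"locus"}: those factor scores are
#'   replaced by standardized effect-weighted allele sums from
#'   meiosis-based genotypes (see
#'   \code{\link{simulate_polygenic_pairs}}), so the DZ sharing of 0.5
#'   arises mechanistically rather than by construction.
#' @param n_loci Number of independent biallelic loci in locus mode.
#' @param gating Optional list \code{list(screen =, dependents =)}:
#'   after outcome generation, dependents are set missing for members not
#'   endorsing the screen (see \code{\link{apply_gating}}).
#' @param singleton_fraction Probability a pair loses one member's
#'   phenotypes (the family row is kept, mirroring FIML's use of
#'   incomplete pairs).
#' @param prs_missing Named per-variable probability that a member's
#'   continuous score is individually missing.
#' @param sex_prob Probability a member is female (sex = 1). MZ pairs are
#'   same-sex; DZ members are drawn independently.
#' @param age_range Age range in whole years, sampled uniformly per family
#'   (twins share age).
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_mz_pairs, n_dz_pairs, model, seed,
                       prs_mode = c("latent", "locus"), n_loci = 1000,
                       gating = NULL, singleton_fraction = 0,
                       prs_missing = NULL, sex_prob = 0.67,
                       age_range = c(19, 39)) {
  prs_mode <- match.arg(prs_mode)
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0,
            inherits(model, "cholesky_model"),
            singleton_fraction >= 0, singleton_fraction <= 1,
            sex_prob >= 0, sex_prob <= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (!is.null(gating)) {
    stopifnot(is.character(gating$screen), length(gating$screen) == 1L)
    if (gating$screen %in% gating$dependents)
      stop("gating screen variable cannot be one of its dependents")
  }
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 model = model, seed = as.integer(seed),
                 prs_mode = prs_mode, n_loci = as.integer(n_loci),
                 gating = gating,
                 singleton_fraction = singleton_fraction,
                 prs_missing = prs_missing, sex_prob = sex_prob,
                 age_range = age_range),
            class = "sim_config")
}

#' Simulate a twin cohort under a Cholesky ACE generating model
#'
#' Latent factor scores follow the classical twin design: additive-genetic
#' factors are identical across MZ members and correlate 0.5 across DZ
#' members (built as sqrt(0.5) * pair-common + sqrt(0.5) * member-unique
#' standard normals, or mechanistically by meiosis in locus mode for
#' pure-A score variables), shared-environment factors are identical
#' within every pair, unique-environment factors are independent.
#' Observed liabilities are the Cholesky-weighted factor sums plus
#' covariate effects; binary variables are the indicator that liability
#' exceeds the threshold. Gating, singleton creation and score missingness
#' are applied after outcome generation.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with elements \code{dataset} (a
#'   \code{\link{twin_dataset}}) and \code{truth} (per-family latent
#'   component contributions per member and variable, the factor scores,
#'   and the generating parameter vector; never written into the
#'   analysis-facing table).
#' @export
simulate_ace_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$model
  imp <- model_implied(m)
  binary <- m$scale == "binary_liability"
  if (any(abs(diag(imp$Sw)[binary] - 1) > 1e-6))
    stop("generating model gives ordinal variables total variance != 1: ",
         paste(m$vars[binary][abs(diag(imp$Sw)[binary] - 1) > 1e-6],
               collapse = ", "))
  set.seed(config$seed)
  parts <- list()
  truth <- list()
  for (zyg in c("MZ", "DZ")) {
    n <- if (zyg == "MZ") config$n_mz_pairs else config$n_dz_pairs
    if (n == 0L) next
    g <- simulate_zygosity_group(n, zyg, config)
    parts[[zyg]] <- g$data
    truth[[zyg]] <- g$truth
  }
  d <- do.call(rbind, parts)
  d$family_id <- sprintf("fam%05d", seq_len(nrow(d)))
  rownames(d) <- NULL
  ds <- twin_dataset(
    d, m$variables,
    covariates = intersect(c("sex", "age"), unique(m$beta$covariate)),
    provenance = sprintf("simulated ACE cohort, seed %d", config$seed))
  if (!is.null(config$gating))
    ds <- apply_gating(ds, config$gating$screen, config$gating$dependents)
  list(dataset = ds,
       truth = list(components = truth,
                    params = model_get_params(m)))
}

simulate_zygosity_group <- function(n, zyg, config) {
  m <- config$model
  p <- m$p
  pureA <- vapply(m$allowed, function(a) identical(a, "A"), TRUE)

  # factor scores: list of n x p matrices per member
  draw_factors <- function() matrix(stats::rnorm(n * p), n, p)
  if (zyg == "MZ") {
    A1 <- A2 <- draw_factors()
  } else {
    common <- draw_factors()
    A1 <- sqrt(0.5) * common + sqrt(0.5) * draw_factors()
    A2 <- sqrt(0.5) * common + sqrt(0.5) * draw_factors()
  }
  if (config$prs_mode == "locus" && any(pureA)) {
    for (j in which(pureA)) {
      g <- simulate_polygenic_pairs(n, zyg, config$n_loci)
      A1[, j] <- g$prs[, 1L]
      A2[, j] <- g$prs[, 2L]
    }
  }
  C1 <- C2 <- draw_factors()
  E1 <- draw_factors(); E2 <- draw_factors()

  contrib <- function(Fm, X)
    if (X %in% m$comp) Fm %*% t(m$L[[X]]) else matrix(0, n, p)
  Acon <- list(contrib(A1, "A"), contrib(A2, "A"))
  Ccon <- list(contrib(C1, "C"), contrib(C2, "C"))
  Econ <- list(contrib(E1, "E"), contrib(E2, "E"))

  # covariates: twins share age (whole years); MZ pairs share sex
  age <- sample(seq(config$age_range[1L], config$age_range[2L]), n,
                replace = TRUE)
  if (zyg == "MZ") {
    sex1 <- sex2 <- stats::rbinom(n, 1L, config$sex_prob)
  } else {
    sex1 <- stats::rbinom(n, 1L, config$sex_prob)
    sex2 <- stats::rbinom(n, 1L, config$sex_prob)
  }

  d <- data.frame(family_id = rep("", n), zygosity = zyg,
                  stringsAsFactors = FALSE)
  shift <- function(sex, age) {
    sh <- matrix(0, n, p)
    if (nrow(m$beta)) for (r in seq_len(nrow(m$beta))) {
      i <- match(m$beta$variable[r], m$vars)
      x <- switch(m$beta$covariate[r], sex = sex, age = age,
                  stop("unknown covariate in generating model: ",
                       m$beta$covariate[r]))
      sh[, i] <- sh[, i] + m$beta$value[r] * x
    }
    sh
  }
  liab <- list(Acon[[1L]] + Ccon[[1L]] + Econ[[1L]] + shift(sex1, age),
               Acon[[2L]] + Ccon[[2L]] + Econ[[2L]] + shift(sex2, age))
  for (i in seq_len(p)) {
    v <- m$vars[i]
    for (mm in 1:2) {
      y <- liab[[mm]][, i]
      if (m$scale[i] == "binary_liability") {
        y <- as.integer(y > m$tau[[v]])
      } else {
        y <- y + m$mu[[v]]
      }
      d[[paste0(v, "_t", mm)]] <- y
    }
  }
  d$sex_t1 <- sex1; d$sex_t2 <- sex2
  d$age_t1 <- age; d$age_t2 <- age

  # incomplete pairs: one member loses all phenotypes, row retained
  if (config$singleton_fraction > 0) {
    single <- stats::runif(n) < config$singleton_fraction
    who <- ifelse(stats::runif(n) < 0.5, 1L, 2L)
    for (i in which(single)) {
      cols <- paste0(m$vars, "_t", who[i])
      d[i, cols] <- NA
    }
  }
  if (!is.null(config$prs_missing)) {
    for (v in names(config$prs_missing)) {
      for (mm in 1:2) {
        drop <- stats::runif(n) < config$prs_missing[[v]]
        d[drop, paste0(v, "_t", mm)] <- NA
      }
    }
  }
  list(data = d,
       truth = list(A = Acon, C = Ccon, E = Econ,
                    factors_A = list(A1, A2)))
}

#' Simulate polygenic scores for twin pairs from meiosis
#'
#' Each family draws two parents with independent genotypes at
#' \code{n_loci} biallelic loci (allele counts Binomial(2, p_l), allele
#' frequencies uniform on \code{maf_range}). MZ pairs receive one child
#' genotype duplicated; DZ pairs are full siblings generated by
#' independent meiosis: each child independently receives one allele from
#' each parent, transmitted with probability g/2 for parental allele
#' count g. The polygenic score is the effect-weighted allele-count sum,
#' standardized over all members; full siblings' scores correlate 0.5 in
#' expectation.
#'
#' @param n_pairs Number of twin pairs.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @param n_loci Number of independent loci (>= 1).
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @param maf_range Range of allele frequencies.
#' @param weights Optional per-locus effect sizes (default N(0,1) draws).
#' @return List with \code{prs} (n_pairs x 2 standardized scores),
#'   \code{raw} (unstandardized weighted sums), \code{freqs},
#'   \code{weights}.
#' @export
simulate_polygenic_pairs <- function(n_pairs, zygosity, n_loci,
                                     seed = NULL, maf_range = c(0.1, 0.9),
                                     weights = NULL) {
  if (!zygosity %in% c("MZ", "DZ")) stop("unknown zygosity: ", zygosity)
  stopifnot(n_loci >= 1, n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  freqs <- stats::runif(n_loci, maf_range[1L], maf_range[2L])
  if (is.null(weights)) weights <- stats::rnorm(n_loci)
  stopifnot(length(weights) == n_loci)
  raw1 <- raw2 <- numeric(n_pairs)
  chunk <- 250L
  for (s in seq(1L, n_loci, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n_loci)
    L <- length(idx)
    pf <- matrix(freqs[idx], n_pairs, L, byrow = TRUE)
    gm <- matrix(stats::rbinom(n_pairs * L, 2L, pf), n_pairs, L)
    gf <- matrix(stats::rbinom(n_pairs * L, 2L, pf), n_pairs, L)
    meiosis <- function()
      matrix(stats::rbinom(n_pairs * L, 1L, gm / 2), n_pairs, L) +
      matrix(stats::rbinom(n_pairs * L, 1L, gf / 2), n_pairs, L)
    c1 <- meiosis()
    c2 <- if (zygosity == "MZ") c1 else meiosis()
    raw1 <- raw1 + drop(c1 %*% weights[idx])
    raw2 <- raw2 + drop(c2 %*% weights[idx])
  }
  all <- c(raw1, raw2)
  prs <- cbind((raw1 - mean(all)) / stats::sd(all),
               (raw2 - mean(all)) / stats::sd(all))
  list(prs = prs, raw = cbind(raw1, raw2), freqs = freqs, weights = weights)
}

#' Apply conditional-assessment gating
#'
#' Mirrors assessment designs where follow-up items are asked only of
#' members endorsing a screening item: for every member whose screen value
#' is 0 or missing, all dependent variables are set missing; members with
#' screen = 1 are untouched.
#'
#' @param ds A \code{twin_dataset}.
#' @param screen Name of the binary screen variable.
#' @param dependents Character vector of dependent variable names.
#' @return The gated dataset.
#' @export
apply_gating <- function(ds, screen, dependents) {
  if (screen %in% dependents)
    stop("screen variable cannot be among the dependents")
  if (is.null(ds$variables[[screen]]) ||
      ds$variables[[screen]]$scale != "binary_liability")
    stop("screen must be a binary variable in the dataset")
  miss <- setdiff(dependents, names(ds$variables))
  if (length(miss)) stop("unknown dependent variable(s): ",
                         paste(miss, collapse = ", "))
  for (mm in 1:2) {
    s <- ds$data[[paste0(screen, "_t", mm)]]
    gate <- is.na(s) | s == 0
    for (v in dependents)
      ds$data[gate, paste0(v, "_t", mm)] <- NA
  }
  ds
}
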