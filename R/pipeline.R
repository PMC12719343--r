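#' Define an end-to-end analysis plan
#'
#' A plan names the dataset (or the simulation config that generates it),
#' the variable roles — which continuous scores act as polygenic
#' predictors, which binary variable is the diagnosis, which are the
#' conditionally assessed items — the model-selection ladder, and the
#' run settings. The default plan reproduces the standard analysis graph:
#' one threshold-homogeneity test per binary variable, twin-pair and
#' phenotypic correlations, one trivariate score/diagnosis/item ladder per
#' score-by-item combination, one multivariate diagnosis-plus-items
#' ladder, and an optional bootstrap of the diagnosis/attempt AE model.
#'
#' @param dataset A \code{\link{twin_dataset}}, or \code{NULL} to simulate.
#' @param sim A \code{\link{sim_config}} used when \code{dataset} is NULL.
#' @param prs Continuous score variables (each combined with the
#'   diagnosis and each item in a trivariate ladder).
#' @param diagnosis The diagnosis variable (exactly one).
#' @param stb The conditionally assessed item variables.
#' @param components Components of the full model (ladder built by
#'   \code{\link{model_ladder}}).
#' @param alpha Significance level for the chi-squared selection screen.
#' @param restarts Optimizer restarts per fit.
#' @param ci \code{"none"} or \code{"profile"}: whether standardized
#'   estimates are reported with profile-likelihood intervals.
#' @param bootstrap_B Bootstrap replicates for the diagnosis/attempt
#'   robustness check (0 disables it).
#' @param seed Master seed; every stage derives its stream from it.
#' @param control Optimizer control passed to \code{\link{fit_cholesky}}.
#' @return An object of class \code{"analysis_plan"}.
#' @export
analysis_plan <- function(dataset = NULL, sim = NULL,
                          prs = c("prs_md", "prs_sb"),
                          diagnosis = "mdd",
                          stb = c("si", "sp", "sa"),
                          components = c("A", "C", "E"),
                          alpha = 0.05, restarts = 2,
                          ci = c("none", "profile"),
                          bootstrap_B = 0, seed = 1,
                          control = list()) {
  ci <- match.arg(ci)
  if (length(diagnosis) != 1L) stop("exactly one diagnosis variable")
  if (is.null(dataset) && is.null(sim))
    stop("supply a dataset or a simulation config")
  structure(list(dataset = dataset, sim = sim, prs = prs,
                 diagnosis = diagnosis, stb = stb,
                 components = components, alpha = alpha,
                 restarts = restarts, ci = ci,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed),
                 control = control),
            class = "analysis_plan")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: threshold-homogeneity tests for every binary
#' variable; twin-pair correlations by zygosity and the FIML phenotypic
#' correlation matrix; for every score-by-item combination a trivariate
#' Cholesky ladder with model selection; the multivariate
#' diagnosis-plus-items ladder; and (optionally) a non-parametric
#' bootstrap of the diagnosis/attempt AE submodel. Stage failures are
#' recorded in the run log and dependent stages skipped; the partial
#' bundle is still returned. Fully deterministic given the plan seed.
#'
#' @param plan An \code{\link{analysis_plan}}.
#' @return A \code{"report_bundle"}: list with elements
#'   \code{homogeneity}, \code{twin_correlations}, \code{phenotypic},
#'   \code{trivariate}, \code{multivariate}, \code{bootstrap}, \code{log}.
#' @export
run_pipeline <- function(plan) {
  stopifnot(inherits(plan, "analysis_plan"))
  bundle <- list(log = character())
  note <- function(...) bundle$log <<- c(bundle$log, sprintf(...))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      note("stage '%s' failed: %s", label, conditionMessage(e))
      NULL
    })
  }

  ds <- stage("data", {
    if (!is.null(plan$dataset)) plan$dataset
    else simulate_ace_cohort(plan$sim)$dataset
  })
  if (is.null(ds)) {
    note("no dataset; downstream stages skipped")
    return(structure(bundle, class = "report_bundle"))
  }
  note("dataset: %d families (MZ %d, DZ %d), seed %d",
       nrow(ds$data), zygosity_counts(ds)[["MZ"]],
       zygosity_counts(ds)[["DZ"]], plan$seed)
  note("covariate adjustment: definition-variable threshold shifts only")
  binaries <- names(ds$variables)[vapply(ds$variables, `[[`, "", "scale") ==
                                    "binary_liability"]

  bundle$homogeneity <- stage("homogeneity", {
    tabs <- lapply(binaries, function(v) {
      row <- test_threshold_homogeneity(ds, v)
      cbind(variable = v, row)
    })
    do.call(rbind, tabs)
  })

  bundle$twin_correlations <- stage("twin_correlations", {
    out <- list()
    for (v in c(plan$diagnosis, plan$stb, plan$prs))
      for (z in c("MZ", "DZ"))
        out[[paste(v, z, sep = ".")]] <- twin_pair_correlation(ds, v, z)
    out
  })

  bundle$phenotypic <- stage("phenotypic", fiml_correlation_matrix(ds))

  specs <- ds$variables
  fit_seed <- function(k) (plan$seed %% 100000L) * 13L + k

  bundle$trivariate <- stage("trivariate", {
    out <- list()
    k <- 0L
    for (pv in plan$prs) for (sv in plan$stb) {
      k <- k + 1L
      full <- cholesky_model(specs[c(pv, plan$diagnosis, sv)],
                             components = plan$components)
      sel <- select_model(model_ladder(full), ds, alpha = plan$alpha,
                          restarts = plan$restarts, seed = fit_seed(k),
                          control = plan$control)
      out[[paste(pv, sv, sep = ".")]] <- sel
    }
    out
  })

  bundle$multivariate <- stage("multivariate", {
    full <- cholesky_model(specs[c(plan$diagnosis, plan$stb)],
                           components = plan$components)
    select_model(model_ladder(full), ds, alpha = plan$alpha,
                 restarts = plan$restarts, seed = fit_seed(100L),
                 control = plan$control)
  })

  if (plan$ci == "profile" && !is.null(bundle$trivariate)) {
    bundle$trivariate_ci <- stage("trivariate_ci", {
      lapply(bundle$trivariate, function(sel) {
        f <- sel$best
        qs <- unlist(lapply(f$model$vars[f$model$scale == "binary_liability"],
                            function(v) paste0(c("A[", "E["), v, "]")))
        stats::setNames(lapply(qs, function(q) profile_ci(f, q)), qs)
      })
    })
  }

  if (plan$bootstrap_B > 0) {
    bundle$bootstrap <- stage("bootstrap", {
      sa <- plan$stb[length(plan$stb)]
      mod <- cholesky_model(specs[c(plan$diagnosis, sa)],
                            components = c("A", "E"))
      f <- fit_cholesky(mod, ds, restarts = plan$restarts,
                        seed = fit_seed(200L), control = plan$control)
      bootstrap_ci(f, B = plan$bootstrap_B, seed = fit_seed(201L),
                   quantities = paste0("A[", c(plan$diagnosis, sa), "]"))
    })
  }
  structure(bundle, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  for (nm in setdiff(names(x), "log"))
    cat(sprintf("  %s: %s\n", nm, class(x[[nm]])[1L]))
  cat("log:\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Render report tables
#'
#' Formats a bundle component in the conventional twin-study layouts:
#' \describe{
#'   \item{table1}{Twin-pair correlations with 95% CIs, MZ and DZ columns.}
#'   \item{table2}{Standardized A and E (with CIs when computed) for the
#'     diagnosis and item in each trivariate model.}
#'   \item{table3}{Component correlation matrix of the multivariate model:
#'     genetic correlations below the diagonal, unique-environment
#'     correlations above, unit diagonal.}
#'   \item{s3}{Threshold-homogeneity comparisons.}
#'   \item{s4,s5}{Trivariate model-fit comparisons for the first and
#'     second score variable.}
#'   \item{s6}{Multivariate diagnosis-plus-items model-fit comparisons.}
#' }
#'
#' @param bundle A \code{"report_bundle"} from \code{\link{run_pipeline}}.
#' @param which Table id.
#' @return A data.frame (or character matrix for \code{table3}).
#' @export
reproduce_tables <- function(bundle, which) {
  valid <- c("table1", "table2", "table3", "s3", "s4", "s5", "s6")
  if (!is.character(which) || length(which) != 1L || !which %in% valid)
    stop("unknown table id; valid ids: ", paste(valid, collapse = ", "))
  fmt <- function(v, d = 2) formatC(as.numeric(v), digits = d, format = "f")
  switch(which,
    table1 = {
      tc <- bundle$twin_correlations
      vars <- unique(sub("\\.(MZ|DZ)$", "", names(tc)))
      do.call(rbind, lapply(vars, function(v) {
        mz <- tc[[paste0(v, ".MZ")]]; dz <- tc[[paste0(v, ".DZ")]]
        data.frame(variable = v,
                   rMZ = sprintf("%s (%s, %s)", fmt(mz$value),
                                 fmt(mz$ci[1]), fmt(mz$ci[2])),
                   rDZ = sprintf("%s (%s, %s)", fmt(dz$value),
                                 fmt(dz$ci[1]), fmt(dz$ci[2])),
                   stringsAsFactors = FALSE)
      }))
    },
    table2 = {
      do.call(rbind, lapply(names(bundle$trivariate), function(nm) {
        f <- bundle$trivariate[[nm]]$best
        pr <- f$summary$proportions
        vars <- f$model$vars[f$model$scale == "binary_liability"]
        ci <- bundle$trivariate_ci[[nm]]
        cell <- function(v, X) {
          q <- paste0(X, "[", v, "]")
          if (!is.null(ci) && !is.null(ci[[q]]))
            sprintf("%s (%s, %s)", fmt(pr[v, X]), fmt(ci[[q]]$lower),
                    fmt(ci[[q]]$upper))
          else fmt(pr[v, X])
        }
        data.frame(model = nm, selected = f$label,
                   A_diagnosis = cell(vars[1L], "A"),
                   E_diagnosis = cell(vars[1L], "E"),
                   A_item = cell(vars[2L], "A"),
                   E_item = cell(vars[2L], "E"),
                   stringsAsFactors = FALSE)
      }))
    },
    table3 = {
      f <- bundle$multivariate$best
      rr <- component_correlations(f$model)
      p <- f$model$p
      blank <- matrix(NA_real_, p, p,
                      dimnames = list(f$model$vars, f$model$vars))
      rA <- rr$A %||% blank
      rE <- rr$E %||% blank
      out <- matrix("", p, p, dimnames = dimnames(rA))
      for (i in seq_len(p)) for (j in seq_len(p)) {
        out[i, j] <- if (i == j) "1.00"
        else if (i > j) fmt(rA[i, j]) else fmt(rE[i, j])
      }
      out
    },
    s3 = bundle$homogeneity,
    s4 = trivariate_comparisons(bundle, 1L),
    s5 = trivariate_comparisons(bundle, 2L),
    s6 = {
      sel <- bundle$multivariate
      cbind(selected = sel$best$label, sel$comparisons)
    })
}

trivariate_comparisons <- function(bundle, prs_index) {
  nms <- names(bundle$trivariate)
  prs <- unique(vapply(strsplit(nms, ".", fixed = TRUE), `[[`, "", 1L))
  if (prs_index > length(prs)) stop("no such score variable in the bundle")
  keep <- startsWith(nms, paste0(prs[prs_index], "."))
  do.call(rbind, lapply(nms[keep], function(nm) {
    sel <- bundle$trivariate[[nm]]
    cbind(model = nm, selected = sel$best$label, sel$comparisons)
  }))
}
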