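#' Construct a twin-pair dataset
#'
#' The unit of analysis is the family (twin pair). Data are held wide, one
#' row per family: \code{family_id}, \code{zygosity} (\code{"MZ"} or
#' \code{"DZ"}), then per-member columns \code{<variable>_t1} /
#' \code{<variable>_t2} for every phenotype and covariate. Binary
#' phenotypes are coded 0 = unaffected, 1 = affected, \code{NA} = missing;
#' sex is coded 0 = male, 1 = female. Twin order is taken as given by the
#' column suffix and is never re-randomized on load.
#'
#' A member may have all phenotypes missing (an "incomplete pair" retained
#' for FIML) only if the co-twin has at least one observed phenotype.
#'
#' @param data Wide data.frame as described above.
#' @param variables List of \code{\link{variable_spec}} objects, in model
#'   order.
#' @param covariates Character vector of covariate column stems (default
#'   \code{c("sex","age")}); set to \code{character()} if none.
#' @param provenance Free-text metadata (source description, seed if
#'   simulated). Carried through \code{\link{write_cohort}} /
#'   \code{\link{read_cohort}} round trips.
#' @return An object of class \code{"twin_dataset"}.
#' @export
twin_dataset <- function(data, variables, covariates = c("sex", "age"),
                         provenance = "") {
  if (inherits(variables, "variable_spec")) variables <- list(variables)
  stopifnot(is.data.frame(data), length(variables) >= 1L)
  names(variables) <- vapply(variables, `[[`, "", "name")
  ds <- structure(
    list(data = as.data.frame(data, stringsAsFactors = FALSE),
         variables = variables,
         covariates = as.character(covariates),
         provenance = provenance),
    class = "twin_dataset")
  validate_twin_dataset(ds)
  ds
}

member_cols <- function(stem) paste0(stem, c("_t1", "_t2"))

#' Validate a twin dataset
#'
#' Checks every structural invariant of the family records: required
#' columns, unique family ids, known zygosity codes, binary values in
#' {0, 1, NA}, finite continuous values, and that no family has both
#' members entirely unphenotyped.
#'
#' @param ds A \code{twin_dataset}.
#' @return \code{ds}, invisibly, if valid; otherwise an error is raised
#'   identifying the offending rows.
#' @export
validate_twin_dataset <- function(ds) {
  d <- ds$data
  need <- c("family_id", "zygosity",
            unlist(lapply(names(ds$variables), member_cols)),
            unlist(lapply(ds$covariates, member_cols)))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("dataset is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$family_id))
    stop("duplicate family_id: ",
         paste(unique(d$family_id[duplicated(d$family_id)]), collapse = ", "))
  bad_zyg <- !(d$zygosity %in% c("MZ", "DZ"))
  if (any(bad_zyg))
    stop("unknown zygosity code in row(s) ",
         paste(which(bad_zyg), collapse = ", "), ": ",
         paste(unique(d$zygosity[bad_zyg]), collapse = ", "))
  for (v in ds$variables) {
    for (col in member_cols(v$name)) {
      x <- d[[col]]
      if (v$scale == "binary_liability") {
        bad <- !is.na(x) & !(x %in% c(0, 1))
        if (any(bad))
          stop("binary column '", col, "' has values outside {0,1,NA} in row(s) ",
               paste(which(bad), collapse = ", "))
      } else {
        bad <- !is.na(x) & !is.finite(x)
        if (any(bad))
          stop("continuous column '", col, "' has non-finite values in row(s) ",
               paste(which(bad), collapse = ", "))
      }
    }
  }
  phen1 <- as.matrix(d[, paste0(names(ds$variables), "_t1"), drop = FALSE])
  phen2 <- as.matrix(d[, paste0(names(ds$variables), "_t2"), drop = FALSE])
  empty <- rowSums(!is.na(phen1)) == 0 & rowSums(!is.na(phen2)) == 0
  if (any(empty))
    stop("family rows with no observed phenotypes on either member: row(s) ",
         paste(which(empty), collapse = ", "))
  invisible(ds)
}

#' @export
print.twin_dataset <- function(x, ...) {
  zc <- zygosity_counts(x)
  cat(sprintf("<twin_dataset> %d families (MZ %d, DZ %d), %d variables: %s\n",
              nrow(x$data), zc[["MZ"]], zc[["DZ"]],
              length(x$variables),
              paste(names(x$variables), collapse = ", ")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Count families by zygosity
#' @param ds A \code{twin_dataset}.
#' @return Named integer vector with elements \code{MZ} and \code{DZ}.
#' @export
zygosity_counts <- function(ds) {
  c(MZ = sum(ds$data$zygosity == "MZ"),
    DZ = sum(ds$data$zygosity == "DZ"))
}

#' Read a family-structured cohort CSV
#'
#' One row per family; see \code{\link{twin_dataset}} for the column
#' layout. Empty fields and the literal string \code{"NA"} are read as
#' missing. Leading lines starting with \code{#} are treated as a
#' provenance sidecar header and recovered into the dataset's provenance
#' field.
#'
#' @param path CSV file path.
#' @param spec Either a list as returned by
#'   \code{\link{read_variable_config}}, a path to such a YAML config, or a
#'   list of \code{\link{variable_spec}} (covariates then default to
#'   \code{c("sex","age")} intersected with available columns).
#' @return A validated \code{twin_dataset}.
#' @export
read_cohort <- function(path, spec) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(spec) && length(spec) == 1L)
    spec <- read_variable_config(spec)
  if (!is.null(spec$variables)) {
    variables <- spec$variables
    covariates <- spec$covariates
  } else {
    variables <- spec
    covariates <- c("sex", "age")
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  hdr <- hdr[hdr == seq_along(hdr)]  # leading comment block only
  provenance <- paste(sub("^#\\s?", "", lines[hdr]), collapse = "\n")
  body <- if (length(hdr)) lines[-hdr] else lines
  d <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE,
                    na.strings = c("", "NA")),
    error = function(e) stop("malformed CSV '", path, "' (after ",
                             length(hdr), " header line(s)): ",
                             conditionMessage(e)))
  names(variables) <- vapply(variables, `[[`, "", "name")
  covariates <- intersect(covariates,
                          unique(sub("_t[12]$", "",
                                     grep("_t[12]$", names(d), value = TRUE))))
  twin_dataset(d, variables, covariates, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' Missing values are serialized as empty fields; provenance metadata is
#' written as leading \code{#} comment lines so that
#' \code{read_cohort(write_cohort(ds))} is the identity on values,
#' missingness, zygosity labels and provenance.
#'
#' @param ds A validated \code{twin_dataset}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(ds, path) {
  validate_twin_dataset(ds)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  if (nzchar(ds$provenance))
    writeLines(paste0("# ", strsplit(ds$provenance, "\n")[[1L]]), con)
  utils::write.csv(ds$data, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Standardize a continuous variable to mean 0, SD 1
#'
#' Polygenic scores are standardized over all non-missing member values
#' (both member slots pooled) before modelling; the sample SD uses divisor
#' n - 1. The missingness pattern is unchanged.
#'
#' @param ds A \code{twin_dataset}.
#' @param variable Name of a continuous variable with at least two
#'   non-missing values.
#' @return The dataset with the variable standardized.
#' @export
standardize_prs <- function(ds, variable) {
  v <- ds$variables[[variable]]
  if (is.null(v)) stop("unknown variable: ", variable)
  if (v$scale != "continuous")
    stop("'", variable, "' is not continuous")
  cols <- member_cols(variable)
  x <- unlist(ds$data[cols], use.names = FALSE)
  obs <- x[!is.na(x)]
  if (length(obs) < 2L) stop("fewer than 2 non-missing values in ", variable)
  s <- stats::sd(obs)
  if (s < .Machine$double.eps^0.5) stop("zero variance in ", variable)
  m <- mean(obs)
  for (col in cols) ds$data[[col]] <- (ds$data[[col]] - m) / s
  ds
}
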