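#' Declare an analysis variable
#'
#' A variable specification fixes the measurement scale of one analysis
#' variable, which latent variance components it may load on, and which
#' covariates (definition variables) shift its expected liability or mean.
#'
#' Binary variables are modelled on the liability-threshold scale: the
#' observed 0/1 response indicates whether a standard-normal latent
#' liability exceeds a threshold, so they carry exactly one threshold and
#' their model-implied residual variance is constrained to 1. Polygenic
#' scores are declared continuous with \code{components = "A"}: all of
#' their variance is additive-genetic, with no shared- or unique-
#' environment loading.
#'
#' @param name Variable name (must match the cohort column stems, e.g.
#'   \code{"mdd"} for columns \code{mdd_t1}/\code{mdd_t2}).
#' @param scale \code{"binary_liability"} or \code{"continuous"}.
#' @param components Character subset of \code{c("A","C","E")} the variable
#'   may load on. Must be non-empty.
#' @param covariates Character vector of covariate names whose effects enter
#'   this variable's liability mean (threshold shift for binary variables).
#' @return An object of class \code{"variable_spec"}.
#' @examples
#' variable_spec("prs_md", "continuous", components = "A")
#' variable_spec("mdd", "binary_liability", covariates = "sex")
#' @export
variable_spec <- function(name,
                          scale = c("binary_liability", "continuous"),
                          components = c("A", "C", "E"),
                          covariates = character()) {
  scale <- match.arg(scale)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  if (length(components) == 0L)
    stop("'components' must be a non-empty subset of A, C, E")
  components <- match.arg(components, c("A", "C", "E"), several.ok = TRUE)
  structure(
    list(name = name,
         scale = scale,
         components = components,
         covariates = as.character(covariates),
         threshold_count = if (scale == "binary_liability") 1L else 0L),
    class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s: %s, components {%s}%s\n",
              x$name, x$scale, paste(x$components, collapse = ","),
              if (length(x$covariates))
                paste0(", covariates {", paste(x$covariates, collapse = ","), "}")
              else ""))
  invisible(x)
}

#' Read variable specifications from a YAML config
#'
#' The config declares the analysis variables in order, their scales,
#' allowed variance components and covariate attachments, plus the list of
#' covariate columns, e.g.:
#' \preformatted{
#' variables:
#'   - name: prs_md
#'     scale: continuous
#'     components: [A]
#'   - name: mdd
#'     scale: binary_liability
#'     components: [A, C, E]
#'     covariates: [sex]
#' covariates: [sex, age]
#' }
#'
#' @param path Path to a YAML file.
#' @return A list with elements \code{variables} (list of
#'   \code{variable_spec}) and \code{covariates} (character).
#' @export
read_variable_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables)) stop("config has no 'variables' entry")
  vars <- lapply(cfg$variables, function(v) {
    variable_spec(name = v$name,
                  scale = if (is.null(v$scale)) "binary_liability" else v$scale,
                  components = if (is.null(v$components)) c("A", "C", "E")
                               else unlist(v$components),
                  covariates = if (is.null(v$covariates)) character()
                               else unlist(v$covariates))
  })
  list(variables = vars,
       covariates = if (is.null(cfg$covariates)) character()
                    else unlist(cfg$covariates))
}
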