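#' Declare a model covariate
#'
#' A covariate specification records how one column of the woman-level
#' data enters the design matrix: binary columns enter as 0/1, categorical
#' columns are dummy-coded against a reference level, continuous columns
#' enter as-is or standardized (centered and scaled on the estimation
#' sample, with the transform stored for reuse at prediction time).
#'
#' @param name column name in the woman-level data.
#' @param kind one of `"binary"`, `"categorical"`, `"continuous"`.
#' @param levels for categorical covariates, the ordered vector of allowed
#'   levels (at least two).
#' @param reference for categorical covariates, the reference level;
#'   defaults to the first element of `levels`.
#' @param standardize for continuous covariates, whether to center/scale.
#' @return An object of class `mcpr_covariate`.
#' @seealso [default_covariates()]
#' @export
covariate_spec <- function(name,
                           kind = c("binary", "categorical", "continuous"),
                           levels = NULL, reference = NULL,
                           standardize = FALSE) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2)
      stop("categorical covariate '", name, "' needs >= 2 levels")
    if (is.null(reference)) reference <- levels[1]
    if (!reference %in% levels)
      stop("reference level '", reference, "' of '", name,
           "' is not among its levels")
  } else {
    levels <- NULL
    reference <- NULL
  }
  structure(list(name = name, kind = kind, levels = levels,
                 reference = reference,
                 standardize = isTRUE(standardize) && kind == "continuous"),
            class = "mcpr_covariate")
}

#' Default covariate set
#'
#' The standard set of twelve woman-level determinants of modern
#' contraceptive use: residence, schooling, wealth quintile, child
#' survival, age, cohabitation, recent sexual activity, health worker
#' visit, exposure to family planning messages, fertility intention,
#' parity, and distance to the nearest facility. The exact codings used
#' with the original microdata are not public, so these are plausible
#' defaults (e.g. wealth quintile as a five-level factor, parity as a
#' count) and every element can be replaced by the user.
#'
#' @return A named list of [covariate_spec()] objects, class
#'   `mcpr_covariates`.
#' @examples
#' names(default_covariates())
#' @export
default_covariates <- function() {
  specs <- list(
    covariate_spec("residence", "binary"),
    covariate_spec("schooling", "categorical",
                   levels = c("none", "primary", "secondary+")),
    covariate_spec("wealth_quintile", "categorical",
                   levels = paste0("Q", 1:5)),
    covariate_spec("child_survival", "binary"),
    covariate_spec("age", "continuous", standardize = TRUE),
    covariate_spec("cohabitation", "binary"),
    covariate_spec("recent_sex", "binary"),
    covariate_spec("health_worker_visit", "binary"),
    covariate_spec("fp_message", "binary"),
    covariate_spec("fertility_intention", "binary"),
    covariate_spec("parity", "continuous"),
    covariate_spec("distance_facility", "continuous", standardize = TRUE)
  )
  as_covariates(specs)
}

#' Bundle covariate specifications
#'
#' @param specs list of [covariate_spec()] objects.
#' @return The list, named by covariate, class `mcpr_covariates`.
#' @export
as_covariates <- function(specs) {
  if (inherits(specs, "mcpr_covariates")) return(specs)
  if (inherits(specs, "mcpr_covariate")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "mcpr_covariate")))
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs)))
    stop("duplicate covariate names in specification")
  structure(specs, class = "mcpr_covariates")
}

#' @export
print.mcpr_covariates <- function(x, ...) {
  cat("Covariate specification (", length(x), " covariates)\n", sep = "")
  for (s in x) {
    extra <- switch(s$kind,
      categorical = paste0(" [", paste(s$levels, collapse = ", "),
                           "; ref = ", s$reference, "]"),
      continuous = if (s$standardize) " [standardized]" else "",
      "")
    cat(sprintf("  %-20s %-12s%s\n", s$name, s$kind, extra))
  }
  invisible(x)
}

# JSON round-trip used by the command-line interface
covariates_to_json <- function(specs, path) {
  x <- lapply(unclass(specs), function(s) s[!vapply(s, is.null, TRUE)])
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

covariates_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_covariates(lapply(x, function(s) {
    covariate_spec(s$name, s$kind, levels = s$levels,
                   reference = s$reference,
                   standardize = isTRUE(s$standardize))
  }))
}
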