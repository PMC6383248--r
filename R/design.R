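#' Extract the complete-case model frame
#'
#' Rows with a missing value in any model covariate are dropped
#' (complete-case analysis); the number of dropped rows is attached as
#' attribute `"dropped"` and logged via `message()` when positive.
#'
#' @param data validated woman-level data frame.
#' @param covariates `mcpr_covariates` specification.
#' @param quiet suppress the dropped-row message.
#' @return The complete-case data frame.
#' @export
model_frame <- function(data, covariates, quiet = FALSE) {
  covariates <- as_covariates(covariates)
  cc <- stats::complete.cases(data[names(covariates)])
  dropped <- sum(!cc)
  if (dropped > 0 && !quiet)
    message("dropped ", dropped, " row(s) with missing covariate values")
  out <- data[cc, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Build the design matrix
#'
#' Columns are T round-indicator intercepts (exactly one per row, no
#' separate global intercept) followed by the encoded covariates:
#' binary as 0/1, categorical dummy-coded against the reference level,
#' continuous optionally standardized. The encoding (round labels,
#' categorical levels, centering/scaling constants) is stored so the same
#' transform can be replayed on new data at prediction time.
#'
#' @param data complete-case woman-level data frame.
#' @param covariates `mcpr_covariates` specification.
#' @param encoding encoding from a previous `build_design()` call, to
#'   re-encode new data consistently; `NULL` learns it from `data`.
#' @return List of class `bhm_design`: `X` (numeric matrix with named
#'   columns), `round_index` (1..T per row), and `encoding`.
#' @export
build_design <- function(data, covariates, encoding = NULL) {
  covariates <- as_covariates(covariates)
  new_enc <- is.null(encoding)
  if (new_enc)
    encoding <- list(rounds = sort(unique(data$round)), center = list(),
                     scale = list())
  rounds <- encoding$rounds
  t_idx <- match(data$round, rounds)
  if (anyNA(t_idx))
    stop("encoding error: round(s) not seen at fit time: ",
         paste(setdiff(unique(data$round), rounds), collapse = ", "))
  T <- length(rounds)
  Xint <- matrix(0, nrow(data), T,
                 dimnames = list(NULL, paste0("round_", rounds)))
  Xint[cbind(seq_len(nrow(data)), t_idx)] <- 1

  cols <- list()
  for (s in covariates) {
    v <- data[[s$name]]
    if (anyNA(v))
      stop("missing values in covariate '", s$name,
           "'; apply model_frame() first")
    if (s$kind == "binary") {
      cols[[s$name]] <- as.numeric(v)
    } else if (s$kind == "categorical") {
      bad <- setdiff(unique(v), s$levels)
      if (length(bad))
        stop("encoding error: unseen level(s) in '", s$name, "': ",
             paste(bad, collapse = ", "))
      for (lv in setdiff(s$levels, s$reference))
        cols[[paste(s$name, lv, sep = "_")]] <- as.numeric(v == lv)
    } else {
      v <- as.numeric(v)
      if (s$standardize) {
        if (new_enc) {
          encoding$center[[s$name]] <- mean(v)
          encoding$scale[[s$name]] <- sd(v)
          if (!is.finite(encoding$scale[[s$name]]) ||
              encoding$scale[[s$name]] == 0)
            encoding$scale[[s$name]] <- 1
        }
        v <- (v - encoding$center[[s$name]]) / encoding$scale[[s$name]]
      }
      cols[[s$name]] <- v
    }
  }
  X <- cbind(Xint, do.call(cbind, cols))
  structure(list(X = X, round_index = t_idx, encoding = encoding),
            class = "bhm_design")
}
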