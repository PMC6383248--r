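#' @name women-data
#' @title Woman-level survey data contract
#' @description
#' All estimation functions take a data frame with one row per
#' woman-interview and columns `country_id`, `region_id`, `ea_id`
#' (enumeration area, the sampling cluster, nested within region),
#' `woman_id`, `round` (integer survey wave, 1..T), `y` (1 = modern
#' contraceptive user, 0 = non-user), `weight` (positive sampling weight,
#' defaulting to 1 when absent) and one column per declared covariate.
#' Missing covariate values are `NA` (empty string in CSV); rows with a
#' missing model covariate are dropped, with a logged count, when the
#' design matrix is built.
NULL

.id_cols <- c("country_id", "region_id", "ea_id", "woman_id")
.req_cols <- c(.id_cols, "round", "y")

#' Validate a woman-level table
#'
#' Checks the data contract: required columns, `y` in \{0, 1\}, positive
#' weights, integer rounds, and that every enumeration area belongs to
#' exactly one region. A missing `weight` column is filled with 1.
#'
#' @param data data frame of woman records.
#' @param covariates optional `mcpr_covariates`; when given, the presence
#'   of each covariate column and the legality of categorical levels are
#'   also checked.
#' @return The validated (possibly weight-augmented) data frame,
#'   invisibly useful in pipelines.
#' @export
validate_women <- function(data, covariates = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0)
    stop("empty input: no woman records")
  miss <- setdiff(.req_cols, names(data))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cc in .id_cols) data[[cc]] <- as.character(data[[cc]])
  bad_y <- which(!data$y %in% c(0, 1))
  if (length(bad_y))
    stop("value error: y outside {0,1} in row(s) ",
         paste(utils::head(bad_y, 5), collapse = ", "))
  rr <- data$round
  if (any(is.na(rr)) || any(rr != as.integer(rr)) || any(rr < 1))
    stop("value error: round must be a positive integer")
  data$round <- as.integer(rr)
  if (is.null(data$weight)) data$weight <- 1
  bad_w <- which(!(is.finite(data$weight) & data$weight > 0))
  if (length(bad_w))
    stop("value error: non-positive weight in row(s) ",
         paste(utils::head(bad_w, 5), collapse = ", "))
  nreg <- tapply(data$region_id, data$ea_id,
                 function(r) length(unique(r)))
  if (any(nreg > 1))
    stop("nesting error: enumeration area(s) mapped to multiple regions: ",
         paste(names(nreg)[nreg > 1], collapse = ", "))
  if (!is.null(covariates)) {
    covariates <- as_covariates(covariates)
    miss <- setdiff(names(covariates), names(data))
    if (length(miss))
      stop("schema error: missing covariate column(s): ",
           paste(miss, collapse = ", "))
    for (s in covariates) {
      v <- data[[s$name]]
      if (s$kind == "binary" && !all(v[!is.na(v)] %in% c(0, 1)))
        stop("value error: binary covariate '", s$name, "' outside {0,1}")
      if (s$kind == "categorical") {
        bad <- setdiff(unique(v[!is.na(v)]), s$levels)
        if (length(bad))
          stop("value error: covariate '", s$name, "' has undeclared ",
               "level(s): ", paste(bad, collapse = ", "))
      }
    }
  }
  data
}

#' Read woman-level records from CSV
#'
#' Comma-separated, UTF-8, header required; identifier columns are read
#' as strings and empty covariate cells become `NA`. The table is
#' validated against the contract in [women-data] before being returned.
#'
#' @param path CSV file path.
#' @param covariates covariate specification used for column/level checks
#'   (default: the twelve standard covariates).
#' @return Validated data frame of woman records.
#' @export
read_women <- function(path, covariates = default_covariates()) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- read.csv(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), colClasses = NA)
  validate_women(data, covariates)
}

#' Write woman-level records to CSV
#'
#' Inverse of [read_women()]: `NA` covariate values are written as empty
#' strings so the round trip is the identity on valid tables.
#'
#' @param data woman-level data frame.
#' @param path output path.
#' @export
write_women <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Profile a dataset
#'
#' Per-round counts of distinct regions, enumeration areas and women, the
#' per-EA-by-round sample sizes, and the list of EAs not observed in
#' every round (which the analytical sample excludes).
#'
#' @param data woman-level data frame.
#' @return Object of class `mcpr_profile`: list with elements `per_round`
#'   (data frame), `totals`, `n_kt` (EA x round count matrix) and
#'   `unbalanced_eas`.
#' @export
profile_dataset <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0)
    stop("empty input: no woman records to profile")
  rounds <- sort(unique(data$round))
  per_round <- data.frame(
    round = rounds,
    n_regions = vapply(rounds, function(t)
      length(unique(data$region_id[data$round == t])), 1L),
    n_eas = vapply(rounds, function(t)
      length(unique(data$ea_id[data$round == t])), 1L),
    n_women = vapply(rounds, function(t)
      sum(data$round == t), 1L))
  n_kt <- table(factor(data$ea_id), factor(data$round, levels = rounds))
  n_kt <- unclass(matrix(n_kt, nrow(n_kt), ncol(n_kt),
                         dimnames = dimnames(n_kt)))
  unbalanced <- rownames(n_kt)[rowSums(n_kt > 0) < length(rounds)]
  structure(list(
    per_round = per_round,
    totals = list(n_regions = length(unique(data$region_id)),
                  n_eas = length(unique(data$ea_id)),
                  n_women = nrow(data), n_rounds = length(rounds)),
    n_kt = n_kt,
    unbalanced_eas = unbalanced), class = "mcpr_profile")
}

#' @export
print.mcpr_profile <- function(x, ...) {
  cat("Survey profile:", x$totals$n_women, "women,",
      x$totals$n_eas, "enumeration areas,",
      x$totals$n_regions, "regions,",
      x$totals$n_rounds, "round(s)\n")
  print(x$per_round, row.names = FALSE)
  if (length(x$unbalanced_eas))
    cat("EAs not present in all rounds:",
        paste(x$unbalanced_eas, collapse = ", "), "\n")
  invisible(x)
}

#' Restrict to enumeration areas observed in every round
#'
#' The analytical sample keeps only EAs covered in all survey rounds of
#' the dataset, so that area trajectories are comparable across rounds.
#'
#' @param data woman-level data frame.
#' @return The filtered data frame. Idempotent.
#' @export
filter_balanced_eas <- function(data) {
  prof <- profile_dataset(data)
  keep <- setdiff(rownames(prof$n_kt), prof$unbalanced_eas)
  if (length(keep) == 0)
    stop("all EAs unbalanced: no enumeration area is present in every round")
  out <- data[data$ea_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
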