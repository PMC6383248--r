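#' Write the standard report tables
#'
#' Emits, under `dir`: `estimates_by_round.csv` (region x round posterior
#' median mCPR with 95% interval, national `ALL` row included, in
#' percentage points), `change.csv` (first-to-last-round change per
#' region), `shrinkage.csv`, `residuals.csv` (Z-values), and
#' `convergence.csv`, plus `metadata.json` recording the seed, sampler
#' settings, package and R versions and a hash of the model
#' configuration. Values are rounded only at write time.
#'
#' @param fit `bhm` object.
#' @param dir output directory (created if needed).
#' @param level unit level for shrinkage/residual tables (default the
#'   fit's random-effect level).
#' @param digits rounding for the CSV output.
#' @return Invisibly, the vector of files written.
#' @export
report_bhm <- function(fit, dir, level = fit$area_level, digits = 1) {
  stopifnot(inherits(fit, "bhm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pct <- function(x) round(100 * x, digits)

  est <- mcpr_table(fit)
  est[c("mcpr", "lower", "upper")] <- lapply(
    est[c("mcpr", "lower", "upper")], pct)
  write.csv(est, file.path(dir, "estimates_by_round.csv"),
            row.names = FALSE)

  chg <- change_table(fit)
  chg[c("change", "lower", "upper")] <- lapply(
    chg[c("change", "lower", "upper")], pct)
  write.csv(chg, file.path(dir, "change.csv"), row.names = FALSE)

  shr <- shrinkage_table(fit, level)
  num <- vapply(shr, is.numeric, TRUE) & names(shr) != "n"
  shr[num] <- lapply(shr[num], round, digits + 3)
  write.csv(shr, file.path(dir, "shrinkage.csv"), row.names = FALSE)

  res <- z_values(fit, level)
  res[c("pred_mean", "pred_sd", "z")] <-
    lapply(res[c("pred_mean", "pred_sd", "z")], round, digits + 3)
  write.csv(res, file.path(dir, "residuals.csv"), row.names = FALSE)

  write.csv(fit$convergence, file.path(dir, "convergence.csv"),
            row.names = FALSE)

  cfg <- list(area_level = fit$area_level, rounds = fit$rounds,
              covariates = lapply(unclass(fit$covariates), function(s)
                s[!vapply(s, is.null, TRUE)]),
              priors = unclass(fit$priors), sampler = fit$sampler)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  meta <- list(package = "mcprsae",
               version = as.character(packageVersion("mcprsae")),
               r_version = R.version.string,
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               seed = fit$sampler$seed, sampler = fit$sampler,
               config_md5 = unname(tools::md5sum(tf)),
               n_women = nrow(fit$data), n_areas = length(fit$areas),
               dropped_rows = fit$dropped,
               accept_rates = fit$accept,
               convergence_pass = attr(fit$convergence, "pass"))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  unlink(tf)
  invisible(file.path(dir, c("estimates_by_round.csv", "change.csv",
                             "shrinkage.csv", "residuals.csv",
                             "convergence.csv", "metadata.json")))
}

#' Persist posterior draws as a tidy CSV
#'
#' One row per chain x draw x parameter (`chain`, `draw`, `parameter`,
#' `value`), a self-describing format any tool can read back.
#'
#' @param fit `bhm` object.
#' @param path output CSV path.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "bhm"))
  pars <- cbind(fit$draws$beta, fit$draws$u, rho = fit$draws$rho,
                sigma = fit$draws$sigma)
  S_ch <- fit$n_draws / fit$n_chains
  long <- data.frame(
    chain = rep(fit$chain, times = ncol(pars)),
    draw = rep(rep(seq_len(S_ch), fit$n_chains), times = ncol(pars)),
    parameter = rep(colnames(pars), each = nrow(pars)),
    value = as.vector(pars))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write model metadata JSON for draw persistence
#'
#' Companion of [write_draws()]: records the encoding, areas, rounds,
#' covariate specification, priors and sampler settings needed by
#' [bhm_restore()].
#'
#' @param fit `bhm` object.
#' @param path output JSON path.
#' @export
write_model_meta <- function(fit, path) {
  meta <- list(
    area_level = fit$area_level, areas = fit$areas, rounds = fit$rounds,
    covariates = lapply(unclass(fit$covariates), function(s)
      s[!vapply(s, is.null, TRUE)]),
    encoding = fit$encoding, priors = unclass(fit$priors),
    sampler = fit$sampler, id = fit$id,
    beta_names = colnames(fit$draws$beta))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Rebuild a fitted-model object from persisted draws
#'
#' Counterpart of [write_draws()] plus the model metadata JSON written by
#' the command-line `fit` stage: reconstructs a `bhm` object against the
#' original data so the estimation and diagnostic functions can run in a
#' separate process from the sampler.
#'
#' @param data the woman-level data the model was fitted to.
#' @param meta_path path of the model metadata JSON.
#' @param draws_path path of the tidy draws CSV.
#' @return A `bhm` object.
#' @export
bhm_restore <- function(data, meta_path, draws_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  covariates <- as_covariates(lapply(meta$covariates, function(s)
    covariate_spec(s$name, s$kind, levels = s$levels,
                   reference = s$reference,
                   standardize = isTRUE(s$standardize))))
  priors <- do.call(bhm_priors, meta$priors)
  data <- validate_women(data, covariates)
  data <- model_frame(data, covariates, quiet = TRUE)
  enc <- meta$encoding
  enc$rounds <- as.integer(enc$rounds)
  des <- build_design(data, covariates, encoding = enc)
  area_col <- if (meta$area_level == "ea") "ea_id" else "region_id"
  areas <- meta$areas
  a_idx <- match(data[[area_col]], areas)
  if (anyNA(a_idx))
    stop("data contain areas absent from the persisted fit")

  long <- read.csv(draws_path, stringsAsFactors = FALSE)
  S_ch <- max(long$draw)
  chains <- max(long$chain)
  pars <- unique(long$parameter)
  long <- long[order(match(long$parameter, pars), long$chain,
                     long$draw), ]
  M <- matrix(long$value, ncol = length(pars),
              dimnames = list(NULL, pars))
  chain_id <- rep(seq_len(chains), each = S_ch)
  K <- length(areas); T <- length(meta$rounds)
  u_cols <- paste(rep(areas, T), rep(meta$rounds, each = K), sep = "|")

  fit <- structure(list(
    draws = list(beta = M[, meta$beta_names, drop = FALSE],
                 u = M[, u_cols, drop = FALSE],
                 rho = M[, "rho"], sigma = M[, "sigma"]),
    chain = chain_id, n_chains = chains, n_draws = nrow(M),
    areas = areas, area_level = meta$area_level,
    rounds = as.integer(meta$rounds), covariates = covariates,
    encoding = des$encoding, priors = priors, data = data, X = des$X,
    area_index = a_idx, round_index = des$round_index,
    dropped = attr(data, "dropped") %||% 0L,
    accept = list(rho = NA_real_, sigma = NA_real_),
    sampler = meta$sampler, id = meta$id), class = "bhm")
  fit$convergence <- convergence_report(fit, quiet = TRUE)
  fit
}
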