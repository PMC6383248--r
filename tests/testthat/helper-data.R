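# tiny in-memory fixtures; everything is generated in code

# minimal valid woman table: vectors are recycled to the longest length
make_women <- function(region = "A", ea = "E1", round = 1L, y = 0L,
                       weight = 1, ...) {
  n <- max(lengths(list(region, ea, round, y, weight)))
  df <- data.frame(country_id = "XX",
                   region_id = rep_len(region, n),
                   ea_id = rep_len(ea, n),
                   woman_id = sprintf("W%03d", seq_len(n)),
                   round = rep_len(as.integer(round), n),
                   y = rep_len(y, n), weight = rep_len(weight, n),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  df
}

# two simple covariates used throughout the fast tests
test_covariates <- function() {
  as_covariates(list(
    covariate_spec("urban", "binary"),
    covariate_spec("age", "continuous", standardize = TRUE)))
}

test_beta <- function(rounds = 3) {
  traj <- c(0.18, 0.20, 0.22, 0.24)[seq_len(rounds)]
  c(setNames(qlogis(traj) - 0.2, paste0("round_", seq_len(rounds))),
    urban = 0.4, age = -0.2)
}

# a small shared fit, computed once per test run
shared_fit_env <- new.env()
shared_fit <- function() {
  if (is.null(shared_fit_env$fit)) {
    sim <- generate_dataset(generator_config(
      n_regions = 4, eas_per_region = 3, rounds = 3,
      women_per_round = 600, covariates = test_covariates(),
      beta = test_beta(3), rho = 0.6, sigma = 0.5, seed = 42))
    shared_fit_env$sim <- sim
    shared_fit_env$fit <- suppressWarnings(
      bhm(sim$data, covariates = test_covariates(), chains = 2,
          iter = 200, warmup = 200, seed = 7, quiet = TRUE))
  }
  shared_fit_env$fit
}
shared_sim <- function() {
  shared_fit()
  shared_fit_env$sim
}
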