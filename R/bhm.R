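#' Fit the Bayesian hierarchical logistic model
#'
#' Fits, by MCMC, the woman-level model
#' `logit(P) = x' beta + u[area, round]` with round-specific intercepts,
#' the declared covariates, and area-by-round random effects following a
#' stationary AR(1) process over rounds — the small-area model whose
#' posterior underlies all regional prevalence and change estimates.
#' Sampling uses Polya-Gamma data augmentation, giving Gaussian Gibbs
#' updates for `beta` and `u`, with adaptive random-walk Metropolis steps
#' for `rho` (atanh scale) and `sigma` (log scale). The likelihood is the
#' unweighted woman-level Bernoulli; survey weights enter only when
#' posterior draws are aggregated.
#'
#' @param data woman-level data frame (see [women-data]); validated
#'   internally.
#' @param covariates `mcpr_covariates` specification.
#' @param area_level `"ea"` (default; the sampling-cluster level of the
#'   data hierarchy) or `"region"`: the level of the random effects.
#' @param priors [bhm_priors()] configuration.
#' @param chains number of independent chains.
#' @param iter retained draws per chain (after warmup, before thinning).
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param thin thinning interval.
#' @param seed integer seed; fixed seed gives bit-identical draws.
#' @param quiet suppress progress and dropped-row messages.
#' @return Object of class `bhm` with posterior draws of `beta`
#'   (S x p), `u` (S x K*T, columns `area|round`), `rho` and `sigma`,
#'   the model frame and design encoding, and a convergence table
#'   (rank-normalized split potential-scale-reduction and bulk effective
#'   sample size per parameter). A warning is issued — the fit is kept —
#'   when any potential-scale-reduction factor exceeds 1.05.
#' @seealso [summary.bhm()], [predict.bhm()], [aggregate_mcpr()],
#'   [convergence_report()]
#' @examples
#' \donttest{
#' sim <- generate_dataset(generator_config(n_regions = 4,
#'   eas_per_region = 3, rounds = 2, women_per_round = 600, seed = 1))
#' fit <- bhm(sim$data, chains = 2, iter = 200, warmup = 200, seed = 1)
#' summary(fit)
#' }
#' @export
bhm <- function(data, covariates = default_covariates(),
                area_level = c("ea", "region"),
                priors = bhm_priors(), chains = 4, iter = 1000,
                warmup = 1000, thin = 1, seed = 1, quiet = FALSE) {
  area_level <- match.arg(area_level)
  covariates <- as_covariates(covariates)
  stopifnot(inherits(priors, "bhm_priors"), chains >= 1, iter >= 1,
            warmup >= 0, thin >= 1)
  data <- validate_women(data, covariates)
  data <- model_frame(data, covariates, quiet = quiet)
  if (nrow(data) == 0) stop("no complete-case rows left")

  area_col <- if (area_level == "ea") "ea_id" else "region_id"
  areas <- sort(unique(data[[area_col]]))
  K <- length(areas)
  if (K < 2) stop("need >= 2 areas to fit the hierarchical model")
  if (length(unique(data$y)) == 1)
    warning("degenerate data: all outcomes equal; fit proceeds")

  des <- build_design(data, covariates)
  X <- des$X
  p <- ncol(X)
  T <- length(des$encoding$rounds)
  a_idx <- match(data[[area_col]], areas)

  set.seed(as.integer(seed %% 2100000000L))
  chain_seeds <- sample.int(2147483646L, chains)

  bm <- rep_len(priors$beta_mean, p)
  bs <- rep_len(priors$beta_sd, p)
  res <- vector("list", chains)
  t0 <- Sys.time()
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    init_beta <- rnorm(p, 0, 0.1)
    init_sigma <- exp(rnorm(1, log(0.5), 0.3))
    init_rho <- runif(1, -0.3, 0.3)
    res[[ch]] <- bhm_gibbs_cpp(
      X, data$y, a_idx - 1L, des$round_index - 1L, K, T, bm, bs,
      priors$sigma_scale, priors$rho_shape1, priors$rho_shape2,
      warmup, iter %/% thin, thin,
      init_beta, matrix(0, K, T), init_rho, init_sigma)
    if (!quiet)
      message(sprintf("chain %d/%d done (%.1fs)", ch, chains,
                      as.numeric(Sys.time() - t0, units = "secs")))
  }

  S_ch <- nrow(res[[1]]$beta)
  beta_d <- do.call(rbind, lapply(res, `[[`, "beta"))
  colnames(beta_d) <- colnames(X)
  u_d <- do.call(rbind, lapply(res, `[[`, "u"))
  colnames(u_d) <- paste(rep(areas, T),
                         rep(des$encoding$rounds, each = K), sep = "|")
  rho_d <- unlist(lapply(res, `[[`, "rho"))
  sigma_d <- unlist(lapply(res, `[[`, "sigma"))
  chain_id <- rep(seq_len(chains), each = S_ch)

  fit <- structure(list(
    draws = list(beta = beta_d, u = u_d, rho = rho_d, sigma = sigma_d),
    chain = chain_id, n_chains = chains, n_draws = length(rho_d),
    areas = areas, area_level = area_level, rounds = des$encoding$rounds,
    covariates = covariates, encoding = des$encoding, priors = priors,
    data = data, X = X, area_index = a_idx,
    round_index = des$round_index,
    dropped = attr(data, "dropped") %||% 0L,
    accept = list(rho = mean(vapply(res, `[[`, 1, "accept_rho")),
                  sigma = mean(vapply(res, `[[`, 1, "accept_sigma"))),
    sampler = list(chains = chains, iter = iter, warmup = warmup,
                   thin = thin, seed = seed),
    id = sprintf("bhm-%s-%d", format(t0, "%Y%m%d%H%M%S"),
                 chain_seeds[1])), class = "bhm")

  fit$convergence <- convergence_report(fit, quiet = TRUE)
  bad <- fit$convergence$rhat > 1.05
  if (any(bad, na.rm = TRUE))
    warning("possible non-convergence: max potential-scale-reduction ",
            sprintf("%.3f", max(fit$convergence$rhat, na.rm = TRUE)),
            " (parameters: ",
            paste(utils::head(fit$convergence$parameter[which(bad)], 5),
                  collapse = ", "), ")")
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bhm <- function(x, ...) {
  cat("Bayesian hierarchical logistic model (AR(1) area-round effects)\n")
  cat(sprintf("  %d women, %d %s-level areas, %d round(s), %d coefficients\n",
              nrow(x$data), length(x$areas), x$area_level,
              length(x$rounds), ncol(x$draws$beta)))
  cat(sprintf("  %d chains x %d draws (warmup %d, thin %d), seed %d\n",
              x$n_chains, x$n_draws / x$n_chains, x$sampler$warmup,
              x$sampler$thin, x$sampler$seed))
  cat(sprintf("  rho: %.3f [%.3f, %.3f]  sigma: %.3f [%.3f, %.3f]\n",
              median(x$draws$rho),
              quantile(x$draws$rho, 0.025), quantile(x$draws$rho, 0.975),
              median(x$draws$sigma),
              quantile(x$draws$sigma, 0.025),
              quantile(x$draws$sigma, 0.975)))
  cat(sprintf("  max Rhat %.3f, min bulk ESS %.0f\n",
              max(x$convergence$rhat, na.rm = TRUE),
              min(x$convergence$ess, na.rm = TRUE)))
  invisible(x)
}

#' Posterior summary of model parameters
#'
#' @param object `bhm` fit.
#' @param prob credible-interval mass (default 0.95, equal-tailed).
#' @param ... unused.
#' @return Data frame with posterior mean, median, interval bounds,
#'   potential-scale-reduction and effective sample size for every fixed
#'   effect plus `rho` and `sigma`.
#' @export
summary.bhm <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  mats <- cbind(object$draws$beta, rho = object$draws$rho,
                sigma = object$draws$sigma)
  conv <- object$convergence
  out <- data.frame(
    parameter = colnames(mats),
    mean = colMeans(mats),
    median = apply(mats, 2, median),
    lower = apply(mats, 2, quantile, a),
    upper = apply(mats, 2, quantile, 1 - a),
    row.names = NULL)
  out$rhat <- conv$rhat[match(out$parameter, conv$parameter)]
  out$ess <- conv$ess[match(out$parameter, conv$parameter)]
  class(out) <- c("summary.bhm", "data.frame")
  attr(out, "prob") <- prob
  out
}

#' @export
print.summary.bhm <- function(x, digits = 3, ...) {
  cat("Posterior summary (", attr(x, "prob") * 100,
      "% equal-tailed intervals)\n", sep = "")
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bhm <- function(object, ...) {
  apply(object$draws$beta, 2, median)
}

#' Area-effect draws as an array
#'
#' @param fit `bhm` object.
#' @return S x K x T array of the `u` draws, dimnames `(draw, area,
#'   round)`.
#' @export
u_draws <- function(fit) {
  stopifnot(inherits(fit, "bhm"))
  K <- length(fit$areas); T <- length(fit$rounds)
  array(fit$draws$u, dim = c(nrow(fit$draws$u), K, T),
        dimnames = list(NULL, fit$areas, fit$rounds))
}
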