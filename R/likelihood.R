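#' Prior configuration
#'
#' Weakly informative defaults on the logit scale: independent
#' Normal(0, 5^2) on every coefficient, Half-Normal(1) on the AR(1)
#' innovation scale sigma, and a flat Beta(1, 1) prior on (rho + 1) / 2,
#' i.e. Uniform(-1, 1) on the autocorrelation. The area effects get the
#' stationary AR(1) prior given (rho, sigma).
#'
#' @param beta_mean,beta_sd prior mean and SD for the coefficients
#'   (recycled over components).
#' @param sigma_scale Half-Normal scale for sigma.
#' @param rho_shape1,rho_shape2 Beta shape parameters on (rho + 1) / 2.
#' @return List of class `bhm_priors`.
#' @export
bhm_priors <- function(beta_mean = 0, beta_sd = 5, sigma_scale = 1,
                       rho_shape1 = 1, rho_shape2 = 1) {
  stopifnot(all(beta_sd > 0), sigma_scale > 0, rho_shape1 > 0,
            rho_shape2 > 0)
  structure(list(beta_mean = beta_mean, beta_sd = beta_sd,
                 sigma_scale = sigma_scale, rho_shape1 = rho_shape1,
                 rho_shape2 = rho_shape2), class = "bhm_priors")
}

#' Bernoulli log-likelihood of the hierarchical logistic model
#'
#' Sum over records of `y * log(P) + (1 - y) * log(1 - P)` with
#' `P = plogis(X beta + u[area, round])`, computed with numerically
#' stable log-inverse-logit terms.
#'
#' @param params list with `beta` (length-p vector) and `u` (K x T matrix).
#' @param X design matrix (n x p).
#' @param y binary outcome vector.
#' @param area integer area index (1..K) per row.
#' @param round integer round index (1..T) per row.
#' @return Log-likelihood value.
#' @export
bhm_log_likelihood <- function(params, X, y, area, round) {
  if (length(params$beta) != ncol(X))
    stop("shape error: length(beta) != ncol(X)")
  if (length(y) != nrow(X) || length(area) != nrow(X) ||
      length(round) != nrow(X))
    stop("shape error: y/area/round must match rows of X")
  eta <- drop(X %*% params$beta) + params$u[cbind(area, round)]
  sum(y * plogis(eta, log.p = TRUE) + (1 - y) * plogis(-eta, log.p = TRUE))
}

#' Joint log-prior of the hierarchical logistic model
#'
#' Coefficients Normal, sigma Half-Normal, rho rescaled Beta, and the
#' area-effect matrix u given (rho, sigma) a stationary AR(1) density per
#' area (first round from the stationary distribution). Returns `-Inf`
#' outside the support (|rho| >= 1 or sigma <= 0).
#'
#' @param params list with `beta`, `u` (K x T), `rho`, `sigma`.
#' @param priors [bhm_priors()] configuration.
#' @return Log-prior density.
#' @export
bhm_log_prior <- function(params, priors = bhm_priors()) {
  rho <- params$rho; sigma <- params$sigma
  if (!is.finite(rho) || abs(rho) >= 1 || !is.finite(sigma) || sigma <= 0)
    return(-Inf)
  p <- length(params$beta)
  lp <- sum(dnorm(params$beta, rep_len(priors$beta_mean, p),
                  rep_len(priors$beta_sd, p), log = TRUE))
  lp <- lp + dnorm(sigma, 0, priors$sigma_scale, log = TRUE) + log(2)
  lp <- lp + dbeta((rho + 1) / 2, priors$rho_shape1, priors$rho_shape2,
                   log = TRUE) + log(0.5)
  u <- as.matrix(params$u)
  T <- ncol(u)
  lp <- lp + sum(dnorm(u[, 1], 0, sigma / sqrt(1 - rho^2), log = TRUE))
  if (T > 1)
    for (t in 2:T)
      lp <- lp + sum(dnorm(u[, t], rho * u[, t - 1], sigma, log = TRUE))
  lp
}
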