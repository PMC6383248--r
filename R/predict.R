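# blocked iteration over posterior draws of the linear predictor /
# probability surface, to keep memory flat for large n x S
.p_block_apply <- function(fit, X, a_idx, t_idx, FUN, zero_u = FALSE,
                           block = 512L, u_extra = NULL, link = FALSE) {
  S <- fit$n_draws
  K <- length(fit$areas)
  col_idx <- (t_idx - 1L) * K + a_idx  # column of the u draw matrix
  starts <- seq(1L, S, by = block)
  for (s0 in starts) {
    sb <- s0:min(s0 + block - 1L, S)
    eta <- X %*% t(fit$draws$beta[sb, , drop = FALSE])  # n x B
    if (!zero_u) {
      known <- !is.na(col_idx)
      if (any(known))
        eta[known, ] <- eta[known, ] +
          t(fit$draws$u[sb, col_idx[known], drop = FALSE])
      if (!is.null(u_extra) && any(!known))
        eta[!known, ] <- eta[!known, ] + u_extra[!known, sb, drop = FALSE]
    }
    FUN(if (link) eta else plogis(eta), sb)
  }
  invisible(NULL)
}

#' Posterior draws of each woman's use probability
#'
#' For every retained draw s, computes
#' `P^(s) = plogis(X beta^(s) + u^(s)[area, round])` for each record.
#' Records from areas not seen at fit time are handled by drawing their
#' effect from the stationary AR(1) prior given that draw's (rho, sigma)
#' and flagged as extrapolation.
#'
#' @param fit `bhm` object.
#' @param newdata optional new woman-level data frame (complete cases);
#'   `NULL` uses the estimation data.
#' @return n x S matrix of probability draws; attribute
#'   `"extrapolated_areas"` lists areas absent from the fit, if any.
#' @export
posterior_p <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "bhm"))
  ctx <- .predict_context(fit, newdata)
  P <- matrix(NA_real_, nrow(ctx$X), fit$n_draws)
  .p_block_apply(fit, ctx$X, ctx$a_idx, ctx$t_idx,
                 function(Pb, sb) P[, sb] <<- Pb, u_extra = ctx$u_extra)
  attr(P, "extrapolated_areas") <- ctx$extrapolated
  P
}

# resolve design matrix + area/round indices (and prior draws for unseen
# areas) for either the estimation data or newdata
.predict_context <- function(fit, newdata = NULL) {
  if (is.null(newdata))
    return(list(X = fit$X, a_idx = fit$area_index,
                t_idx = fit$round_index, u_extra = NULL,
                extrapolated = character()))
  newdata <- validate_women(newdata, fit$covariates)
  des <- build_design(newdata, fit$covariates, encoding = fit$encoding)
  area_col <- if (fit$area_level == "ea") "ea_id" else "region_id"
  a_idx <- match(newdata[[area_col]], fit$areas)
  extrapolated <- sort(unique(newdata[[area_col]][is.na(a_idx)]))
  u_extra <- NULL
  if (length(extrapolated)) {
    # one stationary-prior draw per unseen area per posterior draw,
    # shared by all of that area's records within a draw
    sd_stat <- fit$draws$sigma / sqrt(1 - fit$draws$rho^2)
    ue <- vapply(seq_along(extrapolated),
                 function(j) rnorm(fit$n_draws, 0, sd_stat),
                 numeric(fit$n_draws))          # S x n_new_areas
    row_area <- match(newdata[[area_col]], extrapolated)
    u_extra <- t(ue)[row_area, , drop = FALSE]  # n x S (NA rows unused)
    message("areas not in the fit, using AR(1) prior draws ",
            "(extrapolation): ", paste(extrapolated, collapse = ", "))
  }
  list(X = des$X, a_idx = a_idx, t_idx = des$round_index,
       u_extra = u_extra, extrapolated = extrapolated)
}

#' Predict use probabilities
#'
#' @param object `bhm` fit.
#' @param newdata optional new records; `NULL` for the estimation data.
#' @param type `"response"` (probability) or `"link"` (logit scale).
#' @param draws if `TRUE`, return the full n x S draw matrix; otherwise a
#'   data frame of posterior median and equal-tailed 95% interval.
#' @param ... unused.
#' @export
predict.bhm <- function(object, newdata = NULL,
                        type = c("response", "link"), draws = FALSE, ...) {
  type <- match.arg(type)
  ctx <- .predict_context(object, newdata)
  out <- matrix(NA_real_, nrow(ctx$X), object$n_draws)
  .p_block_apply(object, ctx$X, ctx$a_idx, ctx$t_idx,
                 function(Pb, sb) out[, sb] <<- Pb,
                 u_extra = ctx$u_extra, link = (type == "link"))
  if (draws) {
    attr(out, "extrapolated_areas") <- ctx$extrapolated
    return(out)
  }
  data.frame(median = apply(out, 1, median),
             lower = apply(out, 1, quantile, 0.025),
             upper = apply(out, 1, quantile, 0.975))
}

#' @export
fitted.bhm <- function(object, ...) {
  acc <- numeric(nrow(object$X))
  .p_block_apply(object, object$X, object$area_index,
                 object$round_index,
                 function(Pb, sb) acc <<- acc + rowSums(Pb))
  acc / object$n_draws
}

#' Posterior predictive outcome draws
#'
#' Draws replicate outcome vectors: for each simulation a posterior draw
#' s is sampled and `y* ~ Bernoulli(P^(s))` generated record-wise.
#'
#' @param object `bhm` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return n x nsim integer matrix.
#' @export
simulate.bhm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s_idx <- sample.int(object$n_draws, nsim, replace = TRUE)
  n <- nrow(object$X)
  out <- matrix(NA_integer_, n, nsim)
  for (j in seq_len(nsim)) {
    sb <- s_idx[j]
    eta <- drop(object$X %*% object$draws$beta[sb, ]) +
      object$draws$u[sb, (object$round_index - 1L) *
                       length(object$areas) + object$area_index]
    out[, j] <- rbinom(n, 1, plogis(eta))
  }
  out
}

#' Residuals of the fitted model
#'
#' `type = "pearson"` gives woman-level Pearson residuals against the
#' posterior mean probability; `type = "z"` gives the unit-level
#' posterior-predictive standardized residuals of [z_values()] at the
#' fit's area level.
#'
#' @param object `bhm` fit.
#' @param type `"pearson"` or `"z"`.
#' @param ... passed to [z_values()] for `type = "z"`.
#' @export
residuals.bhm <- function(object, type = c("pearson", "z"), ...) {
  type <- match.arg(type)
  if (type == "z") return(z_values(object, level = object$area_level, ...))
  p <- fitted(object)
  (object$data$y - p) / sqrt(p * (1 - p))
}
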