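# --- convergence diagnostics -------------------------------------------

# draws as an iterations x chains matrix
.chain_matrix <- function(x, chain) {
  ch <- sort(unique(chain))
  do.call(cbind, lapply(ch, function(c) x[chain == c]))
}

.rank_normalize <- function(m) {
  z <- qnorm((rank(m) - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

.split_chains <- function(m) {
  n <- nrow(m) %/% 2
  cbind(m[seq_len(n), , drop = FALSE],
        m[(nrow(m) - n + 1):nrow(m), , drop = FALSE])
}

#' Potential scale reduction factor (R-hat)
#'
#' Rank-normalized split R-hat: each chain is split in half, the pooled
#' draws are transformed to normal scores, and the classic
#' between/within-chain variance ratio is computed on the transformed
#' half-chains. Values are floored at 1, so chains in exact agreement
#' report 1.0.
#'
#' @param x numeric matrix of draws, iterations x chains (a vector is
#'   treated as one chain).
#' @param split split each chain in half (recommended; detects
#'   within-chain trends). `split = FALSE` gives the classic variant.
#' @param rank_normalize transform to normal scores first (robust to
#'   heavy tails).
#' @return R-hat value (`NA` for constant draws).
#' @export
rhat <- function(x, split = TRUE, rank_normalize = TRUE) {
  m <- as.matrix(x)
  if (split) m <- .split_chains(m)
  if (all(m == m[1])) return(NA_real_)
  if (rank_normalize) m <- .rank_normalize(m)
  n <- nrow(m)
  mu <- colMeans(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(mu)
  if (W == 0) return(NA_real_)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(max(var_plus / W, 1))
}

#' Bulk effective sample size
#'
#' Rank-normalized split-chain effective sample size using the
#' multi-chain autocorrelation estimate with Geyer's initial monotone
#' positive sequence truncation.
#'
#' @inheritParams rhat
#' @return Effective number of draws (`NA` for constant draws).
#' @export
ess_bulk <- function(x, split = TRUE, rank_normalize = TRUE) {
  m <- as.matrix(x)
  if (split) m <- .split_chains(m)
  if (all(m == m[1])) return(NA_real_)
  if (rank_normalize) m <- .rank_normalize(m)
  n <- nrow(m); M <- ncol(m)
  if (n < 4) return(NA_real_)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(NA_real_)
  max_lag <- n - 1
  acov <- vapply(seq_len(M), function(c)
    acf(m[, c], lag.max = max_lag, type = "covariance",
        plot = FALSE, demean = TRUE)$acf[, 1, 1], numeric(max_lag + 1))
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[i] = lag i-1
  # Geyer: paired sums Gamma_k = rho_{2k} + rho_{2k+1}, kept while
  # positive and enforced non-increasing
  tau <- -1
  prev <- Inf
  k <- 0
  while (2 * k + 2 <= length(rho)) {
    G <- rho[2 * k + 1] + rho[2 * k + 2]
    if (!is.finite(G) || G <= 0) break
    G <- min(G, prev)
    tau <- tau + 2 * G
    prev <- G
    k <- k + 1
  }
  M * n / max(tau, 1e-12)
}

#' Convergence report
#'
#' Per-parameter rank-normalized split R-hat and bulk effective sample
#' size for every fixed effect, `rho`, `sigma` and each area-round
#' effect, with pass/fail flags against the default thresholds (warn at
#' R-hat 1.05, fail at 1.1; ESS at least 100).
#'
#' @param fit `bhm` object.
#' @param include_u include the area-effect cells.
#' @param rhat_warn,rhat_fail,ess_min thresholds.
#' @param quiet suppress the single-chain note.
#' @return Data frame `parameter`, `rhat`, `ess`, `status`; attribute
#'   `"pass"` is `TRUE` when nothing fails.
#' @export
convergence_report <- function(fit, include_u = TRUE, rhat_warn = 1.05,
                               rhat_fail = 1.1, ess_min = 100,
                               quiet = FALSE) {
  stopifnot(inherits(fit, "bhm"))
  if (fit$n_chains < 2 && !quiet)
    message("single chain: diagnostics use split halves only")
  pars <- cbind(fit$draws$beta, rho = fit$draws$rho,
                sigma = fit$draws$sigma)
  if (include_u) pars <- cbind(pars, fit$draws$u)
  res <- data.frame(parameter = colnames(pars),
                    rhat = NA_real_, ess = NA_real_, row.names = NULL)
  for (j in seq_len(ncol(pars))) {
    cm <- .chain_matrix(pars[, j], fit$chain)
    res$rhat[j] <- rhat(cm)
    res$ess[j] <- ess_bulk(cm)
  }
  res$status <- ifelse(is.na(res$rhat), "constant",
                ifelse(res$rhat > rhat_fail, "fail",
                ifelse(res$rhat > rhat_warn | res$ess < ess_min,
                       "warn", "ok")))
  attr(res, "pass") <- !any(res$status == "fail")
  attr(res, "single_chain") <- fit$n_chains < 2
  res
}

# --- posterior-predictive Z-values -------------------------------------

#' Unit-level posterior-predictive standardized residuals (Z-values)
#'
#' For each area-round (or region-round) cell the observed user count is
#' compared with its posterior-predictive distribution:
#' `Z = (observed - predictive mean) / predictive SD`. The analytic route
#' uses, per draw, the predictive moments `sum(P)` and `sum(P (1 - P))`
#' of the cell count and combines them across draws by the law of total
#' variance; the simulation route draws Bernoulli replicates per draw.
#' Under a well-specified model the Z-values are approximately standard
#' normal across units, so extreme values flag cells the model fails to
#' explain. This posterior-predictive construction is this package's
#' definition of the Z diagnostic.
#'
#' With `u_rep = "posterior"` the cell's own estimated effect enters the
#' replication; because that effect absorbs much of the cell's deviation,
#' such Z-values are conservative (variance well below 1 even for a
#' correct model). The default `u_rep = "prior"` is the mixed replication
#' of Marshall and Spiegelhalter: each draw's area effects are re-drawn
#' from their stationary AR(1) prior given that draw's (rho, sigma), so
#' under a correct model the Z-values are calibrated (mean ~ 0,
#' variance ~ 1) and extreme areas stand out.
#'
#' @param fit `bhm` object.
#' @param level `"ea"` or `"region"`.
#' @param rounds rounds to include (default all).
#' @param method `"analytic"` (default) or `"simulate"`.
#' @param u_rep `"prior"` (mixed replication, calibrated; default) or
#'   `"posterior"` (conditional on the estimated area effects).
#' @param seed optional seed for the replication draws.
#' @return Data frame `unit_id`, `round`, `n`, `observed`, `pred_mean`,
#'   `pred_sd`, `z`.
#' @references Marshall, E.C. and Spiegelhalter, D.J. (2007)
#'   Identifying outliers in Bayesian hierarchical models: a
#'   simulation-based approach. Bayesian Analysis 2, 409-444.
#' @export
z_values <- function(fit, level = c("ea", "region"), rounds = NULL,
                     method = c("analytic", "simulate"),
                     u_rep = c("prior", "posterior"), seed = NULL) {
  stopifnot(inherits(fit, "bhm"))
  level <- match.arg(level)
  method <- match.arg(method)
  u_rep <- match.arg(u_rep)
  if (!is.null(seed)) set.seed(seed)
  rounds <- rounds %||% fit$rounds
  if (u_rep == "prior") {
    # replicate the whole u field from its AR(1) prior, draw by draw
    K <- length(fit$areas); T <- length(fit$rounds)
    S <- fit$n_draws
    sd_stat <- fit$draws$sigma / sqrt(1 - fit$draws$rho^2)
    us <- matrix(rnorm(S * K, 0, rep(sd_stat, each = K)), S * K, T)
    if (T > 1)
      for (t in 2:T)
        us[, t] <- rep(fit$draws$rho, each = K) * us[, t - 1] +
          rnorm(S * K, 0, rep(fit$draws$sigma, each = K))
    # reshape to S x (K*T), areas fastest, matching the draw layout
    urep <- matrix(NA_real_, S, K * T)
    for (t in seq_len(T))
      urep[, (t - 1) * K + seq_len(K)] <- t(matrix(us[, t], K, S))
    fit$draws$u <- urep
  }
  keep <- fit$data$round %in% rounds
  unit <- if (level == "ea") fit$data$ea_id else fit$data$region_id
  g <- factor(paste(unit, fit$data$round, sep = "|"))
  g[!keep] <- NA
  gl <- levels(droplevels(g))
  gi <- match(g, gl)
  S <- fit$n_draws
  mu <- matrix(0, length(gl), S)  # per-draw predictive mean count
  vv <- matrix(0, length(gl), S)  # per-draw predictive variance
  sel <- !is.na(gi)
  .p_block_apply(fit, fit$X, fit$area_index, fit$round_index,
                 function(Pb, sb) {
                   if (method == "analytic") {
                     mu[, sb] <<- rowsum(Pb[sel, , drop = FALSE],
                                         gi[sel])
                     vv[, sb] <<- rowsum((Pb * (1 - Pb))[sel, ,
                                                         drop = FALSE],
                                         gi[sel])
                   } else {
                     Yb <- matrix(rbinom(length(Pb), 1, Pb),
                                  nrow(Pb), ncol(Pb))
                     mu[, sb] <<- rowsum(Yb[sel, , drop = FALSE],
                                         gi[sel])
                   }
                 })
  if (method == "analytic") {
    pm <- rowMeans(mu)
    pv <- rowMeans(vv) + apply(mu, 1, var)
  } else {
    pm <- rowMeans(mu)
    pv <- apply(mu, 1, var)
  }
  parts <- do.call(rbind, strsplit(gl, "|", fixed = TRUE))
  obs <- as.vector(rowsum(fit$data$y[sel], gi[sel]))
  n_cell <- as.vector(rowsum(rep(1L, sum(sel)), gi[sel]))
  data.frame(unit_id = parts[, 1], round = as.integer(parts[, 2]),
             n = n_cell, observed = obs, pred_mean = pm,
             pred_sd = sqrt(pv), z = (obs - pm) / sqrt(pv),
             row.names = NULL)
}

# --- shrinkage ---------------------------------------------------------

#' Shrinkage comparison of direct and model-based estimates
#'
#' Joins, per unit-round, the design-based direct estimate, the model
#' posterior, and the covariate-only regression prediction (all random
#' effects zeroed). Hierarchical shrinkage pulls unstable direct
#' estimates toward the regression surface — strongly for small cells,
#' weakly for large ones — and narrows the uncertainty interval; the
#' `shrinkage` and `width_ratio` columns quantify both effects.
#'
#' @param fit `bhm` object.
#' @param level `"ea"` (direct = unweighted ratio with Wilson interval)
#'   or `"region"` (weighted with clustered interval).
#' @param ui_level interval level.
#' @return Data frame with one row per unit-round: sample size, direct
#'   estimate and interval, model median and interval, regression-only
#'   prediction, `shrinkage` = |model - direct| and `width_ratio` =
#'   model interval width / direct interval width.
#' @export
shrinkage_table <- function(fit, level = c("ea", "region"),
                            ui_level = 0.95) {
  stopifnot(inherits(fit, "bhm"))
  level <- match.arg(level)
  direct <- direct_table(fit$data, level,
                         use_weights = (level == "region"), ui_level)
  unit <- if (level == "ea") fit$data$ea_id else fit$data$region_id
  g <- paste(unit, fit$data$round, sep = "|")
  w <- if (level == "region") fit$data$weight else
    rep(1, nrow(fit$data))
  gf <- factor(g)
  den <- as.vector(rowsum(w, gf))
  bhm_d <- matrix(0, nlevels(gf), fit$n_draws)
  reg_d <- matrix(0, nlevels(gf), fit$n_draws)
  .p_block_apply(fit, fit$X, fit$area_index, fit$round_index,
                 function(Pb, sb)
                   bhm_d[, sb] <<- rowsum(Pb * w, gf) / den)
  .p_block_apply(fit, fit$X, fit$area_index, fit$round_index,
                 function(Pb, sb)
                   reg_d[, sb] <<- rowsum(Pb * w, gf) / den,
                 zero_u = TRUE)
  a <- (1 - ui_level) / 2
  key <- paste(direct$unit_id, direct$round, sep = "|")
  idx <- match(key, levels(gf))
  out <- data.frame(
    unit_id = direct$unit_id, round = direct$round, n = direct$n,
    direct = direct$estimate, direct_lower = direct$ui_lower,
    direct_upper = direct$ui_upper,
    bhm = apply(bhm_d[idx, , drop = FALSE], 1, median),
    bhm_lower = apply(bhm_d[idx, , drop = FALSE], 1, quantile, a),
    bhm_upper = apply(bhm_d[idx, , drop = FALSE], 1, quantile, 1 - a),
    reg_pred = apply(reg_d[idx, , drop = FALSE], 1, median),
    row.names = NULL)
  out$shrinkage <- abs(out$bhm - out$direct)
  out$width_ratio <- (out$bhm_upper - out$bhm_lower) /
    (out$direct_upper - out$direct_lower)
  out
}

#' Diagnostic plots
#'
#' `type = "shrinkage"` draws direct versus model-based estimates per
#' unit-round, point area scaled by sample size, with the identity line:
#' points pulled off the diagonal toward the regression surface are the
#' shrinkage effect. `type = "trend"` plots the regional prevalence
#' trajectories over rounds with the national trajectory emphasized.
#'
#' @param x `bhm` object.
#' @param type `"shrinkage"` or `"trend"`.
#' @param level unit level for the shrinkage plot.
#' @param ... passed on to the underlying plotting calls.
#' @export
plot.bhm <- function(x, type = c("shrinkage", "trend"),
                     level = c("ea", "region"), ...) {
  type <- match.arg(type)
  if (type == "shrinkage") {
    st <- shrinkage_table(x, match.arg(level))
    graphics::plot(st$direct, st$bhm, cex = 0.5 + 1.5 * sqrt(st$n) /
                     sqrt(max(st$n)),
                   xlab = "direct estimate", ylab = "model estimate",
                   main = "Shrinkage toward the regression surface",
                   xlim = 0:1, ylim = 0:1, ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    tab <- mcpr_table(x)
    regions <- setdiff(unique(tab$region_id), "ALL")
    mat <- vapply(regions, function(r)
      tab$mcpr[tab$region_id == r][order(tab$round[tab$region_id == r])],
      numeric(length(x$rounds)))
    graphics::matplot(x$rounds, mat, type = "b", pch = 1, lty = 1,
                      col = "grey50", xlab = "round",
                      ylab = "mCPR (posterior median)",
                      main = "Regional trends", ...)
    all_m <- tab$mcpr[tab$region_id == "ALL"][order(
      tab$round[tab$region_id == "ALL"])]
    graphics::lines(x$rounds, all_m, lwd = 3)
  }
  invisible(x)
}
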