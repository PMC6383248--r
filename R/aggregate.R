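# per-draw weighted mean of P over a grouping of records; returns
# G x S matrix (one row per group) computed in draw blocks
.group_mcpr_draws <- function(fit, group, weights) {
  g <- factor(group)
  den <- rowsum(weights, g)
  out <- matrix(NA_real_, nlevels(g), fit$n_draws,
                dimnames = list(levels(g), NULL))
  .p_block_apply(fit, fit$X, fit$area_index, fit$round_index,
                 function(Pb, sb)
                   out[, sb] <<- rowsum(Pb * weights, g) / as.vector(den))
  out
}

.post_summary <- function(draws, ui_level = 0.95) {
  a <- (1 - ui_level) / 2
  c(point = unname(median(draws)),
    lower = unname(quantile(draws, a)),
    upper = unname(quantile(draws, 1 - a)))
}

#' Aggregate probability draws to regional or national prevalence
#'
#' For each posterior draw s the regional (or national) mCPR is the
#' survey-weight-weighted mean of the woman-level probability draws
#' `P^(s)` over the records of that level and round; the posterior of the
#' aggregate is summarized by its median and equal-tailed 95% interval.
#' The target population is the sampled women (no post-stratification).
#'
#' @param fit `bhm` object.
#' @param level `"region"` or `"national"`.
#' @param round survey round (one of the fitted rounds).
#' @param region region identifier (required for `level = "region"`).
#' @param use_weights use the survey weights (default) or uniform weights.
#' @param ui_level credible-interval mass.
#' @return Object of class `mcpr_posterior`: region (or `"ALL"`), round,
#'   the length-S draw vector, posterior median and interval, and the
#'   cell sample size.
#' @seealso [mcpr_table()], [change_posterior()], [prob_target()]
#' @export
aggregate_mcpr <- function(fit, level = c("region", "national"), round,
                           region = NULL, use_weights = TRUE,
                           ui_level = 0.95) {
  stopifnot(inherits(fit, "bhm"))
  level <- match.arg(level)
  if (level == "region" && is.null(region))
    stop("region must be given for level = 'region'")
  rid <- if (level == "region") region else "ALL"
  sel <- fit$data$round == round
  if (level == "region") sel <- sel & fit$data$region_id == region
  if (!any(sel))
    stop("empty cell: no records for ", rid, " in round ", round)
  w <- if (use_weights) fit$data$weight else rep(1, nrow(fit$data))
  w[!sel] <- 0
  draws <- drop(.group_mcpr_draws(fit, rep(1, nrow(fit$data)), w))
  s <- .post_summary(draws, ui_level)
  structure(list(region_id = rid, round = round, draws = draws,
                 point = s["point"], lower = s["lower"],
                 upper = s["upper"], ui_level = ui_level,
                 n = sum(sel), fit_id = fit$id),
            class = "mcpr_posterior")
}

#' @export
print.mcpr_posterior <- function(x, ...) {
  cat(sprintf("mCPR posterior, %s round %s: %.1f%% (%d%% UI %.1f-%.1f), n = %d\n",
              x$region_id, x$round, 100 * x$point, round(100 * x$ui_level),
              100 * x$lower, 100 * x$upper, x$n))
  invisible(x)
}

#' Regional and national prevalence table for all rounds
#'
#' One blocked pass over the posterior produces, for every region and
#' round plus the national `"ALL"` row, the posterior median mCPR and
#' equal-tailed 95% interval — the layout of a round-by-region estimates
#' table.
#'
#' @param fit `bhm` object.
#' @param use_weights use survey weights in the aggregation.
#' @param ui_level credible-interval mass.
#' @return Data frame with columns `region_id`, `round`, `mcpr`, `lower`,
#'   `upper`, `n`; attribute `"draws"` holds the G x S matrix of
#'   aggregate draws (rownames `region|round`).
#' @export
mcpr_table <- function(fit, use_weights = TRUE, ui_level = 0.95) {
  stopifnot(inherits(fit, "bhm"))
  w <- if (use_weights) fit$data$weight else rep(1, nrow(fit$data))
  g_reg <- paste(fit$data$region_id, fit$data$round, sep = "|")
  g_all <- paste("ALL", fit$data$round, sep = "|")
  dr <- rbind(.group_mcpr_draws(fit, g_reg, w),
              .group_mcpr_draws(fit, g_all, w))
  parts <- do.call(rbind, strsplit(rownames(dr), "|", fixed = TRUE))
  sm <- t(apply(dr, 1, .post_summary, ui_level))
  reg_names <- levels(factor(g_reg))
  all_names <- levels(factor(g_all))
  n_cell <- c(as.integer(table(g_reg)[reg_names]),
              as.integer(table(g_all)[all_names]))
  out <- data.frame(region_id = parts[, 1],
                    round = as.integer(parts[, 2]),
                    mcpr = sm[, "point"], lower = sm[, "lower"],
                    upper = sm[, "upper"],
                    n = as.integer(n_cell), row.names = NULL)
  out <- out[order(out$region_id != "ALL", out$region_id, out$round), ]
  rownames(out) <- NULL
  attr(out, "draws") <- dr
  attr(out, "fit_id") <- fit$id
  out
}

#' Posterior of the change in prevalence between two rounds
#'
#' The difference is computed within each joint posterior draw, so the
#' serial correlation induced by the AR(1) area effects is respected: the
#' interval of the change is generally not the difference of the two
#' rounds' intervals, and the median change need not equal the change in
#' medians.
#'
#' @param post_t0,post_t1 `mcpr_posterior` objects for the same region
#'   from the same fit (draw-aligned).
#' @param ui_level credible-interval mass.
#' @return Object of class `mcpr_change`: draw-wise differences, median
#'   change, interval, and whether the interval excludes zero.
#' @export
change_posterior <- function(post_t0, post_t1, ui_level = 0.95) {
  stopifnot(inherits(post_t0, "mcpr_posterior"),
            inherits(post_t1, "mcpr_posterior"))
  if (!identical(post_t0$region_id, post_t1$region_id))
    stop("alignment error: posteriors are for different regions")
  if (length(post_t0$draws) != length(post_t1$draws) ||
      !identical(post_t0$fit_id, post_t1$fit_id))
    stop("alignment error: posteriors come from different fits ",
         "or have different draw counts")
  d <- post_t1$draws - post_t0$draws
  s <- .post_summary(d, ui_level)
  structure(list(region_id = post_t0$region_id,
                 rounds = c(post_t0$round, post_t1$round), draws = d,
                 median = s["point"], lower = s["lower"],
                 upper = s["upper"], ui_level = ui_level,
                 excludes_zero = unname(s["lower"] > 0 | s["upper"] < 0)),
            class = "mcpr_change")
}

#' @export
print.mcpr_change <- function(x, ...) {
  cat(sprintf(
    "mCPR change, %s rounds %s -> %s: %+.1f points (%d%% UI %+.1f to %+.1f)%s\n",
    x$region_id, x$rounds[1], x$rounds[2], 100 * x$median,
    round(100 * x$ui_level), 100 * x$lower, 100 * x$upper,
    if (x$excludes_zero) " [UI excludes 0]" else ""))
  invisible(x)
}

#' Round-to-round change for every region
#'
#' @param fit `bhm` object.
#' @param t0,t1 rounds to compare (defaults: first and last).
#' @param use_weights use survey weights in the aggregation.
#' @param ui_level credible-interval mass.
#' @return Data frame `region_id`, `change`, `lower`, `upper`,
#'   `excludes_zero`, including the national `"ALL"` row.
#' @export
change_table <- function(fit, t0 = NULL, t1 = NULL, use_weights = TRUE,
                         ui_level = 0.95) {
  stopifnot(inherits(fit, "bhm"))
  t0 <- t0 %||% fit$rounds[1]
  t1 <- t1 %||% fit$rounds[length(fit$rounds)]
  tab <- mcpr_table(fit, use_weights, ui_level)
  dr <- attr(tab, "draws")
  regions <- unique(sub("\\|.*$", "", rownames(dr)))
  out <- do.call(rbind, lapply(regions, function(r) {
    d <- dr[paste(r, t1, sep = "|"), ] - dr[paste(r, t0, sep = "|"), ]
    s <- .post_summary(d, ui_level)
    data.frame(region_id = r, change = s["point"], lower = s["lower"],
               upper = s["upper"],
               excludes_zero = unname(s["lower"] > 0 | s["upper"] < 0),
               row.names = NULL)
  }))
  out <- out[order(out$region_id != "ALL", out$region_id), ]
  rownames(out) <- NULL
  attr(out, "rounds") <- c(t0, t1)
  out
}

#' Probability of exceeding a target
#'
#' Fraction of posterior draws strictly above `target` — e.g. the
#' probability that a region has reached a programmatic prevalence goal,
#' or that the change between rounds is positive.
#'
#' @param post `mcpr_posterior` or `mcpr_change` object.
#' @param target threshold on the same scale as the draws (proportion).
#' @return Probability in \[0, 1\].
#' @export
prob_target <- function(post, target) {
  stopifnot(inherits(post, "mcpr_posterior") ||
              inherits(post, "mcpr_change"))
  mean(post$draws > target)
}
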