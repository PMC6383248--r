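#' Wilson score interval for a binomial proportion
#'
#' Respects the \[0, 1\] bounds and behaves sensibly at 0 and n successes,
#' which Wald intervals do not.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level.
#' @return Named vector `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

.direct_row <- function(level, unit_id, round, estimate, n, ui, ui_level,
                        clustered = NA) {
  data.frame(level = level, unit_id = unit_id, round = round,
             estimate = estimate, n = n, ui_lower = ui[["lower"]],
             ui_upper = ui[["upper"]], ui_level = ui_level,
             clustered = clustered, stringsAsFactors = FALSE)
}

#' Direct (design-based) estimate for one enumeration area
#'
#' The maximum-likelihood direct estimate: the number of users divided by
#' the EA sample size, unweighted, with a Wilson score interval.
#'
#' @param data woman-level data frame.
#' @param ea enumeration-area identifier.
#' @param round survey round.
#' @param ui_level interval level.
#' @return One-row data frame: `level`, `unit_id`, `round`, `estimate`,
#'   `n`, `ui_lower`, `ui_upper`, `ui_level`.
#' @export
ea_direct <- function(data, ea, round, ui_level = 0.95) {
  sel <- data$ea_id == ea & data$round == round
  if (!any(sel)) stop("empty cell: no records for EA ", ea,
                      " in round ", round)
  y <- data$y[sel]
  .direct_row("ea", ea, round, mean(y),
              length(y), wilson_interval(sum(y), length(y), ui_level),
              ui_level)
}

#' Direct estimate for a region (or nationally)
#'
#' Weighted proportion `sum(w y) / sum(w)` over the region-round records,
#' with variance by EA-clustered linearization and the interval formed on
#' the logit scale then back-transformed (falling back to a Wilson
#' interval at boundary estimates). With a single EA the interval cannot
#' account for clustering and is flagged `clustered = FALSE`.
#'
#' @param data woman-level data frame.
#' @param region region identifier, or `"ALL"` for the national estimate.
#' @param round survey round.
#' @param use_weights use the survey weights (default) or uniform.
#' @param ui_level interval level.
#' @return One-row data frame as in [ea_direct()], plus `clustered`.
#' @export
region_direct <- function(data, region, round, use_weights = TRUE,
                          ui_level = 0.95) {
  sel <- data$round == round
  if (!identical(region, "ALL")) sel <- sel & data$region_id == region
  if (!any(sel)) stop("empty cell: no records for region ", region,
                      " in round ", round)
  y <- data$y[sel]
  w <- if (use_weights) data$weight[sel] else rep(1, sum(sel))
  cl <- data$ea_id[sel]
  p <- sum(w * y) / sum(w)
  m <- length(unique(cl))
  n <- length(y)
  if (m > 1) {
    # Taylor linearization with EAs as clusters: score totals per cluster
    z_g <- tapply(w * (y - p), cl, sum) / sum(w)
    v <- m / (m - 1) * sum(z_g^2)
    clustered <- TRUE
  } else {
    v <- sum(w^2 * (y - p)^2) / sum(w)^2 * n / max(1, n - 1)
    clustered <- FALSE
  }
  z <- qnorm(1 - (1 - ui_level) / 2)
  if (p > 0 && p < 1 && v > 0) {
    se_logit <- sqrt(v) / (p * (1 - p))
    ui <- c(lower = plogis(qlogis(p) - z * se_logit),
            upper = plogis(qlogis(p) + z * se_logit))
  } else {
    ui <- wilson_interval(as.integer(p * n + 0.5), n, ui_level)
  }
  lvl <- if (identical(region, "ALL")) "national" else "region"
  .direct_row(lvl, region, round, p, n, ui, ui_level, clustered)
}

#' Direct estimates for all units of a level
#'
#' @param data woman-level data frame.
#' @param level `"ea"`, `"region"` or `"national"`.
#' @param use_weights for region/national estimates.
#' @param ui_level interval level.
#' @return Data frame with one row per unit-round cell, the same layout
#'   as the model-based tables so the two can be joined for shrinkage
#'   comparisons.
#' @export
direct_table <- function(data, level = c("ea", "region", "national"),
                         use_weights = TRUE, ui_level = 0.95) {
  level <- match.arg(level)
  rounds <- sort(unique(data$round))
  if (level == "ea") {
    cells <- unique(data[c("ea_id", "round")])
    out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
      ea_direct(data, cells$ea_id[i], cells$round[i], ui_level)))
  } else if (level == "region") {
    cells <- unique(data[c("region_id", "round")])
    out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
      region_direct(data, cells$region_id[i], cells$round[i],
                    use_weights, ui_level)))
  } else {
    out <- do.call(rbind, lapply(rounds, function(t)
      region_direct(data, "ALL", t, use_weights, ui_level)))
  }
  out <- out[order(out$unit_id, out$round), ]
  rownames(out) <- NULL
  out
}
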