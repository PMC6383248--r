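test_that("aggregate draws are the weighted means of probability draws", {
  fit <- shared_fit()
  P <- posterior_p(fit)
  sel <- fit$data$region_id == "R02" & fit$data$round == 2
  w <- fit$data$weight[sel]
  oracle <- drop(crossprod(w, P[sel, , drop = FALSE])) / sum(w)
  post <- aggregate_mcpr(fit, "region", round = 2, region = "R02")
  expect_equal(post$draws, oracle, tolerance = 1e-12)
  expect_equal(unname(post$point), median(oracle))
  expect_equal(unname(post$lower), unname(quantile(oracle, 0.025)))
  expect_error(aggregate_mcpr(fit, "region", round = 9, region = "R02"),
               "empty cell")
})

test_that("weights move the aggregate as a weighted mean should", {
  fit <- shared_fit()
  # force constant probabilities via hacked draws: P = plogis(round ints)
  fit0 <- fit
  fit0$draws$beta[] <- 0
  fit0$draws$u[] <- 0
  # two women, weights 1 and 3, P constant 0.5 each -> 0.5
  post <- aggregate_mcpr(fit0, "national", round = 1)
  expect_equal(unname(post$point), 0.5, tolerance = 1e-12)
  expect_equal(unname(post$upper - post$lower), 0)  # constant posterior
})

test_that("national draws are the weight-share mean of regional draws", {
  fit <- shared_fit()
  tab <- mcpr_table(fit)
  dr <- attr(tab, "draws")
  regions <- setdiff(unique(fit$data$region_id), "ALL")
  for (t in fit$rounds) {
    wr <- vapply(regions, function(r)
      sum(fit$data$weight[fit$data$region_id == r & fit$data$round == t]),
      1)
    nat <- colSums(dr[paste(regions, t, sep = "|"), ] * wr) / sum(wr)
    expect_equal(unname(nat), unname(dr[paste("ALL", t, sep = "|"), ]),
                 tolerance = 1e-12)
  }
})

test_that("change posterior is computed within draws", {
  fit <- shared_fit()
  p1 <- aggregate_mcpr(fit, "national", round = 1)
  p3 <- aggregate_mcpr(fit, "national", round = 3)
  ch <- change_posterior(p1, p3)
  expect_equal(ch$draws, p3$draws - p1$draws)
  # linearity of the mean, exact
  expect_equal(mean(ch$draws), mean(p3$draws) - mean(p1$draws),
               tolerance = 1e-12)
  # constant shift: degenerate change posterior
  p_shift <- p1
  p_shift$draws <- p1$draws + 0.05
  p_shift$round <- 2
  ch2 <- change_posterior(p1, p_shift)
  expect_equal(unname(ch2$median), 0.05, tolerance = 1e-12)
  expect_equal(unname(ch2$upper - ch2$lower), 0)
})

test_that("median of the change can differ from the change of medians", {
  mk <- function(draws, round) structure(
    list(region_id = "X", round = round, draws = draws,
         point = median(draws), lower = quantile(draws, 0.025),
         upper = quantile(draws, 0.975), ui_level = 0.95,
         n = length(draws), fit_id = "f"), class = "mcpr_posterior")
  t0 <- mk(c(0, 0, 0.8), 1)
  t1 <- mk(c(0, 0.9, 0.85), 4)
  ch <- change_posterior(t0, t1)
  expect_equal(unname(ch$median), median(c(0, 0.9, 0.05)))
  expect_false(isTRUE(all.equal(unname(ch$median),
                                median(t1$draws) - median(t0$draws))))
})

test_that("misaligned posteriors are rejected", {
  fit <- shared_fit()
  p1 <- aggregate_mcpr(fit, "region", round = 1, region = "R01")
  p2 <- aggregate_mcpr(fit, "region", round = 2, region = "R02")
  expect_error(change_posterior(p1, p2), "different regions")
  p3 <- aggregate_mcpr(fit, "region", round = 2, region = "R01")
  p3$draws <- p3$draws[1:100]
  expect_error(change_posterior(p1, p3), "alignment error")
  p4 <- aggregate_mcpr(fit, "region", round = 2, region = "R01")
  p4$fit_id <- "other-fit"
  expect_error(change_posterior(p1, p4), "alignment error")
})

test_that("prob_target counts draws strictly above the target", {
  post <- structure(list(region_id = "X", round = 1,
                         draws = c(0.1, 0.2, 0.3, 0.4)),
                    class = "mcpr_posterior")
  expect_equal(prob_target(post, 0.25), 0.5)
  expect_equal(prob_target(post, -1), 1)
  expect_equal(prob_target(post, 0.4), 0)
  fit <- shared_fit()
  p <- aggregate_mcpr(fit, "national", round = 1)
  expect_equal(prob_target(p, -1), 1)
})

test_that("UI is invariant to a consistent draw permutation", {
  fit <- shared_fit()
  p1 <- aggregate_mcpr(fit, "national", round = 1)
  p3 <- aggregate_mcpr(fit, "national", round = 3)
  set.seed(1)
  perm <- sample(length(p1$draws))
  q1 <- p1; q1$draws <- p1$draws[perm]
  q3 <- p3; q3$draws <- p3$draws[perm]
  ch <- change_posterior(p1, p3)
  chp <- change_posterior(q1, q3)
  expect_equal(unname(chp$lower), unname(ch$lower))
  expect_equal(unname(chp$upper), unname(ch$upper))
  expect_equal(unname(chp$median), unname(ch$median))
})

test_that("mcpr_table layout matches a round-by-region estimates table", {
  fit <- shared_fit()
  tab <- mcpr_table(fit)
  expect_setequal(unique(tab$region_id),
                  c("ALL", paste0("R0", 1:4)))
  expect_identical(nrow(tab), 5L * 3L)
  expect_true(all(tab$lower <= tab$mcpr & tab$mcpr <= tab$upper))
  expect_identical(tab$region_id[1:3], rep("ALL", 3))
  chg <- change_table(fit)
  expect_identical(nrow(chg), 5L)
  expect_true(all(chg$lower <= chg$change & chg$change <= chg$upper))
})
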