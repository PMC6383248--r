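test_that("identical seeds reproduce identical retained draws", {
  sim <- generate_dataset(generator_config(
    n_regions = 2, eas_per_region = 3, rounds = 2,
    women_per_round = 300, covariates = test_covariates(),
    beta = test_beta(2), seed = 9))
  f1 <- suppressWarnings(bhm(sim$data, covariates = test_covariates(),
                             chains = 2, iter = 80, warmup = 80,
                             seed = 31, quiet = TRUE))
  f2 <- suppressWarnings(bhm(sim$data, covariates = test_covariates(),
                             chains = 2, iter = 80, warmup = 80,
                             seed = 31, quiet = TRUE))
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$u, f2$draws$u)
  expect_identical(f1$draws$rho, f2$draws$rho)
  f3 <- suppressWarnings(bhm(sim$data, covariates = test_covariates(),
                             chains = 2, iter = 80, warmup = 80,
                             seed = 32, quiet = TRUE))
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("fit object is coherent and methods work", {
  fit <- shared_fit()
  expect_s3_class(fit, "bhm")
  expect_identical(ncol(fit$draws$beta), 5L)  # 3 intercepts + 2 covariates
  expect_identical(ncol(fit$draws$u), 12L * 3L)
  expect_identical(fit$n_draws, 400L)
  expect_named(coef(fit))
  sm <- summary(fit)
  expect_true(all(c("parameter", "median", "lower", "upper", "rhat",
                    "ess") %in% names(sm)))
  expect_true(all(sm$lower <= sm$median & sm$median <= sm$upper))
  expect_output(print(fit), "hierarchical logistic")
  ps <- predict(fit)
  expect_identical(nrow(ps), nrow(fit$data))
  expect_true(all(ps$lower <= ps$median & ps$median <= ps$upper))
})

test_that("probability draws equal the element-wise inverse logit oracle", {
  fit <- shared_fit()
  P <- posterior_p(fit)
  expect_true(all(P > 0 & P < 1))
  # brute force for three records and three draws
  K <- length(fit$areas)
  for (i in c(1L, 5L, 9L)) {
    for (s in c(1L, 100L, 400L)) {
      eta <- sum(fit$X[i, ] * fit$draws$beta[s, ]) +
        unname(fit$draws$u[s, (fit$round_index[i] - 1L) *
                             K + fit$area_index[i]])
      expect_equal(P[i, s], plogis(eta), tolerance = 1e-12)
    }
  }
})

test_that("zeroed draws give P = 0.5 and positive effects are monotone", {
  fit <- shared_fit()
  fit0 <- fit
  fit0$draws$beta[] <- 0
  fit0$draws$u[] <- 0
  expect_equal(unname(posterior_p(fit0)[3, c(1, 50)]), c(0.5, 0.5))
  # fixed positive coefficient on urban: raising it never lowers P
  fitm <- fit
  fitm$draws$beta[, "urban"] <- abs(fitm$draws$beta[, "urban"]) + 0.1
  nd0 <- fit$data; nd0$urban <- 0
  nd1 <- fit$data; nd1$urban <- 1
  P0 <- posterior_p(fitm, nd0)
  P1 <- posterior_p(fitm, nd1)
  expect_true(all(P1 >= P0))
})

test_that("unseen areas fall back to the AR(1) prior and are flagged", {
  fit <- shared_fit()
  nd <- fit$data[1:4, ]
  nd$ea_id <- "NEW_EA"
  nd$region_id <- "R01"
  set.seed(1)
  expect_message(P <- posterior_p(fit, nd), "extrapolation")
  expect_identical(attr(P, "extrapolated_areas"), "NEW_EA")
  expect_true(all(P > 0 & P < 1))
})

test_that("without heterogeneity the posterior area effects collapse to zero", {
  sim <- generate_dataset(generator_config(
    n_regions = 3, eas_per_region = 4, rounds = 2,
    women_per_round = 1500, covariates = test_covariates(),
    beta = test_beta(2), rho = 0, sigma = 1e-6, seed = 14))
  fit <- suppressWarnings(bhm(sim$data, covariates = test_covariates(),
                              chains = 2, iter = 150, warmup = 150,
                              seed = 3, quiet = TRUE))
  med_abs_u <- median(abs(apply(fit$draws$u, 2, median)))
  int_sd <- mean(apply(fit$draws$beta[, 1:2], 2, sd))
  expect_lt(med_abs_u, int_sd)
})

test_that("degenerate outcomes warn but still fit", {
  d <- make_women(region = rep(c("A", "B"), each = 10),
                  ea = rep(c("E1", "E2"), each = 10), round = 1L,
                  y = 0L, urban = rep(c(0, 1), 10),
                  age = runif(20, 15, 49))
  w <- capture_warnings(
    fit <- bhm(d, covariates = test_covariates(), chains = 1,
               iter = 50, warmup = 50, seed = 1, quiet = TRUE))
  expect_match(w, "degenerate", all = FALSE)
  expect_s3_class(fit, "bhm")
})

test_that("posterior interval width for area prevalence shrinks with n", {
  # one dataset with EA sizes 5, 25 and 100
  covs <- test_covariates()
  cfg <- generator_config(n_regions = 3, eas_per_region = 4, rounds = 2,
    women_per_ea = 100, covariates = covs, beta = test_beta(2),
    rho = 0.6, sigma = 0.5, seed = 77)
  sim <- generate_dataset(cfg)
  d <- sim$data
  eas <- sort(unique(d$ea_id))
  size <- setNames(rep(c(5, 25, 100), each = 4), eas)
  keep <- unlist(lapply(split(seq_len(nrow(d)),
                              paste(d$ea_id, d$round)), function(ix)
    ix[seq_len(size[[d$ea_id[ix[1]]]])]))
  d <- d[sort(keep), ]
  fit <- suppressWarnings(bhm(d, covariates = covs, chains = 2,
                              iter = 200, warmup = 200, seed = 5,
                              quiet = TRUE))
  st <- shrinkage_table(fit, "ea")
  w <- tapply(st$bhm_upper - st$bhm_lower, size[st$unit_id], mean)
  expect_true(w[["5"]] > w[["25"]] && w[["25"]] > w[["100"]])
})

test_that("posterior predictive simulation returns valid replicate outcomes", {
  fit <- shared_fit()
  yr <- simulate(fit, nsim = 3, seed = 2)
  expect_identical(dim(yr), c(nrow(fit$data), 3L))
  expect_true(all(yr %in% c(0L, 1L)))
  # replicate prevalence near observed prevalence
  expect_lt(abs(mean(yr) - mean(fit$data$y)), 0.05)
  r <- residuals(fit)
  expect_identical(length(r), nrow(fit$data))
})
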