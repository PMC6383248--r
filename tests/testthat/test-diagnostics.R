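test_that("potential scale reduction detects agreement and disagreement", {
  set.seed(4)
  one <- rnorm(1000)
  copies <- cbind(one, one, one, one)
  # exact copies: split-free variant reports exactly 1
  expect_identical(rhat(copies, split = FALSE), 1)
  # independent well-mixed chains
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(iid), 1.01)
  # one chain shifted far away
  shifted <- iid
  shifted[, 1] <- shifted[, 1] + 10
  expect_gt(rhat(shifted), 1.1)
  # within-chain trend is caught by splitting
  trend <- matrix(rep(seq(0, 1, length.out = 1000), 4) + rnorm(4000, 0,
                                                               0.01),
                  1000, 4)
  expect_gt(rhat(trend), 1.1)
})

test_that("effective sample size is near the draw count for iid chains", {
  set.seed(5)
  iid <- matrix(rnorm(4000), 1000, 4)
  e <- ess_bulk(iid)
  expect_gt(e, 2000)
  expect_lt(e, 6000)
  # strong autocorrelation cuts the ESS
  ar <- replicate(4, as.numeric(arima.sim(list(ar = 0.95), 1000)))
  expect_lt(ess_bulk(ar), 400)
})

test_that("convergence report covers all parameters with thresholds", {
  fit <- shared_fit()
  cr <- convergence_report(fit)
  expect_true(all(c("rho", "sigma", "round_1", "urban") %in%
                    cr$parameter))
  expect_identical(nrow(cr), 5L + 2L + 36L)  # beta + (rho, sigma) + u
  expect_true(all(cr$status %in% c("ok", "warn", "fail", "constant")))
  expect_type(attr(cr, "pass"), "logical")
})

test_that("Z-values center at zero when observed equals the prediction", {
  fit <- shared_fit()
  z1 <- z_values(fit, "ea", seed = 1)
  expect_identical(nrow(z1), 12L * 3L)
  # construction identity: z = (obs - mean)/sd
  expect_equal(z1$z, (z1$observed - z1$pred_mean) / z1$pred_sd,
               tolerance = 1e-12)
  expect_true(all(z1$pred_sd > 0))
})

test_that("analytic and simulated Z-values agree within Monte Carlo error", {
  fit <- shared_fit()
  za <- z_values(fit, "ea", method = "analytic", seed = 3)
  zs <- z_values(fit, "ea", method = "simulate", seed = 3)
  expect_identical(za$observed, zs$observed)
  expect_lt(max(abs(za$z - zs$z)), 0.5)
  expect_lt(mean(abs(za$z - zs$z)), 0.15)
})

test_that("an aberrant all-user area yields a large positive Z", {
  fit <- shared_fit()
  fit2 <- fit
  cell <- fit2$data$ea_id == "R01_EA001" & fit2$data$round == 1
  fit2$data$y[cell] <- 1L
  z <- z_values(fit2, "ea", seed = 2)
  zc <- z$z[z$unit_id == "R01_EA001" & z$round == 1]
  expect_gt(zc, 2)
})

test_that("conditional replication is conservative, mixed is not", {
  fit <- shared_fit()
  zp <- z_values(fit, "ea", u_rep = "posterior", seed = 1)
  zm <- z_values(fit, "ea", u_rep = "prior", seed = 1)
  expect_lt(var(zp$z), var(zm$z))
})

test_that("shrinkage pulls small areas harder and sits between the anchors", {
  fit <- shared_fit()
  st <- shrinkage_table(fit, "ea")
  expect_identical(nrow(st), 36L)
  expect_true(all(st$width_ratio >= 0))
  # model estimate between the direct estimate and the regression
  # surface; the slack covers Monte-Carlo error of posterior medians
  # at the shared fit's 400 retained draws
  eps <- 0.03
  lo <- pmin(st$direct, st$reg_pred) - eps
  hi <- pmax(st$direct, st$reg_pred) + eps
  expect_gte(mean(st$bhm >= lo & st$bhm <= hi), 0.95)
})

test_that("report writer emits the full table set", {
  fit <- shared_fit()
  dir <- file.path(tempdir(), "rep-test")
  files <- report_bhm(fit, dir)
  expect_true(all(file.exists(files)))
  est <- read.csv(file.path(dir, "estimates_by_round.csv"))
  expect_true(all(c("region_id", "round", "mcpr", "lower", "upper") %in%
                    names(est)))
  expect_true(all(est$mcpr >= 0 & est$mcpr <= 100))  # percent scale
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_identical(meta$package, "mcprsae")
  expect_true(nzchar(meta$config_md5))
})

test_that("draw persistence round-trips through CSV + JSON", {
  fit <- shared_fit()
  dcsv <- tempfile(fileext = ".csv")
  mjson <- tempfile(fileext = ".json")
  write_draws(fit, dcsv)
  write_model_meta(fit, mjson)
  fit2 <- bhm_restore(shared_sim()$data, mjson, dcsv)
  expect_equal(fit2$draws$beta, fit$draws$beta, tolerance = 1e-12)
  expect_equal(unname(fit2$draws$rho), unname(fit$draws$rho),
               tolerance = 1e-12)
  tab1 <- mcpr_table(fit)
  tab2 <- mcpr_table(fit2)
  expect_equal(tab2$mcpr, tab1$mcpr, tolerance = 1e-12)
})
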