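test_that("CSV round trip is the identity on valid tables", {
  d <- make_women(region = c("A", "A", "B"), ea = c("E1", "E1", "E2"),
                  round = c(1L, 2L, 1L), y = c(1L, 0L, 1L),
                  weight = c(1, 2.5, 0.75),
                  urban = c(1, 0, 1), age = c(21, 35, 42))
  f <- tempfile(fileext = ".csv")
  write_women(d, f)
  d2 <- read_women(f, test_covariates())
  expect_equal(d2, d)
})

test_that("reader rejects contract violations with informative errors", {
  covs <- test_covariates()
  base <- make_women(region = c("A", "B"), ea = c("E1", "E1"),
                     round = 1L, y = 0L, urban = 0, age = 30)
  f <- tempfile(fileext = ".csv")
  write_women(base, f)
  expect_error(read_women(f, covs), "nesting error.*E1")

  bad_y <- make_women(y = c(0L, 2L, 1L), urban = 0, age = 30)
  write_women(bad_y, f)
  expect_error(read_women(f, covs), "value error.*y outside.*2")

  no_col <- base[setdiff(names(base), "ea_id")]
  write.csv(no_col, f, row.names = FALSE)
  expect_error(read_women(f, covs), "schema error.*ea_id")

  expect_error(read_women(tempfile(), covs), "not found")
  expect_error(validate_women(make_women(weight = -1, urban = 0, age = 1),
                              covs), "weight")
})

test_that("empty covariate cells become NA and are dropped at model build", {
  d <- make_women(y = rep(0L, 4), urban = c(1, NA, 0, 1),
                  age = c(20, 30, NA, 40))
  f <- tempfile(fileext = ".csv")
  write_women(d, f)
  d2 <- read_women(f, test_covariates())
  expect_identical(sum(is.na(d2$urban)), 1L)
  expect_message(mf <- model_frame(d2, test_covariates()),
                 "dropped 2 row")
  expect_identical(nrow(mf), 2L)
  expect_identical(attr(mf, "dropped"), 2L)
})

test_that("profile counts match the survey structure", {
  # Ghana-like round 1: 10 regions, 94 EAs, 3460 women
  sim <- generate_dataset(generator_config(seed = 3))
  pr <- profile_dataset(sim$data)
  expect_equal(unlist(pr$per_round[1, c("n_regions", "n_eas", "n_women")]),
               c(n_regions = 10, n_eas = 94, n_women = 3460))
  expect_equal(pr$per_round$n_women, c(3460, 3645, 4251, 4801))
  expect_equal(pr$totals$n_women, 16157)
  # per-EA cell counts sum to the round totals
  expect_equal(unname(colSums(pr$n_kt)), pr$per_round$n_women)
})

test_that("profile is permutation invariant and flags partial EAs", {
  d <- make_women(region = "A", ea = rep(c("E1", "E2"), each = 4),
                  round = c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 2L), y = 0L)
  d$ea_id[8] <- "E1"  # E2 only in round 1
  pr <- profile_dataset(d)
  expect_identical(pr$unbalanced_eas, "E2")
  perm <- d[sample(nrow(d)), ]
  pr2 <- profile_dataset(perm)
  expect_equal(pr2$per_round, pr$per_round)
  expect_equal(pr2$n_kt, pr$n_kt)
  expect_error(profile_dataset(d[0, ]), "empty input")

  single <- make_women(ea = "E9", round = 1L, y = rep(0L, 5))
  pr3 <- profile_dataset(single)
  expect_equal(unlist(pr3$per_round[1, 2:4]),
               c(n_regions = 1, n_eas = 1, n_women = 5))
})

test_that("filter_balanced_eas keeps exactly the always-present EAs", {
  d <- make_women(region = "A",
                  ea = c("E1", "E1", "E2", "E2", "E3"),
                  round = c(1L, 2L, 1L, 2L, 1L), y = 0L)
  out <- filter_balanced_eas(d)
  expect_setequal(unique(out$ea_id), c("E1", "E2"))
  # idempotent; identity when already balanced
  expect_equal(filter_balanced_eas(out), out)
  d3 <- d[d$ea_id == "E3", ]
  d3$round <- 1L
  d_none <- rbind(d3, transform(d3, ea_id = "E4", round = 2L))
  expect_error(filter_balanced_eas(d_none), "all EAs unbalanced")
})

test_that("covariate specifications enforce their invariants", {
  expect_error(covariate_spec("x", "categorical", levels = "only"),
               ">= 2 levels")
  expect_error(covariate_spec("x", "categorical", levels = c("a", "b"),
                              reference = "c"), "reference")
  expect_identical(names(default_covariates()),
                   c("residence", "schooling", "wealth_quintile",
                     "child_survival", "age", "cohabitation",
                     "recent_sex", "health_worker_visit", "fp_message",
                     "fertility_intention", "parity",
                     "distance_facility"))
  d <- make_women(y = 0L, urban = 2, age = 1)
  expect_error(validate_women(d, test_covariates()), "outside \\{0,1\\}")
})
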