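reg <- default_registry()
ids <- reg$indicators$id
cap_ids <- unlist(reg$areas[reg$domains$capacity])

test_that("parent inheritance copies only missing cells", {
  d <- make_random_districts(4, seed = 1)
  child <- d
  child[2, cap_ids] <- NA
  out <- inherit_from_parent(child, c(d002 = "d001"), ids)
  expect_equal(unlist(out[2, cap_ids]), unlist(d[1, cap_ids]))
  # untouched cells stay put
  expect_equal(out$anc4, child$anc4)
  prov <- attr(out, "imputed_cells")
  expect_setequal(prov$indicator, cap_ids)
  expect_true(all(prov$method == "inherit"))

  # no missing values: a no-op
  expect_equal(inherit_from_parent(d, c(d002 = "d001"), ids)[ids], d[ids])
})

test_that("parent inheritance enforces its contract", {
  d <- make_random_districts(4, seed = 2)
  d$anc4[2] <- NA
  expect_error(inherit_from_parent(d, c(d002 = "ghost"), ids), "d002")
  # chain with the parent itself missing: single-step only
  d$anc4[3] <- NA
  err <- expect_error(
    inherit_from_parent(d, c(d002 = "d003", d003 = "d004"), "anc4"))
  expect_match(conditionMessage(err), "single-step")
  expect_error(inherit_from_parent(d, c(d002 = "d003", d003 = "d002"),
                                   "anc4"), "cyclic")
})

test_that("hot-deck draws stay inside the stratum donor support", {
  d <- make_random_districts(12, seed = 3)
  d$state_id <- rep(c("s1", "s2"), each = 6)
  d[2:4, cap_ids] <- NA          # recipients in s1
  donors <- d[c(1, 5, 6), cap_ids]
  out <- hot_deck(d, cap_ids, seed = 7)
  expect_false(anyNA(as.matrix(out[cap_ids])))
  for (i in 2:4) {
    expect_true(any(apply(donors, 1, function(row) {
      all(abs(row - unlist(out[i, cap_ids])) < 1e-12)
    })))
  }
  # s2 untouched
  expect_equal(out[7:12, ids], d[7:12, ids])
})

test_that("a single donor is always drawn; empty strata error", {
  d <- make_random_districts(5, seed = 4)
  d$state_id <- "s1"
  d[2:5, cap_ids] <- NA
  out <- hot_deck(d, cap_ids, seed = 1)
  for (i in 2:5) {
    expect_equal(unlist(out[i, cap_ids]), unlist(d[1, cap_ids]))
  }

  d2 <- make_random_districts(4, seed = 5)
  d2$state_id <- c("s1", "s1", "s2", "s2")
  d2[1:2, "beds"] <- NA  # s1 has recipients but no complete donor
  expect_error(hot_deck(d2, cap_ids, seed = 1), "s1")
  # documented global fallback
  out2 <- hot_deck(d2, cap_ids, seed = 1, fallback_global = TRUE)
  expect_false(anyNA(out2$beds))
})

test_that("two equally likely donors are used about half the time each", {
  n <- 1002
  d <- make_districts(n, 50)
  d$state_id <- "s1"
  d$beds[1] <- 10; d$beds[2] <- 90      # the two donors differ only here
  d$beds[3:n] <- NA
  out <- hot_deck(d, "beds", seed = 123)
  share_first <- mean(out$beds[3:n] == 10)
  expect_true(all(out$beds[3:n] %in% c(10, 90)))
  expect_lt(abs(share_first - 0.5), 0.05)
})

test_that("hot-deck is deterministic and leaves complete tables alone", {
  d <- make_random_districts(10, seed = 6)
  expect_identical(hot_deck(d, cap_ids, seed = 1), d)
  d[3, cap_ids] <- NA
  a <- hot_deck(d, cap_ids, seed = 9)
  b <- hot_deck(d, cap_ids, seed = 9)
  expect_identical(a, b)
})

test_that("regression imputation is exact on a noiseless linear target", {
  n <- 40
  d <- make_random_districts(n, seed = 7)
  d$state_id <- "s1"
  d$cat_expenditure <- 5 + 0.3 * d$insurance
  holes <- c(3, 10, 25)
  truth <- d$cat_expenditure[holes]
  d$cat_expenditure[holes] <- NA
  out <- regression_impute(d, "cat_expenditure", "insurance")
  expect_equal(out$cat_expenditure[holes], truth, tolerance = 1e-8)
  expect_equal(attr(out, "imputed_cells")$method, rep("regression", 3))
})

test_that("regression imputation recovers a noisy target near the noise floor", {
  set.seed(99)
  n <- 600
  d <- make_districts(n, 50)
  d$state_id <- rep(c("s1", "s2", "s3"), each = 200)
  x <- runif(n, 20, 80)
  d$insurance <- x
  d$impoverishment <- 20 + 0.5 * x + rnorm(n, 0, 1)
  holes <- sample(n, 100)
  truth <- d$impoverishment[holes]
  d$impoverishment[holes] <- NA
  out <- regression_impute(d, "impoverishment", "insurance")
  rmse <- sqrt(mean((out$impoverishment[holes] - truth)^2))
  expect_lt(rmse, 1.25)  # oracle noise SD is 1
})

test_that("regression fits clamp to [0, 100] and reject rank deficiency", {
  d <- make_districts(12, 50)
  d$state_id <- "s1"
  d$insurance <- c(seq(10, 20, length.out = 11), 2)
  d$cat_expenditure <- 0.5 * d$insurance - 2   # in range for x >= 10
  d$cat_expenditure[12] <- NA                  # fitted value = -1
  out <- regression_impute(d, "cat_expenditure", "insurance")
  expect_equal(out$cat_expenditure[12], 0)

  d2 <- make_random_districts(20, seed = 8)
  d2$dup <- d2$insurance
  d2$cat_expenditure[2] <- NA
  expect_error(regression_impute(d2, "cat_expenditure",
                                 c("insurance", "dup")),
               "rank-deficient")
})

test_that("imputation never alters non-missing cells and completes the table", {
  cfg <- simulation_config(seed = 31)
  d <- simulate_districts(cfg, reg)
  d <- inject_missingness(d, "by_domain", 0.05, seed = 32, registry = reg)
  d$cat_expenditure[5:9] <- NA
  before <- d
  out <- impute_all(d, reg, seed = 33)
  expect_false(anyNA(as.matrix(out[ids])))
  for (id in ids) {
    keep <- !is.na(before[[id]])
    expect_equal(out[[id]][keep], before[[id]][keep])
  }
  prov <- attr(out, "imputed_cells")
  expect_setequal(unique(prov$method), c("hotdeck", "regression"))
})
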