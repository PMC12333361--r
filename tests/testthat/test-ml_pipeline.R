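test_that("SNE class thresholds follow the closed-medium boundary convention", {
  expect_equal(as.character(classify_sne(c(10, 39.99, 40, 65, 90, 90.01, 120))),
               c("low", "low", "medium", "medium", "medium", "high", "high"))
  expect_error(classify_sne(-1), "domain error")
})

test_that("repeated-split classification is deterministic and row-normalized", {
  cs <- generate_class_structured(generator_params(seed = 4),
                                  n_sites = 100, separation = 1)
  c1 <- repeated_split_classification(cs, n_runs = 5, seed = 9)
  c2 <- repeated_split_classification(cs, n_runs = 5, seed = 9)
  expect_identical(c1$matrix, c2$matrix)
  expect_identical(c1$importances, c2$importances)
  expect_equal(unname(rowSums(c1$matrix)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(c1$matrix >= 0 & c1$matrix <= 1))
  expect_equal(sum(c1$importances), 1, tolerance = 1e-12)
})

test_that("well-separated classes are classified nearly perfectly", {
  cs <- generate_class_structured(generator_params(seed = 6),
                                  n_sites = 100, separation = 10)
  cc <- repeated_split_classification(cs, n_runs = 50, seed = 2)
  expect_true(all(diag(cc$matrix) >= 0.98))
})

test_that("uninformative features give chance-level classification", {
  cs <- generate_class_structured(generator_params(seed = 14),
                                  n_sites = 190, separation = 0)
  cc <- repeated_split_classification(cs, n_runs = 30, seed = 3)
  acc <- sum(diag(cc$counts)) / sum(cc$counts)
  prior <- max(attr(cs, "class_counts")) / 190
  expect_lt(abs(acc - prior), 0.12)
})

test_that("classification needs every class populated", {
  few <- tiny_table(sprintf("M%d", 1:6), "1",
                    fukui = runif(6), sne = c(10, 12, 14, 16, 18, 20))
  expect_error(repeated_split_classification(few, n_runs = 1, seed = 1),
               ">= 2 members")
})

test_that("performance_score reproduces its defining identities", {
  y <- c(3, 1, 4, 1, 5, 9)
  ps <- performance_score(y, y)
  expect_equal(ps$r_squared, 1)
  expect_equal(ps$rmse, 0)
  expect_equal(ps$mae, 0)
  null_ps <- performance_score(y, rep(mean(y), 6))
  expect_equal(null_ps$r_squared, 0)
  expect_error(performance_score(1:3, 1:4), "length mismatch")
  expect_error(performance_score(1, 1), "at least 2")
  set.seed(55)
  # independent standard Gaussian pairs: squared correlation ~ 0 and the
  # coefficient of determination ~ -1 (E[SS_res] = 2 SS_tot)
  indep <- performance_score(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(indep$pearson_r2), 0.03)
  expect_lt(abs(indep$r_squared + 1), 0.1)
})

test_that("ridge recovers a noiseless linear response almost perfectly", {
  tb <- linear_response_table()
  rep <- repeated_split_regression(tb, models = "ridge", n_runs = 3,
                                   seed = 10)
  expect_gte(rep[[1]]$composite_score, 0.999)
})

test_that("the regression suite is deterministic and validates model names", {
  lib <- generate_library(generator_params(seed = 18))
  r1 <- repeated_split_regression(lib$table, models = c("knn", "ridge"),
                                  n_runs = 3, seed = 11)
  r2 <- repeated_split_regression(lib$table, models = c("knn", "ridge"),
                                  n_runs = 3, seed = 11)
  expect_identical(lapply(r1, `[[`, "per_run_scores"),
                   lapply(r2, `[[`, "per_run_scores"))
  expect_identical(lapply(r1, `[[`, "importances"),
                   lapply(r2, `[[`, "importances"))
  for (r in r1) expect_equal(sum(r$importances), 1, tolerance = 1e-12)
  expect_error(repeated_split_regression(lib$table, models = "catboost"),
               "unknown model")
})
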