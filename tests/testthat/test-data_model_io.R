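test_that("a well-formed CSV round-trips through load_feature_table", {
  tb <- tiny_table("M1", c("1", "2", "3"), fukui = c(0.5, 0.3, 0.2),
                   sne = c(100, 20, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tb, path)
  back <- load_feature_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(as.data.frame(back), as.data.frame(tb),
               ignore_attr = TRUE)
})

test_that("write -> read preserves every numeric field exactly", {
  lib <- generate_library(generator_params(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(lib$table, path)
  back <- load_feature_table(path)
  for (cn in c(feature_names(), "sne")) {
    expect_identical(as.data.frame(back)[[cn]],
                     as.data.frame(lib$table)[[cn]], label = cn)
  }
})

test_that("schema and integrity errors are specific", {
  tb <- tiny_table("M1", c("1", "2"), fukui = c(0.6, 0.4), sne = c(50, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tb, path)
  raw <- read.csv(path, check.names = FALSE)
  raw$fukui <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path2, row.names = FALSE)
  expect_error(load_feature_table(path2), "fukui")

  df <- as.data.frame(tb)
  df$site_id <- c("1", "1")
  expect_error(feature_table(df), "duplicate")
})

test_that("rows with missing required fields are rejected and reported", {
  tb <- tiny_table("M1", c("1", "2", "3"), fukui = c(0.5, 0.3, 0.2),
                   sne = c(100, 20, 5))
  df <- as.data.frame(tb)
  df$sne[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feature_table(df), path)
  expect_warning(back <- load_feature_table(path), "rejected 1 row")
  expect_equal(nrow(back), 2)
  expect_equal(attr(back, "rejected_rows"), 2L)
})

test_that("validation reports violations and is idempotent", {
  lib <- generate_library(generator_params(seed = 9))
  rep1 <- validate_dataset(lib$table)
  expect_true(rep1$clean)
  expect_equal(rep1$n_molecules, 40)

  df <- as.data.frame(lib$table)
  df$sne[4] <- -5
  rep_bad <- validate_dataset(df)
  expect_false(rep_bad$clean)
  expect_equal(rep_bad$violations$row, 4L)
  expect_equal(rep_bad$violations$column, "sne")

  rep2 <- validate_dataset(lib$table)
  expect_identical(rep1[names(rep1) != "n_sites_per_molecule"],
                   rep2[names(rep2) != "n_sites_per_molecule"])
  expect_equal(rep1$n_sites_per_molecule, rep2$n_sites_per_molecule)
})

test_that("config enforces ordered thresholds and YAML round-trips", {
  expect_error(pipeline_config(class_thresholds = c(90, 40)), "thresholds")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(b0 = 9.4, random_seed = 7L,
                        class_thresholds = c(30, 80)), path)
  cfg <- read_config(path)
  expect_equal(cfg$b0, 9.4)
  expect_equal(cfg$class_thresholds, c(30, 80))
  expect_equal(cfg$g_dye, pipeline_config()$g_dye)
})

test_that("derived child seeds are deterministic, distinct, and 32-bit safe", {
  s1 <- derive_seed(123, "classify")
  expect_identical(s1, derive_seed(123, "classify"))
  expect_false(s1 == derive_seed(123, "regress"))
  expect_false(s1 == derive_seed(124, "classify"))
  expect_true(all(vapply(1:50, function(i) derive_seed(i, "x"), integer(1)) >= 0))
})
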