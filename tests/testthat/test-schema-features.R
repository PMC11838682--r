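# Cohort loading, difference features, stratified splitting, summaries.

write_fixture_files <- function(df, specs_list, outcome = "outcome") {
  dir <- tempfile("fixture")
  dir.create(dir)
  table_path <- file.path(dir, "cohort.csv")
  dict_path <- file.path(dir, "dict.yaml")
  utils::write.csv(df, table_path, row.names = FALSE, na = "")
  yaml::write_yaml(list(outcome = outcome, variables = specs_list),
                   dict_path)
  list(table = table_path, dict = dict_path)
}

test_that("load_cohort reads a dictionary-described table and normalizes missing markers", {
  df <- data.frame(a = c(1.5, NA, 3, 4), b = c("x", "y", "", "NaN"),
                   outcome = c(0, 1, 0, 1), stringsAsFactors = FALSE)
  paths <- write_fixture_files(df, list(
    list(name = "a", kind = "continuous", timepoint = "baseline"),
    list(name = "b", kind = "categorical")))
  co <- suppressMessages(load_cohort(paths$table, paths$dict))
  expect_s3_class(co, "cohort_table")
  expect_identical(co$y, c(0L, 1L, 0L, 1L))
  # empty cell and sentinel strings flagged missing, never zero
  expect_true(is.na(co$x$a[2]))
  expect_identical(is.na(co$x$b), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(co$specs$timepoint, c("baseline", "static"))
})

test_that("load_cohort accepts an arbitrary-size dictionary (135 variables)", {
  n_var <- 135
  df <- as.data.frame(matrix(rnorm(4 * n_var), 4,
                             dimnames = list(NULL, paste0("v", 1:n_var))))
  df$outcome <- c(0, 1, 0, 1)
  paths <- write_fixture_files(df, lapply(paste0("v", 1:n_var), function(nm) {
    list(name = nm, kind = "continuous")
  }))
  co <- suppressMessages(load_cohort(paths$table, paths$dict))
  expect_identical(nrow(co$specs), 135L)
  expect_identical(ncol(co$x), 135L)
})

test_that("schema violations are rejected", {
  df <- data.frame(a = 1:4, tri = c("x", "y", "z", "x"),
                   outcome = c(0, 1, 0, 1), stringsAsFactors = FALSE)
  # column declared in dictionary but absent from table
  paths <- write_fixture_files(df, list(
    list(name = "a", kind = "continuous"),
    list(name = "ghost", kind = "continuous")))
  expect_error(suppressMessages(load_cohort(paths$table, paths$dict)),
               "ghost")
  # binary column with three observed levels
  paths2 <- write_fixture_files(df, list(
    list(name = "tri", kind = "binary")))
  expect_error(suppressMessages(load_cohort(paths2$table, paths2$dict)),
               "binary")
  # missing/non-binary outcome is fatal
  df_bad <- transform(df, outcome = c(0, 1, 2, 0))
  paths3 <- write_fixture_files(df_bad, list(
    list(name = "a", kind = "continuous")))
  expect_error(suppressMessages(load_cohort(paths3$table, paths3$dict)),
               "binary 0/1")
})

test_that("difference features follow the baseline-minus-later contract", {
  df <- data.frame(
    `CRT Baseline` = c(0.60, 0.55, NA, 0.58),
    `CRT Acute` = c(0.70, NA, 0.62, 0.58),
    `HADS Baseline` = c(3, 4, 5, 6),  # baseline-only instrument
    outcome = c(1, 0, 1, 0), check.names = FALSE)
  specs <- variable_specs(
    c("CRT Baseline", "CRT Acute", "HADS Baseline"),
    kind = "continuous",
    timepoint = c("baseline", "acute", "baseline"))
  co <- cohort_table(df, specs)
  co2 <- suppressMessages(build_difference_features(co))
  expect_true("CRT Difference Baseline Acute" %in% co2$specs$name)
  d <- co2$x[["CRT Difference Baseline Acute"]]
  expect_equal(d[1], -0.10, tolerance = 1e-12)   # 0.60 - 0.70
  expect_true(is.na(d[2]) && is.na(d[3]))        # missingness propagates
  expect_identical(d[4], 0)                      # identical values
  # baseline-only measures yield no difference feature
  expect_false(any(grepl("HADS Difference", co2$specs$name)))
  # originals retained
  expect_true(all(co$specs$name %in% co2$specs$name))
})

test_that("difference features are anti-symmetric in their operands", {
  set.seed(7)
  b <- rnorm(20, 10)
  a <- rnorm(20, 9)
  make <- function(base, later) {
    df <- data.frame(`M Baseline` = base, `M Acute` = later,
                     outcome = rep(c(0, 1), 10), check.names = FALSE)
    co <- cohort_table(df, variable_specs(
      c("M Baseline", "M Acute"), kind = "continuous",
      timepoint = c("baseline", "acute")))
    suppressMessages(build_difference_features(co))$x[["M Difference Baseline Acute"]]
  }
  expect_equal(make(b, a), -make(a, b), tolerance = 1e-12)
})

test_that("stratified split reproduces the published 194-subject partition", {
  co <- make_table1_cohort()
  expect_identical(sum(co$y), 120L)
  sp <- suppressMessages(stratified_split(co, 0.2, seed = 3))
  expect_identical(length(sp$train$subjects), 155L)
  expect_identical(sum(sp$train$y == 1L), 96L)
  expect_identical(sum(sp$train$y == 0L), 59L)
  expect_identical(length(sp$test$subjects), 39L)
  expect_identical(sum(sp$test$y == 1L), 24L)
  expect_identical(sum(sp$test$y == 0L), 15L)
})

test_that("stratified split conserves subjects, is deterministic, and stratifies exactly", {
  g <- generate_cohort(generator_spec(n_subjects = 120, n_noise = 6,
                                      n_categorical = 1, seed = 5))
  co <- g$cohort
  sp <- suppressMessages(stratified_split(co, 0.25, seed = 11))
  expect_setequal(c(sp$train$subjects, sp$test$subjects), co$subjects)
  expect_length(intersect(sp$train$subjects, sp$test$subjects), 0)
  # per-class counts sum to class totals
  expect_identical(sum(sp$train$y == 1L) + sum(sp$test$y == 1L), sum(co$y == 1L))
  # same seed, bit-identical membership
  sp2 <- suppressMessages(stratified_split(co, 0.25, seed = 11))
  expect_identical(sp$train$subjects, sp2$train$subjects)
  expect_identical(sp$test$subjects, sp2$test$subjects)
  # symmetric case: 10/10 at 0.5 gives exactly 5+5 per half
  df <- data.frame(v = rnorm(20), outcome = rep(c(0, 1), each = 10))
  co2 <- cohort_table(df, variable_specs("v"))
  sp3 <- suppressMessages(stratified_split(co2, 0.5, seed = 1))
  expect_identical(sum(sp3$test$y == 1L), 5L)
  expect_identical(sum(sp3$test$y == 0L), 5L)
})

test_that("a category level held by a single subject never lands in the test set", {
  set.seed(2)
  df <- data.frame(
    v = rnorm(12),
    cat = c("unique", rep(c("a", "b"), c(6, 5))),
    outcome = rep(c(0, 1), 6), stringsAsFactors = FALSE)
  co <- cohort_table(df, variable_specs(c("v", "cat"),
                                        kind = c("continuous", "categorical")))
  for (seed in 1:25) {
    sp <- suppressMessages(stratified_split(co, 0.3, seed = seed))
    expect_true("unique" %in% sp$train$x$cat,
                label = sprintf("seed %d keeps the singleton level in train", seed))
  }
})

test_that("cohort_summary reproduces event rates and matches brute-force counting", {
  co <- make_table1_cohort()
  s <- cohort_summary(co, c("Sport", "Sex"))
  fh <- s[s$Sport == "Field Hockey" & s$Sex == "female", ]
  expect_identical(fh$n_non_event, 1L)
  expect_identical(fh$n_event, 8L)
  expect_identical(fh$event_rate, 0.889)
  fb <- s[s$Sport == "Football" & s$Sex == "male", ]
  expect_identical(fb$event_rate, 0.643)
  sw <- s[s$Sport == "Swimming and Diving" & s$Sex == "male", ]
  expect_identical(sw$event_rate, 0)
  # equal counts give rate 0.5
  ch <- s[s$Sport == "Cheer", ]
  expect_true(all(ch$event_rate == 0.5))
  # brute force across every group
  for (i in seq_len(nrow(s))) {
    idx <- co$x$Sport == s$Sport[i] & co$x$Sex == s$Sex[i]
    expect_identical(s$event_rate[i],
                     round(sum(co$y[idx]) / sum(idx), 3))
  }
})

test_that("cohort write/load round trip preserves the data", {
  g <- generate_cohort(generator_spec(n_subjects = 40, n_noise = 4,
                                      n_categorical = 1, seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_cohort(g$cohort, file.path(dir, "syn"), truth = g$truth)
  expect_true(all(file.exists(paths)))
  co2 <- suppressMessages(load_cohort(paths[["table"]], paths[["dictionary"]]))
  expect_identical(co2$y, g$cohort$y)
  expect_identical(co2$specs, g$cohort$specs)
  expect_equal(as.data.frame(co2$x), as.data.frame(g$cohort$x),
               tolerance = 1e-12)
})
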