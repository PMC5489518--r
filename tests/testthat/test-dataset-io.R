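test_that("CSV parsing yields the expected dataset and preserves column order", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tiny_df(), f)
  d <- load_dataset(f, label_col = "class")
  expect_s3_class(d, "wolf_dataset")
  expect_equal(dim(d), c(3L, 2L))
  expect_identical(d$feature_names, c("f1", "f2"))
  expect_identical(d$classes, c("A", "B"))
  expect_equal(unname(d$features[, "f1"]), c(1, 3, 5))
})

test_that("the same data as ARFF parses to identical content as the CSV", {
  fc <- withr::local_tempfile(fileext = ".csv")
  fa <- withr::local_tempfile(fileext = ".arff")
  readr::write_csv(tiny_df(), fc)
  dc <- load_dataset(fc, label_col = "class")
  save_dataset(dc, fa, format = "arff")
  da <- load_dataset(fa, label_col = "class")
  expect_equal(unname(da$features), unname(dc$features))
  expect_identical(da$labels, dc$labels)
  expect_identical(da$feature_names, dc$feature_names)
})

test_that("every supported format round-trips the numeric matrix exactly", {
  g <- generate_synth(10, 6, 2, effect_size = 1, seed = 3)
  for (fmt in c("csv", "tsv", "arff", "libsvm")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    save_dataset(g$dataset, f, format = fmt)
    d2 <- load_dataset(f, format = fmt, label_col = "class")
    expect_equal(unname(d2$features), unname(g$dataset$features),
                 tolerance = 0, label = fmt)
    expect_identical(d2$labels, g$dataset$labels)
  }
})

test_that("loader errors name the problem: missing values, bad label column, single class", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- tiny_df()
  df$f2[2] <- NaN
  readr::write_csv(df, f)
  expect_error(load_dataset(f, label_col = "class"), "row 2.*column 2|column 2.*row 2")
  expect_silent(load_dataset(f, label_col = "class", impute = TRUE))

  readr::write_csv(tiny_df(), f)
  expect_error(load_dataset(f, label_col = "phenotype"), "phenotype")
  expect_error(load_dataset(f, label_col = 7), "out of range")

  df <- tiny_df()
  df$class <- "A"
  readr::write_csv(df, f)
  expect_error(load_dataset(f, label_col = "class"), "single class")
})

test_that("label column can be given as a 0-based index", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tiny_df(), f)
  d <- load_dataset(f, label_col = 2)
  expect_identical(d$classes, c("A", "B"))
  expect_identical(d$feature_names, c("f1", "f2"))
})

test_that("non-numeric feature columns are rejected by name", {
  expect_error(
    as_wolf_dataset(data.frame(f1 = 1:3, f2 = c("x", "y", "z"),
                               class = c("A", "B", "A"))),
    "f2")
})

test_that("selection results survive a JSON round trip bit-exactly", {
  res <- new_selection_result(
    mask = c(1L, 0L, 1L, 1L), fitness_history = c(0.5, 1 / 3 + 1 / 3, 0.7),
    method = "ebwsa", dataset_name = "demo",
    config_echo = list(pop_size = 10L, step_size = 0.15), seed = 99L,
    final_metrics = list(accuracy = 2 / 3, kappa = 0.123456789123456789))
  f <- withr::local_tempfile(fileext = ".json")
  save_result(res, f)
  r2 <- load_result(f)
  expect_identical(r2$mask, res$mask)
  expect_identical(r2$fitness_history, res$fitness_history)
  expect_identical(r2$seed, res$seed)
  expect_identical(unlist(r2$final_metrics), unlist(res$final_metrics))
  expect_identical(r2$selected_count, 3L)
})

test_that("invalid selection results are rejected", {
  expect_error(new_selection_result(mask = integer(0), fitness_history = 0.5),
               "length")
  expect_error(
    new_selection_result(mask = c(1L, 0L), fitness_history = c(0.5, 0.4)),
    "non-decreasing")
  res <- new_selection_result(mask = c(1L, 0L), fitness_history = c(0.4, 0.5))
  res$dimension_pct <- 10
  expect_error(save_result(res, withr::local_tempfile()), "dimension_pct")
})

test_that("dimension_pct recomputed from the mask matches the stored value", {
  for (seed in 1:5) {
    g <- generate_synth(20, 15, 3, seed = seed)
    mask <- withr::with_seed(seed, sample(0:1, 15, replace = TRUE))
    mask[1] <- 1L
    res <- new_selection_result(mask, fitness_history = 0.5)
    expect_equal(res$dimension_pct, 100 * sum(mask) / length(mask),
                 tolerance = 1e-12)
  }
})

test_that("libsvm files with sparse rows load with zeros filled in", {
  f <- withr::local_tempfile(fileext = ".libsvm")
  writeLines(c("pos 1:0.5 3:2", "neg 2:-1", "pos 3:4"), f)
  d <- load_dataset(f)
  expect_equal(dim(d), c(3L, 3L))
  expect_equal(unname(d$features[2, ]), c(0, -1, 0))
  expect_identical(d$labels, c("pos", "neg", "pos"))
})
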