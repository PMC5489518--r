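test_that("the all-zero mask scores 0 without training a classifier", {
  sp <- small_problem()
  ev <- fitness_evaluator(sp$gen$dataset, elm_seed = 1, split_seed = 1)
  before <- ev$n_trainings
  expect_identical(evaluate_mask(ev, rep(0L, 30)), 0)
  expect_identical(ev$n_trainings, before)
})

test_that("the cache returns bit-identical scores with exactly one training pass", {
  g <- generate_synth(60, 15, 3, effect_size = 2, seed = 8)
  ev <- fitness_evaluator(g$dataset, elm_seed = 2, split_seed = 3)
  mask <- c(rep(1L, 5), rep(0L, 10))
  s1 <- evaluate_mask(ev, mask)
  fits_after_first <- ev$n_trainings
  s2 <- evaluate_mask(ev, mask)
  expect_identical(s1, s2)
  expect_identical(ev$n_trainings, fits_after_first)  # pure cache hit
  expect_equal(fits_after_first, ev$k)                # one fit per fold
})

test_that("mask length mismatches are rejected", {
  g <- generate_synth(30, 10, 2, seed = 4)
  ev <- fitness_evaluator(g$dataset)
  expect_error(evaluate_mask(ev, rep(1L, 9)), "mask length")
})

test_that("truly informative features outscore pure noise across evaluator seeds", {
  g <- generate_synth(200, 20, 5, effect_size = 3, seed = 7)
  truth_mask <- as.integer(seq_len(20) %in% g$informative)
  noise_feats <- setdiff(seq_len(20), g$informative)[1:5]
  noise_mask <- as.integer(seq_len(20) %in% noise_feats)
  wins <- sum(vapply(1:10, function(s) {
    ev <- fitness_evaluator(g$dataset, elm_seed = 100 + s, split_seed = s)
    evaluate_mask(ev, truth_mask) >= evaluate_mask(ev, noise_mask)
  }, logical(1)))
  expect_gte(wins, 9)
})

test_that("holdout scheme works and is deterministic per evaluator", {
  g <- generate_synth(80, 12, 3, effect_size = 2.5, seed = 5)
  ev <- fitness_evaluator(g$dataset, scheme = "holdout",
                          holdout_fraction = 0.3, elm_seed = 4, split_seed = 6)
  mask <- as.integer(seq_len(12) %in% g$informative)
  a <- evaluate_mask(ev, mask)
  ev2 <- fitness_evaluator(g$dataset, scheme = "holdout",
                           holdout_fraction = 0.3, elm_seed = 4, split_seed = 6)
  expect_identical(a, evaluate_mask(ev2, mask))
  expect_true(a >= 0 && a <= 1)
})

test_that("final_evaluate on indistinguishable classes sits at chance level", {
  # both classes drawn from the same cloud: expected accuracy = majority rate
  g <- generate_synth(100, 10, 5, effect_size = 0, class_balance = 0.4,
                      seed = 10)
  fe <- final_evaluate(g$dataset, rep(1L, 10), folds = 5, repeats = 6,
                       seed = 3)
  rep_acc <- attr(fe, "per_repeat")$accuracy
  chance <- max(table(g$dataset$labels)) / 100
  expect_lt(abs(mean(rep_acc) - chance), 3 * max(sd(rep_acc), 0.02) + 0.1)
})

test_that("perfectly separable clusters give accuracy and kappa of 1", {
  x <- rbind(matrix(rnorm(150, 0, 0.05), 50), matrix(rnorm(150, 5, 0.05), 50))
  d <- wolf_dataset(x, rep(c("lo", "hi"), each = 50), name = "clusters")
  fe <- final_evaluate(d, c(1L, 1L, 0L), folds = 5, repeats = 2, seed = 1)
  expect_equal(fe$mean[fe$metric == "accuracy"], 1)
  expect_equal(fe$mean[fe$metric == "kappa"], 1)
})

test_that("final_evaluate is deterministic in its seed schedule", {
  g <- generate_synth(60, 8, 2, effect_size = 2, seed = 6)
  mask <- c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  f1 <- final_evaluate(g$dataset, mask, folds = 5, repeats = 2, seed = 11)
  f2 <- final_evaluate(g$dataset, mask, folds = 5, repeats = 2, seed = 11)
  expect_identical(f1$mean, f2$mean)
  expect_identical(f1$sd, f2$sd)
  expect_error(final_evaluate(g$dataset, rep(0L, 8)), "empty mask")
})

test_that("folds are reduced with a warning when a class is too rare", {
  x <- matrix(rnorm(40), 20)
  d <- wolf_dataset(x, rep(c("a", "b"), c(17, 3)))
  expect_warning(final_evaluate(d, c(1L, 1L), folds = 10, repeats = 1,
                                seed = 2),
                 "reducing folds")
})

test_that("search-time fitness tracks the final 10-fold evaluation", {
  g <- generate_synth(150, 25, 5, effect_size = 2.5, seed = 14)
  ev <- fitness_evaluator(g$dataset, elm_seed = 8, split_seed = 9)
  diffs <- withr::with_seed(21, vapply(1:10, function(i) {
    mask <- sample(0:1, 25, replace = TRUE)
    if (!any(mask == 1)) mask[1] <- 1L
    fe <- final_evaluate(g$dataset, mask, folds = 10, repeats = 2,
                         seed = 30 + i)
    abs(evaluate_mask(ev, mask) - fe$mean[fe$metric == "accuracy"])
  }, numeric(1)))
  expect_lte(mean(diffs), 0.15)
  expect_gte(sum(diffs <= 0.15), 8)
})
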