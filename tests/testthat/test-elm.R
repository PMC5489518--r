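test_that("two distinct one-feature points are separated perfectly", {
  x <- matrix(c(0, 1), ncol = 1)
  fit <- elm_train(x, c("A", "B"), n_hidden = 5, seed = 0)
  expect_identical(elm_predict(fit, x), c("A", "B"))
})

test_that("random hidden features solve XOR for most seeds at L = 20", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("A", "A", "B", "B")
  hits <- sum(vapply(0:9, function(s) {
    fit <- elm_train(x, y, n_hidden = 20, activation = "sigmoid", seed = s)
    all(elm_predict(fit, x) == y)
  }, logical(1)))
  expect_gte(hits, 8)
})

test_that("output weights agree with independent least-squares solves", {
  skip_if_not_installed("MASS")
  g <- generate_synth(40, 6, 2, effect_size = 1.5, seed = 13)
  x <- g$dataset$features
  y <- g$dataset$labels
  fit <- elm_train(x, y, n_hidden = 15, seed = 3)
  # rebuild the hidden activations exactly as the model saw them
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  h <- 1 / (1 + exp(-(tcrossprod(xs, fit$input_weights) +
                        matrix(fit$hidden_biases, nrow(x), fit$n_hidden,
                               byrow = TRUE))))
  targets <- matrix(0, nrow(x), 2)
  targets[cbind(seq_len(nrow(x)), match(y, fit$class_map))] <- 1
  b_ginv <- MASS::ginv(h) %*% targets
  expect_lt(max(abs(fit$output_weights - b_ginv)), 1e-8)
  b_qr <- qr.coef(qr(h), targets)  # full-rank case: ordinary LS solve
  if (!anyNA(b_qr)) expect_lt(max(abs(fit$output_weights - b_qr)), 1e-8)
})

test_that("training is deterministic in (x, y, L, seed)", {
  g <- generate_synth(30, 5, 2, seed = 21)
  f1 <- elm_train(g$dataset$features, g$dataset$labels, n_hidden = 10, seed = 7)
  f2 <- elm_train(g$dataset$features, g$dataset$labels, n_hidden = 10, seed = 7)
  expect_identical(f1$output_weights, f2$output_weights)
  f3 <- elm_train(g$dataset$features, g$dataset$labels, n_hidden = 10, seed = 8)
  expect_false(identical(f1$input_weights, f3$input_weights))
})

test_that("prediction handles empty input, duplicates and ties deterministically", {
  g <- generate_synth(30, 5, 2, effect_size = 2, seed = 2)
  fit <- elm_train(g$dataset$features, g$dataset$labels, seed = 1)
  expect_identical(elm_predict(fit, g$dataset$features[0, , drop = FALSE]),
                   character(0))
  dup <- g$dataset$features[c(1, 1), , drop = FALSE]
  pred <- elm_predict(fit, dup)
  expect_identical(pred[1], pred[2])
  # a model scoring both classes identically must return the earlier class
  tie <- fit
  tie$output_weights[] <- 0
  expect_identical(elm_predict(tie, g$dataset$features[1, , drop = FALSE]),
                   fit$class_map[1])
})

test_that("an appended all-zero feature with zeroed weights leaves predictions unchanged", {
  g <- generate_synth(40, 6, 2, effect_size = 2, seed = 5)
  x <- g$dataset$features
  fit <- elm_train(x, g$dataset$labels, n_hidden = 12, seed = 4)
  ext <- fit
  ext$input_weights <- cbind(fit$input_weights, 0)
  ext$center <- c(fit$center, 0)
  ext$scale <- c(fit$scale, 1)
  expect_identical(elm_predict(ext, cbind(x, 0)), elm_predict(fit, x))
})

test_that("training residual never increases as the hidden layer widens", {
  g <- generate_synth(50, 8, 3, effect_size = 1, seed = 17)
  x <- g$dataset$features
  y <- g$dataset$labels
  resid_for <- function(L) {
    fit <- elm_train(x, y, n_hidden = L, seed = 11)
    xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
    h <- 1 / (1 + exp(-(tcrossprod(xs, fit$input_weights) +
                          matrix(fit$hidden_biases, nrow(x), L, byrow = TRUE))))
    targets <- matrix(0, nrow(x), 2)
    targets[cbind(seq_len(nrow(x)), match(y, fit$class_map))] <- 1
    sum((h %*% fit$output_weights - targets)^2)
  }
  # same seed => nested hidden-feature sets (neuron-major parameter draws)
  resids <- vapply(c(5, 10, 20, 40, 80), resid_for, numeric(1))
  expect_true(all(diff(resids) <= 1e-9))
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(10), ncol = 2)
  expect_error(elm_train(x, rep("A", 5), n_hidden = 5), "single class")
  expect_error(elm_train(x, c("A", "B", "A", "B", "A"), n_hidden = 0),
               "n_hidden")
  fit <- elm_train(x, c("A", "B", "A", "B", "A"), n_hidden = 5, seed = 1)
  expect_error(elm_predict(fit, matrix(0, 2, 3)), "features")
})
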