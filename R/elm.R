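#' Train an extreme learning machine classifier
#'
#' Single-hidden-layer feed-forward network in which the hidden-layer weights
#' and biases are drawn once at random (uniform on `[-1, 1]`) and never
#' trained; only the linear output layer is fitted, by minimum-norm least
#' squares against one-hot (+1/0) class targets.  This makes training a
#' single pseudo-inverse solve, which is what makes the classifier cheap
#' enough to sit inside a wrapper feature-selection loop that calls it
#' thousands of times.
#'
#' Features are standardized internally (per-column mean 0, SD 1; constant
#' columns map to 0) because a sigmoid hidden layer saturates on raw
#' expression scales; the standardization parameters are stored in the model
#' and re-applied at prediction time.  Hidden parameters are drawn per
#' neuron (weights then bias), so models with the same seed and nested
#' hidden-layer sizes share their leading neurons exactly.
#'
#' @param x numeric matrix, `n x d` (n samples, d features).
#' @param y class labels, length `n`, at least two distinct classes.
#' @param n_hidden number of hidden neurons `L`; default
#'   `min(100, ceiling(n / 2))`.  Bounding by half the sample count keeps
#'   the unregularised least-squares fit well away from the interpolation
#'   threshold `L = n`, where validation accuracy collapses even on strong
#'   signal, and stops tiny-sample expression data requesting an absurdly
#'   wide layer.
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @param seed integer seed for the hidden parameters; the surrounding RNG
#'   state is untouched.
#' @return an object of class `elm` with fields `input_weights` (`L x d`),
#'   `hidden_biases` (`L`), `output_weights` (`L x K`), `activation`,
#'   `class_map` (classes in first-appearance order), `center`, `scale`,
#'   `seed`.
#' @export
#' @examples
#' fit <- elm_train(matrix(c(0, 1), ncol = 1), c("A", "B"),
#'                  n_hidden = 5, seed = 0)
#' elm_predict(fit, matrix(c(0, 1), ncol = 1))
elm_train <- function(x, y, n_hidden = NULL,
                      activation = c("sigmoid", "tanh"), seed = 0L) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (d < 1) stop("need at least one feature")
  if (length(y) != n) stop("x and y sizes differ")
  y <- as.character(y)
  class_map <- unique(y)
  k <- length(class_map)
  if (k < 2) stop("y contains a single class")
  if (n < k) stop("need at least as many samples as classes")
  n_hidden <- as.integer(n_hidden %||% min(100L, ceiling(n / 2)))
  if (n_hidden < 1) stop("n_hidden must be >= 1")

  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- Inf  # constant column -> 0 after scaling
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  # one uniform draw per hidden-neuron parameter, neuron-major, so the first
  # L neurons of a (seed, L') model with L' > L are identical
  draws <- withr::with_seed(as.integer(seed),
                            runif(n_hidden * (d + 1), -1, 1))
  params <- matrix(draws, nrow = n_hidden, byrow = TRUE)
  input_weights <- params[, seq_len(d), drop = FALSE]
  hidden_biases <- params[, d + 1]

  h <- elm_hidden(xs, input_weights, hidden_biases, activation)
  targets <- matrix(0, n, k)
  targets[cbind(seq_len(n), match(y, class_map))] <- 1
  output_weights <- pinv_solve(h, targets)

  structure(
    list(input_weights = input_weights, hidden_biases = hidden_biases,
         output_weights = output_weights, activation = activation,
         class_map = class_map, center = center, scale = scale,
         n_hidden = n_hidden, seed = as.integer(seed)),
    class = "elm")
}

elm_hidden <- function(xs, w, b, activation) {
  z <- tcrossprod(xs, w) + matrix(b, nrow(xs), length(b), byrow = TRUE)
  if (activation == "sigmoid") 1 / (1 + exp(-z)) else tanh(z)
}

# Minimum-norm least squares via SVD: B = pinv(H) %*% T.
pinv_solve <- function(h, targets) {
  s <- svd(h)
  tol <- max(dim(h)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(h), ncol(targets)))
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * crossprod(s$u[, pos, drop = FALSE], targets))
}

#' Predict class labels with a trained ELM
#'
#' Scores are `activation(x W' + b) B`; the predicted label is the class with
#' the maximal score, ties broken toward the earlier class in the model's
#' class order.
#'
#' @param model an [elm_train()] fit.
#' @param x numeric matrix `m x d` with `d` matching the training dimension;
#'   `m = 0` returns an empty label vector.
#' @return character vector of predicted labels, length `m`.
#' @export
elm_predict <- function(model, x) {
  stopifnot(inherits(model, "elm"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol(model$input_weights)) {
    stop("x has ", ncol(x), " features but the model was trained on ",
         ncol(model$input_weights))
  }
  if (nrow(x) == 0) return(character(0))
  scores <- elm_scores(model, x)
  model$class_map[apply(scores, 1, which.max)]  # which.max: first max wins
}

elm_scores <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  h <- elm_hidden(xs, model$input_weights, model$hidden_biases,
                  model$activation)
  h %*% model$output_weights
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm>  %d hidden neurons (%s), %d features, classes: %s\n",
              x$n_hidden, x$activation, ncol(x$input_weights),
              paste(x$class_map, collapse = ", ")))
  invisible(x)
}
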