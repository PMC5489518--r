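#' Wrapper fitness evaluator
#'
#' Maps a binary feature mask to a classification-accuracy score by training
#' the extreme learning machine on the masked columns under fixed stratified
#' splits.  The splits, the ELM hidden seed and the hidden-layer size are
#' frozen when the evaluator is created, so fitness is a deterministic
#' function of the mask, and every score is cached: re-evaluating a mask
#' returns the identical value without retraining.  The all-zero mask scores
#' 0 (the worst possible) without touching the classifier.
#'
#' The default scheme is a single stratified 3-fold cross-validation: cheap
#' enough for a search loop that evaluates thousands of masks, while final
#' reporting uses the stricter repeated 10-fold protocol of
#' [final_evaluate()].
#'
#' @param dataset a [wolf_dataset()].
#' @param scheme `"kfold"` (default) or `"holdout"`.
#' @param k number of folds for `"kfold"` (default 3).
#' @param holdout_fraction validation fraction for `"holdout"` (default 0.3).
#' @param elm_hidden hidden-layer size passed to [elm_train()]; `NULL` uses
#'   the ELM default.
#' @param elm_seed seed for the ELM hidden parameters (fixed per evaluator).
#' @param split_seed seed for the stratified splits (fixed per evaluator).
#' @return a `fitness_evaluator` object (environment-backed, so its cache is
#'   shared by reference across selectors that compare on the same fitness).
#' @export
fitness_evaluator <- function(dataset, scheme = c("kfold", "holdout"), k = 3,
                              holdout_fraction = 0.3, elm_hidden = NULL,
                              elm_seed = 1L, split_seed = 1L) {
  stopifnot(inherits(dataset, "wolf_dataset"))
  scheme <- match.arg(scheme)
  ev <- new.env(parent = emptyenv())
  ev$dataset <- dataset
  ev$scheme <- scheme
  ev$holdout_fraction <- holdout_fraction
  ev$elm_hidden <- elm_hidden
  ev$elm_seed <- as.integer(elm_seed)
  ev$split_seed <- as.integer(split_seed)
  ev$cache <- new.env(parent = emptyenv())
  ev$n_trainings <- 0L   # classifier fits actually performed (cache audit)
  if (scheme == "kfold") {
    f <- stratified_folds(dataset$labels, k, split_seed)
    ev$fold <- f$fold
    ev$k <- f$k
  } else {
    n <- nrow(dataset$features)
    val <- withr::with_seed(as.integer(split_seed), {
      unlist(lapply(unique(dataset$labels), function(cl) {
        idx <- which(dataset$labels == cl)
        sample(idx, max(1L, round(length(idx) * holdout_fraction)))
      }))
    })
    ev$holdout <- sort(val)
  }
  class(ev) <- "fitness_evaluator"
  ev
}

#' @export
print.fitness_evaluator <- function(x, ...) {
  cat(sprintf(
    "<fitness_evaluator>  dataset '%s', scheme %s%s, %d cached mask(s)\n",
    x$dataset$name, x$scheme,
    if (x$scheme == "kfold") sprintf(" (k=%d)", x$k) else "",
    length(ls(x$cache))))
  invisible(x)
}

#' Score one feature mask
#'
#' @param evaluator a [fitness_evaluator()].
#' @param mask binary (0/1) vector, length `n_features` of the evaluator's
#'   dataset.
#' @return mean validation accuracy in `[0, 1]`; 0 for the all-zero mask.
#' @export
evaluate_mask <- function(evaluator, mask) {
  stopifnot(inherits(evaluator, "fitness_evaluator"))
  p <- ncol(evaluator$dataset$features)
  if (length(mask) != p) {
    stop("mask length ", length(mask), " != n_features ", p)
  }
  mask <- as.integer(mask != 0)
  if (!any(mask == 1)) return(0)
  key <- mask_key(mask)
  hit <- get0(key, envir = evaluator$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  x <- evaluator$dataset$features[, mask == 1, drop = FALSE]
  y <- evaluator$dataset$labels
  score <- if (evaluator$scheme == "kfold") {
    accs <- vapply(seq_len(evaluator$k), function(f) {
      tr <- evaluator$fold != f
      fit <- elm_train(x[tr, , drop = FALSE], y[tr],
                       n_hidden = evaluator$elm_hidden,
                       seed = evaluator$elm_seed)
      evaluator$n_trainings <- evaluator$n_trainings + 1L
      mean(elm_predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(accs)
  } else {
    val <- evaluator$holdout
    fit <- elm_train(x[-val, , drop = FALSE], y[-val],
                     n_hidden = evaluator$elm_hidden,
                     seed = evaluator$elm_seed)
    evaluator$n_trainings <- evaluator$n_trainings + 1L
    mean(elm_predict(fit, x[val, , drop = FALSE]) == y[val])
  }
  assign(key, score, envir = evaluator$cache)
  score
}

#' Final evaluation of a feature mask by repeated stratified k-fold CV
#'
#' The reporting protocol: stratified 10-fold cross-validation of the ELM on
#' the masked dataset, repeated with distinct fold seeds, summarised as mean
#' and SD of accuracy, Cohen's kappa, precision and recall.  Folds are
#' reduced with a warning when the rarest class has fewer members than
#' `folds`.
#'
#' @param dataset a [wolf_dataset()].
#' @param mask binary vector, length `n_features`, with at least one 1.
#' @param folds number of CV folds (default 10).
#' @param repeats number of repetitions with different fold seeds.
#' @param seed master seed; fold and ELM seeds are derived from it.
#' @param elm_hidden optional hidden-layer size.
#' @param averaging precision/recall averaging, `"weighted"` or `"macro"`.
#' @return tibble with columns `metric`, `mean`, `sd`; the per-repeat values
#'   are attached as attribute `"per_repeat"` (a tibble).
#' @export
final_evaluate <- function(dataset, mask, folds = 10, repeats = 10,
                           seed = 1L, elm_hidden = NULL,
                           averaging = "weighted") {
  stopifnot(inherits(dataset, "wolf_dataset"))
  mask <- as.integer(mask != 0)
  if (length(mask) != ncol(dataset$features)) stop("mask length mismatch")
  if (!any(mask == 1)) stop("cannot evaluate an empty mask")
  if (folds < 2) stop("folds must be >= 2")
  if (repeats < 1) stop("repeats must be >= 1")

  x <- dataset$features[, mask == 1, drop = FALSE]
  y <- dataset$labels
  seeds <- derive_seeds(seed, 2 * repeats)
  rows <- purrr::map_dfr(seq_len(repeats), function(r) {
    f <- stratified_folds(y, folds, seeds[r])
    pred <- character(length(y))
    for (fd in seq_len(f$k)) {
      tr <- f$fold != fd
      fit <- elm_train(x[tr, , drop = FALSE], y[tr], n_hidden = elm_hidden,
                       seed = seeds[repeats + r])
      pred[!tr] <- elm_predict(fit, x[!tr, , drop = FALSE])
    }
    cm <- confusion_matrix(y, pred, classes = dataset$classes)
    tibble::as_tibble(metric_set(cm, averaging)) |>
      dplyr::mutate(repeat_id = r, .before = 1)
  })
  out <- rows |>
    tidyr::pivot_longer(-"repeat_id", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0) |>
    dplyr::arrange(match(.data$metric,
                         c("accuracy", "kappa", "precision", "recall")))
  attr(out, "per_repeat") <- rows
  out
}
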