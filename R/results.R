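#' Selection result
#'
#' The common return type of every selector: the chosen feature mask, the
#' best-so-far fitness trace, final evaluation metrics (when computed), and
#' enough configuration echo to reproduce the run from its seed alone.
#'
#' @param mask integer 0/1 vector, length `n_features` (>= 1).
#' @param fitness_history best-so-far fitness per iteration; must be
#'   non-decreasing.
#' @param method selector name (`"ebwsa"`, `"wsa"`, `"bpso"`, `"pso"`).
#' @param dataset_name dataset the mask refers to.
#' @param config_echo named list of resolved configuration values.
#' @param seed integer seed the run used.
#' @param final_metrics named list/map metric -> value (possibly empty until
#'   [final_evaluate()] has been run).
#' @param trace optional per-iteration diagnostic tibble.
#' @param diagnostics optional named list of counters.
#' @return object of class `selection_result`.
#' @export
new_selection_result <- function(mask, fitness_history, method = "ebwsa",
                                 dataset_name = "dataset",
                                 config_echo = list(), seed = NA_integer_,
                                 final_metrics = list(), trace = NULL,
                                 diagnostics = list()) {
  mask <- as.integer(mask)
  if (!length(mask)) stop("mask must have length >= 1")
  res <- structure(
    list(mask = mask, selected_count = sum(mask == 1L),
         dimension_pct = dimension_pct(sum(mask == 1L), length(mask)),
         fitness_history = as.numeric(fitness_history),
         final_metrics = final_metrics, config_echo = config_echo,
         seed = as.integer(seed), method = method,
         dataset_name = dataset_name, trace = trace,
         diagnostics = diagnostics),
    class = "selection_result")
  validate_selection_result(res)
  res
}

validate_selection_result <- function(res) {
  if (!length(res$mask)) stop("mask must have length >= 1")
  if (!all(res$mask %in% c(0L, 1L))) stop("mask must be binary")
  if (res$selected_count != sum(res$mask == 1L)) {
    stop("selected_count does not match the mask")
  }
  expect_pct <- 100 * res$selected_count / length(res$mask)
  if (abs(res$dimension_pct - expect_pct) > 1e-12) {
    stop("dimension_pct inconsistent with the mask")
  }
  fh <- res$fitness_history
  if (length(fh) > 1 && any(diff(fh) < 0)) {
    stop("fitness_history must be non-decreasing (best-so-far trace)")
  }
  invisible(res)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result: %s on '%s'>\n  %d/%d features selected (%.2f%% of the dimension), best fitness %.4f, seed %s\n",
    x$method, x$dataset_name, x$selected_count, length(x$mask),
    x$dimension_pct, max(x$fitness_history), x$seed))
  if (length(x$final_metrics)) {
    cat("  final metrics:",
        paste(sprintf("%s=%.3f", names(x$final_metrics),
                      unlist(x$final_metrics)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Save / load a selection result as JSON
#'
#' The round trip restores every field bit-exactly for integers and
#' exactly-representable reals (full-precision JSON serialization).  The
#' result is validated on both save and load; an empty mask or a
#' non-monotone fitness history is rejected.
#'
#' @param result a [new_selection_result()].
#' @param path JSON file path.
#' @return `save_result()`: `path` invisibly; `load_result()`: the restored
#'   `selection_result`.
#' @export
save_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  validate_selection_result(result)
  out <- unclass(result)
  out$trace <- NULL  # diagnostics tibble is session-local, not part of the contract
  # I(17) significant digits: every double round-trips bit-exactly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_result
#' @export
load_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_selection_result(
    mask = raw$mask, fitness_history = raw$fitness_history,
    method = raw$method %||% "unknown",
    dataset_name = raw$dataset_name %||% "dataset",
    config_echo = as.list(raw$config_echo), seed = raw$seed,
    final_metrics = as.list(raw$final_metrics),
    diagnostics = as.list(raw$diagnostics))
}

#' Tidy the fitness trace of a selection result
#'
#' @param x a `selection_result`.
#' @param ... unused.
#' @return tibble with `iteration` and `best_fitness` columns (plus the
#'   full diagnostic columns when the run kept a trace).
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  if (!is.null(x$trace)) return(x$trace)
  tibble::tibble(iteration = seq_along(x$fitness_history),
                 best_fitness = x$fitness_history)
}

#' One-row summary of a selection result
#'
#' @param x a `selection_result`.
#' @param ... unused.
#' @return one-row tibble: method, dataset, selected count, dimension %,
#'   best fitness, iterations, seed.
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method, dataset = x$dataset_name,
                 selected = x$selected_count, n_features = length(x$mask),
                 dimension_pct = x$dimension_pct,
                 best_fitness = max(x$fitness_history),
                 iterations = length(x$fitness_history), seed = x$seed)
}

#' Plot the best-so-far fitness trace
#'
#' @param object a `selection_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$fitness_history),
                       best_fitness = object$fitness_history)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$best_fitness)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::labs(x = "iteration", y = "best-so-far fitness",
                  title = sprintf("%s on %s", object$method,
                                  object$dataset_name)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
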