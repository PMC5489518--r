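#' Select features from a labelled data frame
#'
#' The front door of the package: takes a data frame (or a
#' [wolf_dataset()]), runs the requested selector, and optionally appends
#' the repeated 10-fold cross-validation metrics of the chosen mask.
#'
#' One master `seed` fans out deterministically (via [derive_seeds()]) to
#' the search stream, the classifier's hidden layer, and the fitness splits,
#' so the whole run is reconstructible from the logged configuration and
#' seed alone.
#'
#' @param data data frame with feature columns and one label column, or a
#'   [wolf_dataset()].
#' @param label_col label column name or 0-based index (data frames only).
#' @param method `"ebwsa"` (default), `"wsa"`, `"bpso"` or `"pso"`.
#' @param pop_size,max_iter swarm size and iteration budget.
#' @param seed master seed.
#' @param final_cv if `TRUE` (default), run [final_evaluate()] on the
#'   selected mask and store the metric means in `final_metrics`.
#' @param folds,repeats final-evaluation protocol (default 10-fold, 10
#'   repeats).
#' @param evaluator optionally a pre-built [fitness_evaluator()] (shared
#'   across methods to hold the fitness function fixed in comparisons).
#' @param ... further fields for [ebwsa_config()] / [baseline_config()].
#' @return a [new_selection_result()].
#' @export
#' @examples
#' \donttest{
#' g <- generate_synth(60, 25, 4, effect_size = 2.5, seed = 3)
#' res <- wolf_select(g$dataset, method = "ebwsa", pop_size = 8,
#'                    max_iter = 10, seed = 7, final_cv = FALSE)
#' glance(res)
#' }
wolf_select <- function(data, label_col = "class",
                        method = c("ebwsa", "wsa", "bpso", "pso"),
                        pop_size = 15, max_iter = 100, seed = 1L,
                        final_cv = TRUE, folds = 10, repeats = 10,
                        evaluator = NULL, ...) {
  method <- match.arg(method)
  dataset <- if (inherits(data, "wolf_dataset")) data else
    as_wolf_dataset(data, label_col = label_col)
  seeds <- derive_seeds(seed, 4)
  if (is.null(evaluator)) {
    evaluator <- fitness_evaluator(dataset, elm_seed = seeds[2],
                                   split_seed = seeds[3])
  }
  res <- if (method == "ebwsa") {
    run_ebwsa(dataset, evaluator,
              ebwsa_config(pop_size = pop_size, max_iter = max_iter,
                           seed = seeds[1], ...))
  } else {
    cfg <- baseline_config(algorithm = method, pop_size = pop_size,
                           max_iter = max_iter, seed = seeds[1], ...)
    switch(method,
           wsa = run_wsa(dataset, evaluator, cfg),
           bpso = run_bpso(dataset, evaluator, cfg),
           pso = run_pso(dataset, evaluator, cfg))
  }
  res$seed <- as.integer(seed)  # report the master seed, not the derived one
  if (final_cv && res$selected_count > 0) {
    fe <- final_evaluate(dataset, res$mask, folds = folds,
                         repeats = repeats, seed = seeds[4])
    res$final_metrics <- as.list(setNames(fe$mean, fe$metric))
    res$final_metrics$dimension_pct <- res$dimension_pct
  }
  validate_selection_result(res)
  res
}

#' Run a repeated selection experiment
#'
#' The reporting protocol of the accompanying study: each method is run
#' `repeats` times with derived seeds, each selected mask is evaluated by
#' stratified `folds`-fold cross-validation, and the per-run metrics are
#' aggregated to mean and SD — one table row per method, in the shape of the
#' published comparison tables (accuracy, kappa, precision, recall,
#' dimension %).  All methods share one fitness evaluator per run seed, so
#' cross-method comparisons hold the fitness function fixed.
#'
#' @param data data frame or [wolf_dataset()].
#' @param label_col label column for data frames.
#' @param methods character vector from `{"ebwsa", "wsa", "bpso", "pso"}`.
#' @param repeats number of seeded runs per method (default 10).
#' @param folds final CV folds (default 10).
#' @param pop_size,max_iter search budget per run.
#' @param seed master seed.
#' @param ... extra configuration fields passed through to the selectors.
#' @return an `experiment_report`: list with `runs` (list of
#'   [new_selection_result()]s), `aggregate` (tibble: method, metric, mean,
#'   sd), `per_run` (tibble of per-run metrics) and the call configuration.
#' @export
run_experiment <- function(data, label_col = "class", methods = "ebwsa",
                           repeats = 10, folds = 10, pop_size = 15,
                           max_iter = 100, seed = 1L, ...) {
  stopifnot(repeats >= 1)
  methods <- match.arg(methods, c("ebwsa", "wsa", "bpso", "pso"),
                       several.ok = TRUE)
  dataset <- if (inherits(data, "wolf_dataset")) data else
    as_wolf_dataset(data, label_col = label_col)
  run_seeds <- derive_seeds(seed, repeats)

  runs <- list()
  rows <- list()
  for (method in methods) {
    for (r in seq_len(repeats)) {
      res <- wolf_select(dataset, method = method, pop_size = pop_size,
                         max_iter = max_iter, seed = run_seeds[r],
                         final_cv = TRUE, folds = folds, repeats = 1, ...)
      runs[[paste(method, r, sep = "_")]] <- res
      rows[[paste(method, r, sep = "_")]] <- tibble::tibble(
        method = method, run = r,
        metric = c(names(res$final_metrics)),
        value = unlist(res$final_metrics, use.names = FALSE))
    }
  }
  per_run <- dplyr::bind_rows(rows)
  aggregate <- per_run |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     .groups = "drop")
  structure(
    list(runs = runs, per_run = per_run, aggregate = aggregate,
         dataset_name = dataset$name, methods = methods, repeats = repeats,
         folds = folds, pop_size = pop_size, max_iter = max_iter,
         seed = as.integer(seed)),
    class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: '%s', %d repeat(s) x {%s}>\n",
              x$dataset_name, x$repeats, paste(x$methods, collapse = ", ")))
  wide <- tidyr::pivot_wider(
    x$aggregate, names_from = "metric",
    values_from = c("mean", "sd"), names_vary = "slowest")
  print(as.data.frame(wide), digits = 3)
  invisible(x)
}

#' Tidy the per-run metrics of an experiment
#'
#' @param x an `experiment_report`.
#' @param ... unused.
#' @return tibble: method, run, metric, value.
#' @method tidy experiment_report
#' @export
tidy.experiment_report <- function(x, ...) x$per_run

#' Aggregate summary of an experiment
#'
#' @param x an `experiment_report`.
#' @param ... unused.
#' @return tibble: method, metric, mean, sd.
#' @method glance experiment_report
#' @export
glance.experiment_report <- function(x, ...) x$aggregate

#' Plot experiment aggregates as mean +/- SD
#'
#' @param object an `experiment_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot experiment_report
#' @export
autoplot.experiment_report <- function(object, ...) {
  df <- dplyr::filter(object$aggregate, .data$metric != "dimension_pct")
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$mean,
                                   fill = .data$method)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "mean over repeats",
                  title = object$dataset_name) +
    ggplot2::theme_minimal()
}
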