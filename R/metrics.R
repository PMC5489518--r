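#' Confusion matrix
#'
#' Cross-tabulates true against predicted class labels over a fixed class
#' order (rows = truth, columns = predicted).
#'
#' @param truth vector of true labels.
#' @param predicted vector of predicted labels, same length.
#' @param classes class order; defaults to first appearance in `c(truth,
#'   predicted)`.
#' @return `confusion_matrix` object: an integer K x K matrix with the class
#'   order in dimnames.
#' @export
#' @examples
#' cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' accuracy(cm)
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted lengths differ")
  }
  classes <- classes %||% unique(c(truth, predicted))
  if (!all(c(truth, predicted) %in% classes)) {
    stop("labels outside the declared class set")
  }
  counts <- table(factor(truth, levels = classes),
                  factor(predicted, levels = classes))
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

as_confusion <- function(cm) {
  if (inherits(cm, "confusion_matrix")) return(cm)
  m <- as.matrix(cm)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("confusion matrix entries must be non-negative")
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Classification accuracy
#'
#' @param cm a [confusion_matrix()] (or square count matrix).
#' @return trace / total, in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  m <- as_confusion(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(m)) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed accuracy and `p_e` the agreement expected from the marginals.
#' Returns 0 by convention when `p_e = 1` (a degenerate one-cell matrix).
#'
#' @inheritParams accuracy
#' @return kappa in `[-1, 1]`.
#' @export
kappa_statistic <- function(cm) {
  m <- as_confusion(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (abs(1 - p_e) < .Machine$double.eps * 4) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Precision and recall
#'
#' Per-class precision `TP/(TP+FP)` and recall `TP/(TP+FN)` (0 when the
#' denominator is 0), combined across classes either weighted by class
#' support (the default) or as an unweighted macro average.
#'
#' @inheritParams accuracy
#' @param averaging `"weighted"` or `"macro"`.
#' @return named numeric vector `c(precision = , recall = )`.
#' @export
precision_recall <- function(cm, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  m <- as_confusion(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(m)
  support <- rowSums(m)       # truth counts per class
  predicted <- colSums(m)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  w <- if (averaging == "weighted") support / total else
    rep(1 / nrow(m), nrow(m))
  c(precision = sum(w * prec), recall = sum(w * rec))
}

#' Selected-subset size as a percentage of the full dimension
#'
#' @param selected number of selected features.
#' @param total total number of features (> 0).
#' @return `100 * selected / total`.
#' @export
#' @examples
#' dimension_pct(43, 22283)
dimension_pct <- function(selected, total) {
  if (total <= 0) stop("total must be positive")
  if (selected < 0 || selected > total) {
    stop("selected must lie in [0, total]")
  }
  100 * selected / total
}

# All reporting metrics from one confusion matrix, as a named list.
metric_set <- function(cm, averaging = "weighted") {
  pr <- precision_recall(cm, averaging)
  list(accuracy = accuracy(cm), kappa = kappa_statistic(cm),
       precision = unname(pr["precision"]), recall = unname(pr["recall"]))
}
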