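#' Labelled feature-matrix container
#'
#' The object every selector in wolfselect consumes: a numeric samples x
#' features matrix plus a class label per sample.  Labels are kept as opaque
#' class identifiers; internally classes are ordered by first appearance in
#' the data (so the mapping is deterministic and independent of label
#' lexicography).
#'
#' @param features numeric matrix, `n_samples x n_features`.
#' @param labels vector of class identifiers, length `n_samples`.
#' @param feature_names character vector of unique feature names; defaults to
#'   the matrix column names or `f1..fp`.
#' @param name dataset name used in reports.
#' @param require_classes if `TRUE` (default) at least two distinct classes
#'   are required, as classification needs.
#' @return an object of class `wolf_dataset` with fields `features`,
#'   `labels` (character), `feature_names`, `name`, `classes` (first-appearance
#'   order).
#' @export
wolf_dataset <- function(features, labels, feature_names = NULL,
                         name = "dataset", require_classes = TRUE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  p <- ncol(features)
  if (n < 2) stop("a dataset needs at least 2 samples, got ", n)
  if (p < 1) stop("a dataset needs at least 1 feature")
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") != number of samples (", n, ")")
  }
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels contain missing values")
  classes <- unique(labels)
  if (require_classes && length(classes) < 2) {
    stop("labels contain a single class ('", classes,
         "'); classification needs at least 2")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features) %||% paste0("f", seq_len(p))
  }
  if (length(feature_names) != p) stop("feature_names length != n_features")
  if (anyDuplicated(feature_names)) {
    stop("feature names are not unique: e.g. '",
         feature_names[duplicated(feature_names)][1], "'")
  }
  bad <- which(!is.finite(features))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(features))
    stop(sprintf(
      "non-finite feature value at row %d, column %d ('%s'); %d offending cell(s) in total",
      rc[1], rc[2], feature_names[rc[2]], length(bad)))
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels,
         feature_names = feature_names, name = name, classes = classes),
    class = "wolf_dataset")
}

#' Build a dataset from a data frame
#'
#' Tidy entry point: takes a data frame whose columns are features plus one
#' label column, and returns the [wolf_dataset()] container.
#'
#' @param data a data frame (or tibble).
#' @param label_col label column, by name or 0-based index (matching the
#'   on-disk readers).
#' @param name dataset name.
#' @param impute if `TRUE`, missing feature cells are replaced by the feature
#'   (column) mean; the default is a hard error naming the first bad cell.
#' @return a [wolf_dataset()].
#' @export
#' @examples
#' d <- as_wolf_dataset(
#'   data.frame(f1 = c(1, 3, 5), f2 = c(2, 4, 6), class = c("A", "B", "A")),
#'   label_col = "class")
#' d
as_wolf_dataset <- function(data, label_col = "class", name = "dataset",
                            impute = FALSE) {
  data <- as.data.frame(data)
  if (is.numeric(label_col)) {
    j <- as.integer(label_col) + 1L  # 0-based index contract
    if (j < 1 || j > ncol(data)) {
      stop("label column index ", label_col, " out of range (0..",
           ncol(data) - 1, ")")
    }
  } else {
    j <- match(label_col, names(data))
    if (is.na(j)) {
      stop("label column '", label_col, "' not found; columns are: ",
           paste(names(data), collapse = ", "))
    }
  }
  labels <- data[[j]]
  feats <- data[, -j, drop = FALSE]
  non_num <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(non_num)) {
    stop("non-numeric feature column(s): ", paste(non_num, collapse = ", "))
  }
  m <- as.matrix(feats)
  if (impute && anyNA(m)) {
    for (k in seq_len(ncol(m))) {
      nas <- is.na(m[, k])
      if (any(nas)) m[nas, k] <- mean(m[, k], na.rm = TRUE)
    }
  }
  wolf_dataset(m, labels, feature_names = names(feats), name = name)
}

#' Read a labelled dataset from disk
#'
#' Supports delimited text (CSV/TSV with a header row), ARFF, and the libsvm
#' sparse text format.  The format is inferred from the file extension and
#' can be forced with `format`.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"arff"`, `"libsvm"`.
#' @param label_col label column name or 0-based index (ignored for libsvm,
#'   where the label leads each line).
#' @param name dataset name; defaults to the file stem.
#' @param impute mean-impute missing feature cells instead of erroring.
#' @return a [wolf_dataset()].
#' @export
load_dataset <- function(path, format = c("auto", "csv", "tsv", "arff", "libsvm"),
                         label_col = "class", name = NULL, impute = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", tsv = "tsv", txt = "tsv", arff = "arff",
      libsvm = "libsvm", svm = "libsvm",
      stop("cannot infer format from extension '.", ext,
           "'; pass format= explicitly"))
  }
  name <- name %||% tools::file_path_sans_ext(basename(path))
  if (format %in% c("csv", "tsv")) {
    # base strtod parsing is correctly rounded, so shortest-round-trip
    # decimal output re-reads bit-exactly
    df <- utils::read.delim(path, sep = if (format == "csv") "," else "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    return(as_wolf_dataset(df, label_col = label_col, name = name,
                           impute = impute))
  }
  if (format == "arff") {
    df <- foreign::read.arff(path)
    return(as_wolf_dataset(df, label_col = label_col, name = name,
                           impute = impute))
  }
  read_libsvm(path, name = name)
}

# libsvm sparse text: "<label> <index>:<value> ...", 1-based indices.
read_libsvm <- function(path, name = "dataset") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty libsvm file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  labels <- vapply(toks, `[[`, character(1), 1)
  pairs <- lapply(toks, function(tk) {
    if (length(tk) < 2) return(matrix(numeric(0), ncol = 2))
    kv <- strsplit(tk[-1], ":", fixed = TRUE)
    ok <- lengths(kv) == 2
    if (!all(ok)) stop("malformed libsvm entry: '", tk[-1][!ok][1], "'")
    cbind(as.integer(vapply(kv, `[[`, character(1), 1)),
          as.numeric(vapply(kv, `[[`, character(1), 2)))
  })
  p <- max(1L, max(vapply(pairs, function(m) {
    if (nrow(m)) max(m[, 1]) else 0L
  }, numeric(1))))
  feats <- matrix(0, nrow = length(lines), ncol = p)
  for (i in seq_along(pairs)) {
    m <- pairs[[i]]
    if (nrow(m)) feats[i, m[, 1]] <- m[, 2]
  }
  wolf_dataset(feats, labels, feature_names = paste0("f", seq_len(p)),
               name = name)
}

#' Write a dataset to disk
#'
#' Inverse of [load_dataset()] for the CSV/TSV and ARFF formats (a labelled
#' dense matrix; libsvm writing is supported too for completeness).
#'
#' @param dataset a [wolf_dataset()].
#' @param path output file.
#' @param format `"csv"`, `"tsv"`, `"arff"` or `"libsvm"`.
#' @param label_col name to give the label column.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path, format = c("csv", "tsv", "arff", "libsvm"),
                         label_col = "class") {
  stopifnot(inherits(dataset, "wolf_dataset"))
  format <- match.arg(format)
  df <- as.data.frame(dataset$features)
  df[[label_col]] <- dataset$labels
  if (format %in% c("csv", "tsv")) {
    readr::write_delim(df, path, delim = if (format == "csv") "," else "\t",
                       progress = FALSE)
  } else if (format == "arff") {
    # emitted by hand at 17 significant digits (bit-exact round trip);
    # reading still goes through foreign::read.arff
    classes <- unique(dataset$labels)
    header <- c(
      sprintf("@relation '%s'", dataset$name),
      sprintf("@attribute '%s' numeric", dataset$feature_names),
      sprintf("@attribute '%s' {%s}", label_col,
              paste(sprintf("'%s'", classes), collapse = ",")),
      "@data")
    rows <- vapply(seq_len(nrow(dataset$features)), function(i) {
      paste(c(sprintf("%.17g", dataset$features[i, ]),
              sprintf("'%s'", dataset$labels[i])), collapse = ",")
    }, character(1))
    writeLines(c(header, rows), path)
  } else {
    lines <- vapply(seq_len(nrow(dataset$features)), function(i) {
      v <- dataset$features[i, ]
      nz <- which(v != 0)
      paste(c(dataset$labels[i], sprintf("%d:%.17g", nz, v[nz])),
            collapse = " ")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.wolf_dataset <- function(x, ...) {
  cat(sprintf("<wolf_dataset '%s'>  %d samples x %d features, %d classes (%s)\n",
              x$name, nrow(x$features), ncol(x$features), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @export
dim.wolf_dataset <- function(x) dim(x$features)

#' Coerce a dataset back to a tibble
#'
#' @param x a [wolf_dataset()].
#' @param ... unused.
#' @param label_col name for the label column.
#' @return tibble with feature columns followed by the label column.
#' @method as_tibble wolf_dataset
#' @export
as_tibble.wolf_dataset <- function(x, ..., label_col = "class") {
  out <- tibble::as_tibble(as.data.frame(x$features))
  out[[label_col]] <- x$labels
  out
}
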