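#' Derive reproducible child seeds from one master seed
#'
#' A single experiment seed fans out to independent per-component seeds
#' (search stream, classifier hidden layer, data splits) so that any one
#' component can be re-seeded without disturbing the others.  The derivation
#' is a fixed rule: seed the generator with `seed` and draw `n` integers
#' uniformly from `1 .. 2^31 - 2`.
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
#' @examples
#' derive_seeds(42, 3)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Clip positions into [lower, upper]; upper is kept an epsilon below the
# binarization boundary so a maximal component cannot wrap to 0.
clip_position <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` cross-validation folds so that every
#' class is spread as evenly as possible across folds.  Deterministic for a
#' given `seed`; the caller's random-number state is left untouched.
#'
#' @param labels vector of class labels.
#' @param k number of folds (reduced, with a warning, if the rarest class has
#'   fewer than `k` members).
#' @param seed integer seed for the shuffle.
#' @return list with `fold` (integer assignment, length `length(labels)`) and
#'   `k` (the number of folds actually used).
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  min_class <- min(table(labels))
  if (min_class < k) {
    warning(sprintf(
      "rarest class has %d members; reducing folds from %d to %d",
      min_class, k, max(2L, min_class)
    ))
    k <- max(2L, as.integer(min_class))
  }
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  list(fold = fold, k = k)
}

# A compact string key for a binary mask (cache / memory lookup).
mask_key <- function(mask) {
  paste(as.integer(mask), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
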