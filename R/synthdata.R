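#' Generate a high-dimensional two-class dataset with known signal
#'
#' Emulates the shape regime of public gene-expression benchmarks (few
#' samples, thousands of features, binary labels, a small informative subset
#' buried in noise) while recording the ground truth, so selector quality is
#' measurable without external downloads.
#'
#' Informative features are drawn from class-conditional Gaussians whose
#' means differ by `effect_size` noise-SDs (class "neg" mean 0, class "pos"
#' mean `effect_size * noise_sd`).  Redundant features are noisy copies
#' `1 * informative + 0 + eps`, `eps ~ N(0, 0.1 * noise_sd)`.  All remaining
#' features are class-independent `N(0, noise_sd)` noise.  Column positions
#' are shuffled (seeded) so signal has no positional footprint; the returned
#' truth indices refer to the shuffled order.
#'
#' @param n_samples number of samples (the benchmark regime is 60-200).
#' @param n_features total feature count.
#' @param n_informative number of class-associated features.
#' @param effect_size class-mean shift in noise-SD units (0 = pure null).
#' @param n_redundant number of noisy linear copies of informative features.
#' @param noise_sd marginal SD of the noise (> 0).
#' @param class_balance proportion of the "pos" class, in (0, 1); class sizes
#'   are deterministic (`round(n * balance)`).
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   dataset.
#' @param name dataset name.
#' @param permutation optional column permutation from a previous call's
#'   `$permutation`, so an independently drawn hold-out set puts every
#'   feature at the same column position as the training set.
#' @return list with `dataset` (a [wolf_dataset()]), `informative` (integer
#'   indices of the truly class-associated features), `redundant` (indices
#'   of their noisy copies) and `permutation` (the column shuffle used).
#' @export
#' @examples
#' g <- generate_synth(n_samples = 50, n_features = 20, n_informative = 3,
#'                     effect_size = 2, seed = 1)
#' g$dataset
#' g$informative
generate_synth <- function(n_samples, n_features, n_informative,
                           effect_size = 2, n_redundant = 0, noise_sd = 1,
                           class_balance = 0.5, seed = 1L, name = "synth",
                           permutation = NULL) {
  if (n_informative + n_redundant > n_features) {
    stop("n_informative + n_redundant (", n_informative + n_redundant,
         ") exceeds n_features (", n_features, ")")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must lie strictly in (0, 1)")
  }
  if (n_samples < 4) stop("need at least 4 samples")
  n_pos <- round(n_samples * class_balance)
  n_pos <- min(max(n_pos, 2L), n_samples - 2L)  # both classes represented

  withr::with_seed(as.integer(seed), {
    labels <- c(rep("pos", n_pos), rep("neg", n_samples - n_pos))
    labels <- labels[sample.int(n_samples)]
    shift <- ifelse(labels == "pos", effect_size * noise_sd, 0)

    x <- matrix(rnorm(n_samples * n_features, sd = noise_sd),
                n_samples, n_features)
    inf_idx <- seq_len(n_informative)
    if (n_informative > 0) {
      x[, inf_idx] <- x[, inf_idx, drop = FALSE] + shift
    }
    red_idx <- integer(0)
    if (n_redundant > 0) {
      if (n_informative == 0) stop("redundant features need informative ones")
      src <- rep_len(inf_idx, n_redundant)
      red_idx <- n_informative + seq_len(n_redundant)
      x[, red_idx] <- x[, src, drop = FALSE] +
        matrix(rnorm(n_samples * n_redundant, sd = 0.1 * noise_sd),
               n_samples, n_redundant)
    }
    perm <- permutation %||% sample.int(n_features)
    if (length(perm) != n_features || !setequal(perm, seq_len(n_features))) {
      stop("permutation must be a permutation of 1..n_features")
    }
    x <- x[, perm, drop = FALSE]
    informative <- match(inf_idx, perm)
    redundant <- match(red_idx, perm)
  })

  ds <- wolf_dataset(x, labels, feature_names = paste0("f", seq_len(n_features)),
                     name = name)
  list(dataset = ds, informative = sort(informative),
       redundant = sort(redundant), permutation = perm)
}

#' Write a synthetic dataset plus its ground truth
#'
#' Convenience wrapper used by the command-line `synth` subcommand: writes
#' the generated matrix as CSV and the ground-truth indices (plus the
#' generating parameters) as a JSON sidecar.
#'
#' @inheritParams generate_synth
#' @param path output CSV path; the sidecar is `<path>.truth.json`.
#' @return invisible list with `data_path` and `truth_path`.
#' @export
write_synth <- function(path, n_samples, n_features, n_informative,
                        effect_size = 2, n_redundant = 0, noise_sd = 1,
                        class_balance = 0.5, seed = 1L) {
  g <- generate_synth(n_samples, n_features, n_informative,
                      effect_size = effect_size, n_redundant = n_redundant,
                      noise_sd = noise_sd, class_balance = class_balance,
                      seed = seed,
                      name = tools::file_path_sans_ext(basename(path)))
  save_dataset(g$dataset, path, format = "csv")
  truth_path <- paste0(path, ".truth.json")
  jsonlite::write_json(
    list(informative = g$informative, redundant = g$redundant,
         spec = list(n_samples = n_samples, n_features = n_features,
                     n_informative = n_informative, effect_size = effect_size,
                     n_redundant = n_redundant, noise_sd = noise_sd,
                     class_balance = class_balance, seed = seed)),
    truth_path, auto_unbox = TRUE, digits = I(17))
  invisible(list(data_path = path, truth_path = truth_path))
}
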