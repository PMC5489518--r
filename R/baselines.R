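#' Configuration for the comparison selectors
#'
#' Shared settings for the plain binary wolf search and the two particle
#' swarm baselines, mirroring the published comparison settings: population
#' 15, 100 iterations, inertia weight 0.8; the PSO cognitive/social
#' constants and velocity clamp use the canonical defaults `c1 = c2 = 2`,
#' `v_max = 4`.
#'
#' @param algorithm `"wsa"`, `"bpso"` or `"pso"`.
#' @param pop_size swarm size (default 15).
#' @param max_iter iterations (default 100).
#' @param inertia PSO/BPSO inertia weight (default 0.8).
#' @param c1,c2 cognitive and social acceleration constants (default 2).
#' @param v_max velocity clamp (default 4).
#' @param visual_radius,step_size,beta0,escape_threshold,minkowski_order
#'   wolf-search movement parameters, as in [ebwsa_config()].
#' @param lower_bound,upper_bound continuous position box.
#' @param seed integer seed.
#' @return a `baseline_config` list.
#' @export
baseline_config <- function(algorithm = c("wsa", "bpso", "pso"),
                            pop_size = 15, max_iter = 100, inertia = 0.8,
                            c1 = 2, c2 = 2, v_max = 4, visual_radius = NULL,
                            step_size = 0.15, beta0 = 1,
                            escape_threshold = 0.25, minkowski_order = 2,
                            lower_bound = -0.5, upper_bound = 1.5,
                            seed = 1L) {
  algorithm <- match.arg(algorithm)
  cfg <- list(algorithm = algorithm, pop_size = as.integer(pop_size),
              max_iter = as.integer(max_iter), inertia = inertia, c1 = c1,
              c2 = c2, v_max = v_max, visual_radius = visual_radius,
              step_size = step_size, beta0 = beta0,
              escape_threshold = escape_threshold,
              minkowski_order = minkowski_order, lower_bound = lower_bound,
              upper_bound = upper_bound, seed = as.integer(seed))
  if (cfg$pop_size < 2) stop("pop_size must be >= 2")
  if (cfg$max_iter < 1) stop("max_iter must be >= 1")
  if (cfg$v_max <= 0) stop("v_max must be > 0")
  class(cfg) <- "baseline_config"
  cfg
}

#' Plain binary wolf search baseline
#'
#' The original wolf search movement rules (prey step, attraction to a
#' better peer within the visual radius, probabilistic escape beyond it)
#' with a fixed unit step scaling — no elitist weights, no worst-position
#' memory, no rebirth.  Positions are continuous and projected to feature
#' masks by [binarize()].
#'
#' @param dataset a [wolf_dataset()].
#' @param evaluator a [fitness_evaluator()]; `NULL` builds the default.
#' @param config a [baseline_config()] with `algorithm = "wsa"` (or an
#'   [ebwsa_config()], whose movement fields are reused).
#' @return a [new_selection_result()].
#' @export
run_wsa <- function(dataset, evaluator = NULL,
                    config = baseline_config("wsa")) {
  stopifnot(inherits(dataset, "wolf_dataset"))
  if (is.null(evaluator)) {
    sds <- derive_seeds(config$seed, 2)
    evaluator <- fitness_evaluator(dataset, elm_seed = sds[1],
                                   split_seed = sds[2])
  }
  p <- ncol(dataset$features)
  P <- config$pop_size
  r <- config$visual_radius %||% (0.2 * sqrt(p))
  s <- config$step_size
  mu <- config$minkowski_order
  lo <- config$lower_bound
  hi <- config$upper_bound
  p_a <- config$escape_threshold

  withr::with_seed(config$seed, {
    positions <- matrix(runif(P * p, lo, hi - 1e-9), P, p)
    fitness <- vapply(seq_len(P), function(i) {
      evaluate_mask(evaluator, binarize(positions[i, ]))
    }, numeric(1))
    best_i <- which.max(fitness)
    best_fitness <- fitness[best_i]
    best_mask <- binarize(positions[best_i, ])
    history <- numeric(config$max_iter)

    for (m in seq_len(config$max_iter)) {
      for (i in seq_len(P)) {
        x <- prey_move(positions[i, ], s, 1, lo, hi)
        others <- setdiff(seq_len(P), i)
        better <- others[fitness[others] > fitness[i]]
        if (length(better)) {
          d <- vapply(better, function(j) {
            minkowski_distance(x, positions[j, ], mu)
          }, numeric(1))
          keep <- d <= r
          better <- better[keep]
          d <- d[keep]
        }
        if (length(better)) {
          pick <- better[order(d, -fitness[better], better)[1]]
          x <- attract_move(x, positions[pick, ], config$beta0, 1, s, mu,
                            perturb = TRUE, lower = lo, upper = hi)
        } else {
          x <- prey_move(x, s, 1, lo, hi)
        }
        if (runif(1) > p_a) {
          x <- escape_move(x, r, mu, lo, hi)
        }
        positions[i, ] <- x
        fitness[i] <- evaluate_mask(evaluator, binarize(x))
        if (fitness[i] > best_fitness) {
          best_fitness <- fitness[i]
          best_mask <- binarize(x)
        }
      }
      history[m] <- best_fitness
    }
  })

  new_selection_result(
    mask = best_mask, fitness_history = history, method = "wsa",
    dataset_name = dataset$name,
    config_echo = config[setdiff(names(config), "seed")],
    seed = config$seed)
}

#' Binary particle swarm optimisation baseline
#'
#' Canonical BPSO: continuous velocities with inertia, cognitive and social
#' terms, clamped to `[-v_max, v_max]`, transferred through a sigmoid to
#' per-bit flip probabilities.
#'
#' @inheritParams run_wsa
#' @param config a [baseline_config()].
#' @return a [new_selection_result()].
#' @export
run_bpso <- function(dataset, evaluator = NULL,
                     config = baseline_config("bpso")) {
  run_pso_engine(dataset, evaluator, config, binary = TRUE)
}

#' Continuous particle swarm optimisation baseline
#'
#' Standard PSO on continuous positions in the `[-0.5, 1.5]` box; fitness is
#' evaluated on the [binarize()] projection of each position, which makes
#' continuous PSO well-defined for feature selection.
#'
#' @inheritParams run_bpso
#' @return a [new_selection_result()].
#' @export
run_pso <- function(dataset, evaluator = NULL,
                    config = baseline_config("pso")) {
  run_pso_engine(dataset, evaluator, config, binary = FALSE)
}

run_pso_engine <- function(dataset, evaluator, config, binary) {
  stopifnot(inherits(dataset, "wolf_dataset"))
  if (is.null(evaluator)) {
    sds <- derive_seeds(config$seed, 2)
    evaluator <- fitness_evaluator(dataset, elm_seed = sds[1],
                                   split_seed = sds[2])
  }
  p <- ncol(dataset$features)
  P <- config$pop_size
  lo <- config$lower_bound
  hi <- config$upper_bound
  vmax <- config$v_max
  sigmoid <- function(z) 1 / (1 + exp(-z))

  withr::with_seed(config$seed, {
    if (binary) {
      positions <- matrix(as.numeric(runif(P * p) < 0.5), P, p)
    } else {
      positions <- matrix(runif(P * p, lo, hi - 1e-9), P, p)
    }
    velocity <- matrix(runif(P * p, -1, 1), P, p)
    proj <- function(x) if (binary) as.integer(x) else binarize(x)
    fitness <- vapply(seq_len(P), function(i) {
      evaluate_mask(evaluator, proj(positions[i, ]))
    }, numeric(1))
    pbest <- positions
    pbest_fit <- fitness
    g <- which.max(fitness)
    gbest <- positions[g, ]
    gbest_fit <- fitness[g]
    best_mask <- proj(gbest)
    history <- numeric(config$max_iter)

    for (m in seq_len(config$max_iter)) {
      for (i in seq_len(P)) {
        r1 <- runif(p)
        r2 <- runif(p)
        velocity[i, ] <- config$inertia * velocity[i, ] +
          config$c1 * r1 * (pbest[i, ] - positions[i, ]) +
          config$c2 * r2 * (gbest - positions[i, ])
        velocity[i, ] <- pmin(pmax(velocity[i, ], -vmax), vmax)
        if (binary) {
          positions[i, ] <- as.numeric(runif(p) < sigmoid(velocity[i, ]))
        } else {
          positions[i, ] <- clip_position(positions[i, ] + velocity[i, ],
                                          lo, hi - 1e-9)
        }
        fitness[i] <- evaluate_mask(evaluator, proj(positions[i, ]))
        if (fitness[i] > pbest_fit[i]) {
          pbest[i, ] <- positions[i, ]
          pbest_fit[i] <- fitness[i]
        }
        if (fitness[i] > gbest_fit) {
          gbest <- positions[i, ]
          gbest_fit <- fitness[i]
          best_mask <- proj(positions[i, ])
        }
      }
      history[m] <- gbest_fit
    }
  })

  new_selection_result(
    mask = best_mask, fitness_history = history,
    method = if (binary) "bpso" else "pso", dataset_name = dataset$name,
    config_echo = config[setdiff(names(config), "seed")],
    seed = config$seed)
}
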