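#' Binary projection of a continuous position
#'
#' A continuous position component in the search box `[-0.5, 1.5)` maps to a
#' feature-inclusion bit: 1 iff it lies in `[0.5, 1.5)`, else 0.  Positions
#' are kept clipped strictly below 1.5 by the movement code, so a component
#' pushed hard toward "select" can never wrap around to "deselect".
#'
#' @param x numeric vector of position components.
#' @return integer 0/1 vector of the same length.
#' @export
#' @examples
#' binarize(c(-0.5, 0.49, 0.5, 1.0, 1.49))
binarize <- function(x) {
  as.integer(x >= 0.5 & x < 1.5)
}

#' Minkowski distance
#'
#' `(sum |a_k - b_k|^mu)^(1/mu)`; the distance under which a wolf's visual
#' range is defined.  `mu = 2` is Euclidean, `mu = 1` Manhattan.
#'
#' @param a,b numeric vectors of equal length.
#' @param mu order of the distance, integer >= 1.
#' @return non-negative scalar.
#' @export
minkowski_distance <- function(a, b, mu = 2) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (mu < 1) stop("mu must be >= 1")
  sum(abs(a - b)^mu)^(1 / mu)
}

#' Search configuration for the elitist binary wolf search
#'
#' Defaults follow the published experimental settings where stated
#' (population 15, 100 iterations, positions in `[-0.5, 1.5]`) and the
#' package's documented choices elsewhere: visual radius `0.2 * sqrt(p)`
#' scales with dimension, step size 0.15, unit base attraction, escape
#' threshold 0.25 (the wolf escapes when a uniform draw exceeds it), memory
#' capacity 50 with plain FIFO forgetting.
#'
#' @param pop_size number of wolves (default 15).
#' @param max_iter iterations (default 100).
#' @param visual_radius visual range `r`; `NULL` resolves to
#'   `0.2 * sqrt(n_features)` at run time.
#' @param step_size base step `s` (default 0.15).
#' @param beta0 base attraction at zero distance (default 1).
#' @param escape_threshold `p_a` in (0, 1): escape fires when `rand > p_a`.
#' @param minkowski_order distance order `mu` (default 2).
#' @param memory_capacity worst-position memory size (default 50; 0 disables
#'   the memory).
#' @param memory_forget_count entries evicted, oldest first, when the memory
#'   is full (default 1).
#' @param lower_bound,upper_bound position box (defaults -0.5 and 1.5).
#' @param elitist if `FALSE`, the weight economy, rebirth and memory are all
#'   disabled and every wolf keeps weight `1/P` — the plain-WSA reduction.
#' @param attract_perturb add the small escape-flavoured perturbation
#'   (magnitude `s * w * P`, uniform per component) to every attraction move.
#' @param seed integer seed for the search stream.
#' @return a `ebwsa_config` list.
#' @export
ebwsa_config <- function(pop_size = 15, max_iter = 100, visual_radius = NULL,
                         step_size = 0.15, beta0 = 1, escape_threshold = 0.25,
                         minkowski_order = 2, memory_capacity = 50,
                         memory_forget_count = 1, lower_bound = -0.5,
                         upper_bound = 1.5, elitist = TRUE,
                         attract_perturb = TRUE, seed = 1L) {
  cfg <- list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
              visual_radius = visual_radius, step_size = step_size,
              beta0 = beta0, escape_threshold = escape_threshold,
              minkowski_order = minkowski_order,
              memory_capacity = as.integer(memory_capacity),
              memory_forget_count = as.integer(memory_forget_count),
              lower_bound = lower_bound, upper_bound = upper_bound,
              elitist = isTRUE(elitist),
              attract_perturb = isTRUE(attract_perturb),
              seed = as.integer(seed))
  if (cfg$pop_size < 2) stop("pop_size must be >= 2")
  if (cfg$max_iter < 1) stop("max_iter must be >= 1")
  if (cfg$step_size <= 0) stop("step_size must be > 0")
  if (!is.null(cfg$visual_radius) && cfg$visual_radius <= 0) {
    stop("visual_radius must be > 0")
  }
  if (cfg$escape_threshold <= 0 || cfg$escape_threshold >= 1) {
    stop("escape_threshold must lie in (0, 1)")
  }
  if (cfg$minkowski_order < 1) stop("minkowski_order must be >= 1")
  if (cfg$lower_bound >= cfg$upper_bound) stop("bounds out of order")
  class(cfg) <- "ebwsa_config"
  cfg
}

# --- worst-position memory -------------------------------------------------

#' Bounded FIFO memory of forbidden binary positions
#'
#' Stores the worst binary position of each iteration; candidates equal to a
#' stored entry are rejected by the search and re-generated.  When the
#' memory is full, the oldest `forget_count` entries are evicted before the
#' new entry is inserted.
#'
#' @param capacity maximum number of stored masks (0 = memory disabled).
#' @param forget_count entries forgotten (oldest first) on overflow.
#' @return a `wolf_memory` object (environment-backed).
#' @export
wolf_memory <- function(capacity = 50, forget_count = 1) {
  stopifnot(capacity >= 0, forget_count >= 1)
  mem <- new.env(parent = emptyenv())
  mem$capacity <- as.integer(capacity)
  mem$forget_count <- as.integer(forget_count)
  mem$keys <- character(0)   # insertion order
  class(mem) <- "wolf_memory"
  mem
}

#' @rdname wolf_memory
#' @param mem a [wolf_memory()].
#' @param mask binary vector.
#' @return `memory_contains()`: `TRUE` iff an identical mask is stored.
#' @export
memory_contains <- function(mem, mask) {
  mem$capacity > 0 && mask_key(mask) %in% mem$keys
}

#' @rdname wolf_memory
#' @return `memory_record()`: the memory, invisibly.
#' @export
memory_record <- function(mem, mask) {
  if (mem$capacity == 0) return(invisible(mem))
  if (length(mem$keys) >= mem$capacity) {
    drop <- min(mem$forget_count, length(mem$keys))
    mem$keys <- mem$keys[-seq_len(drop)]
  }
  mem$keys <- c(mem$keys, mask_key(mask))
  invisible(mem)
}

#' @rdname wolf_memory
#' @return `memory_size()`: number of stored masks.
#' @export
memory_size <- function(mem) length(mem$keys)

# --- movement primitives ---------------------------------------------------

#' Attraction move toward a better peer
#'
#' `x_i <- x_i + beta0 * exp(-d^2) * (x_j - x_i) * w * P (+ perturbation)`,
#' where `d` is the Minkowski distance between the two wolves and `w * P`
#' is the elitist step scaling (1 for the plain algorithm).  The optional
#' perturbation is uniform per component with magnitude `s * w * P`.  The
#' result is clipped into the position box.
#'
#' @param x_i current wolf position.
#' @param x_j better peer position.
#' @param beta0 base attraction.
#' @param wp weight-times-population step scaling `w * P`.
#' @param s base step size (perturbation magnitude).
#' @param mu Minkowski order.
#' @param perturb include the perturbation term?
#' @param lower,upper position bounds (upper applied with the binarization
#'   epsilon).
#' @return new position vector.
#' @export
attract_move <- function(x_i, x_j, beta0 = 1, wp = 1, s = 0.15, mu = 2,
                         perturb = TRUE, lower = -0.5, upper = 1.5) {
  d <- minkowski_distance(x_i, x_j, mu)
  x <- x_i + beta0 * exp(-d^2) * (x_j - x_i) * wp
  if (perturb) x <- x + s * wp * runif(length(x_i), -1, 1)
  clip_position(x, lower, upper - 1e-9)
}

#' Prey move
#'
#' `x <- x + s * w * P * rand()` with `rand` uniform in `[-1, 1]` per
#' component; the wolf's independent local search.
#'
#' @inheritParams attract_move
#' @param x current position.
#' @return new (clipped) position.
#' @export
prey_move <- function(x, s = 0.15, wp = 1, lower = -0.5, upper = 1.5) {
  clip_position(x + s * wp * runif(length(x), -1, 1), lower, upper - 1e-9)
}

#' Escape jump beyond the visual field
#'
#' Draws a uniformly random position in the box whose Minkowski distance
#' from the current position exceeds the visual radius `r` (rejection
#' sampling, at most `max_tries` draws, after which the farthest draw seen
#' is taken).  Mirrors the rule that a threatened wolf flees to a random
#' position beyond its visual field.
#'
#' @inheritParams attract_move
#' @param x current position.
#' @param r visual radius (minimum jump length).
#' @param max_tries rejection-sampling budget.
#' @return new (clipped) position.
#' @export
escape_move <- function(x, r, mu = 2, lower = -0.5, upper = 1.5,
                        max_tries = 100) {
  p <- length(x)
  best <- x
  best_d <- -Inf
  for (t in seq_len(max_tries)) {
    z <- runif(p, lower, upper)
    d <- minkowski_distance(z, x, mu)
    if (d > r) return(clip_position(z, lower, upper - 1e-9))
    if (d > best_d) {
      best_d <- d
      best <- z
    }
  }
  clip_position(best, lower, upper - 1e-9)
}

# --- elitist weight economy ------------------------------------------------

#' Share of the unit resource held by improving wolves
#'
#' `gamma` is the sum of the weights of wolves whose fitness strictly
#' improved over the previous iteration — the "living environment"
#' indicator.
#'
#' @param weights weight vector summing to 1.
#' @param fitness current fitness values.
#' @param prev_fitness fitness values from the previous iteration.
#' @return `gamma` in `[0, 1]`.
#' @export
compute_gamma <- function(weights, fitness, prev_fitness) {
  sum(weights[fitness > prev_fitness])
}

#' Living-condition log-factor
#'
#' `sigma = 0.5 * ln((1 - gamma) / gamma)` for `gamma` strictly inside
#' (0, 1): positive when improvers hold less than half the resource (a harsh
#' environment, so improvers are rewarded), negative when they hold more
#' than half, zero at exactly half.  The degenerate cases `gamma = 0` and
#' `gamma = 1` return 0, leaving the weights untouched.
#'
#' @param gamma value from [compute_gamma()].
#' @return `sigma`, a real.
#' @export
compute_sigma <- function(gamma) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (gamma == 0 || gamma == 1) return(0)
  0.5 * log((1 - gamma) / gamma)
}

#' Multiplicative weight update with renormalization
#'
#' Improving wolves' weights are multiplied by `exp(sigma)` and the rest by
#' `exp(-sigma)`, then the vector is renormalized to sum to 1 so the total
#' resource in the environment is conserved.
#'
#' @param weights current weights (sum 1).
#' @param improved logical vector: did each wolf improve this iteration?
#' @param sigma value from [compute_sigma()].
#' @return updated weight vector summing to 1.
#' @export
update_weights <- function(weights, improved, sigma) {
  w <- weights * ifelse(improved, exp(sigma), exp(-sigma))
  w / sum(w)
}

#' Weight bounds enforcement: rebirth and capping
#'
#' A wolf whose weight has starved below `1/(100 P)` is flagged for rebirth
#' and its weight reset to `1/P`; a wolf hoarding more than half the
#' resource has its weight multiplied by a fresh uniform draw.  The vector
#' is then renormalized.  Position re-randomization for reborn wolves is the
#' engine's job (it must consult the worst-position memory); this function
#' only handles the weights.  Draws come from the caller's RNG stream.
#'
#' @param weights normalized weight vector.
#' @return list with `weights` (renormalized), `reborn` (logical), `capped`
#'   (logical).
#' @export
enforce_weight_bounds <- function(weights) {
  p <- length(weights)
  reborn <- weights < 1 / (100 * p)
  capped <- weights > 0.5
  w <- weights
  w[reborn] <- 1 / p
  if (any(capped)) w[capped] <- w[capped] * runif(sum(capped))
  list(weights = w / sum(w), reborn = reborn, capped = capped)
}

# --- the search engine -----------------------------------------------------

#' Run the elitist binary wolf search
#'
#' The full metaheuristic: a pack of wolves holds continuous positions in
#' `[-0.5, 1.5]` whose binary projections are feature masks scored by the
#' wrapper evaluator.  Each iteration every wolf (i) takes a weighted prey
#' step, (ii) is attracted to its nearest better peer within the visual
#' radius (or preys again if there is none), and (iii) escapes to a random
#' far position when a uniform draw exceeds the escape threshold; every
#' sub-move is checked against the worst-position memory and re-generated
#' (bounded attempts) on a hit.  After the pack has moved, the elitist
#' weight economy updates each wolf's resource share from the improvement
#' indicator (gamma / sigma, multiplicative update, renormalization),
#' starving wolves are reborn at random memory-checked positions, hoarding
#' wolves are capped, and the iteration's worst binary position is recorded
#' in the memory.
#'
#' @param dataset a [wolf_dataset()].
#' @param evaluator a [fitness_evaluator()] bound to `dataset`; `NULL`
#'   builds a default 3-fold evaluator with seeds derived from the config
#'   seed.
#' @param config an [ebwsa_config()].
#' @return a [selection_result] (see [new_selection_result()]) whose
#'   `fitness_history` is the best-so-far trace (non-decreasing), with a
#'   per-iteration diagnostic tibble in `$trace` (gamma, sigma, weight sum,
#'   weight range, memory size, position range).
#' @export
run_ebwsa <- function(dataset, evaluator = NULL, config = ebwsa_config()) {
  stopifnot(inherits(dataset, "wolf_dataset"), inherits(config, "ebwsa_config"))
  if (is.null(evaluator)) {
    sds <- derive_seeds(config$seed, 2)
    evaluator <- fitness_evaluator(dataset, elm_seed = sds[1],
                                   split_seed = sds[2])
  }
  run_wolf_engine(dataset, evaluator, config, method = "ebwsa")
}

run_wolf_engine <- function(dataset, evaluator, config, method) {
  p <- ncol(dataset$features)
  P <- config$pop_size
  r <- config$visual_radius %||% (0.2 * sqrt(p))
  s <- config$step_size
  mu <- config$minkowski_order
  lo <- config$lower_bound
  hi <- config$upper_bound
  elitist <- config$elitist
  use_memory <- elitist && config$memory_capacity > 0
  mem <- wolf_memory(if (use_memory) config$memory_capacity else 0,
                     config$memory_forget_count)
  collisions_accepted <- 0L
  rebirths <- 0L
  empty_streak <- 0L

  withr::with_seed(config$seed, {
    positions <- matrix(runif(P * p, lo, hi - 1e-9), P, p)
    fitness <- vapply(seq_len(P), function(i) {
      evaluate_mask(evaluator, binarize(positions[i, ]))
    }, numeric(1))
    weights <- rep(1 / P, P)
    best_i <- which.max(fitness)
    best_fitness <- fitness[best_i]
    best_mask <- binarize(positions[best_i, ])
    history <- numeric(config$max_iter)
    trace <- vector("list", config$max_iter)

    # propose() retries while the candidate's mask sits in the memory: first
    # by re-applying the move operator, then (a small local step may be unable
    # to leave a forbidden mask) by generating a fresh uniform location.
    # After max_attempts the candidate is accepted anyway (tiny mask spaces
    # would otherwise livelock) and the event is counted.
    propose <- function(gen, max_attempts = 10L) {
      cand <- gen()
      if (!use_memory) return(cand)
      attempt <- 1L
      while (memory_contains(mem, binarize(cand)) && attempt < max_attempts) {
        cand <- if (attempt < 5L) gen() else
          clip_position(runif(p, lo, hi), lo, hi - 1e-9)
        attempt <- attempt + 1L
      }
      if (memory_contains(mem, binarize(cand))) {
        collisions_accepted <<- collisions_accepted + 1L
      }
      cand
    }

    for (m in seq_len(config$max_iter)) {
      prev_fitness <- fitness
      for (i in seq_len(P)) {
        wp <- if (elitist) weights[i] * P else 1
        x <- positions[i, ]
        # (i) independent prey step
        x <- propose(function() prey_move(x, s, wp, lo, hi))
        # (ii) attraction to the nearest better peer in visual range
        others <- setdiff(seq_len(P), i)
        better <- others[fitness[others] > fitness[i]]
        if (length(better)) {
          d <- vapply(better, function(j) {
            minkowski_distance(x, positions[j, ], mu)
          }, numeric(1))
          in_range <- d <= r
          better <- better[in_range]
          d <- d[in_range]
        }
        if (length(better)) {
          pick <- better[order(d, -fitness[better], better)[1]]
          xj <- positions[pick, ]
          x <- propose(function() {
            attract_move(x, xj, config$beta0, wp, s, mu,
                         perturb = config$attract_perturb, lower = lo,
                         upper = hi)
          })
        } else {
          x <- propose(function() prey_move(x, s, wp, lo, hi))
        }
        # (iii) escape beyond the visual field
        if (runif(1) > config$escape_threshold) {
          x <- propose(function() escape_move(x, r, mu, lo, hi))
        }
        positions[i, ] <- x
        fitness[i] <- evaluate_mask(evaluator, binarize(x))
        if (fitness[i] > best_fitness) {
          best_fitness <- fitness[i]
          best_mask <- binarize(x)
        }
      }

      gamma <- NA_real_
      sigma <- NA_real_
      if (elitist) {
        improved <- fitness > prev_fitness
        gamma <- compute_gamma(weights, fitness, prev_fitness)
        sigma <- compute_sigma(gamma)
        weights <- update_weights(weights, improved, sigma)
        wb <- enforce_weight_bounds(weights)
        weights <- wb$weights
        for (i in which(wb$reborn)) {
          positions[i, ] <- propose(function() {
            clip_position(runif(p, lo, hi), lo, hi - 1e-9)
          })
          fitness[i] <- evaluate_mask(evaluator, binarize(positions[i, ]))
          prev_fitness[i] <- fitness[i]  # neutral restart
          rebirths <- rebirths + 1L
          if (fitness[i] > best_fitness) {
            best_fitness <- fitness[i]
            best_mask <- binarize(positions[i, ])
          }
        }
        if (use_memory) {
          memory_record(mem, binarize(positions[which.min(fitness), ]))
        }
      }

      history[m] <- best_fitness
      trace[[m]] <- tibble::tibble(
        iteration = m, best_fitness = best_fitness, gamma = gamma,
        sigma = sigma, weight_sum = sum(weights),
        min_weight = min(weights), max_weight = max(weights),
        memory_size = memory_size(mem), min_position = min(positions),
        max_position = max(positions))

      if (all(positions < 0.5 | positions >= 1.5)) {
        empty_streak <- empty_streak + 1L
        if (empty_streak >= 5L) {
          stop("every wolf's mask has been empty for 5 consecutive ",
               "iterations; the configuration is pathological")
        }
      } else {
        empty_streak <- 0L
      }
    }
  })

  new_selection_result(
    mask = best_mask, fitness_history = history, method = method,
    dataset_name = dataset$name,
    config_echo = config[setdiff(names(config), "seed")],
    seed = config$seed, trace = dplyr::bind_rows(trace),
    diagnostics = list(memory_collisions_accepted = collisions_accepted,
                       rebirths = rebirths,
                       evaluations = evaluator$n_trainings))
}
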