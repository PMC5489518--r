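# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Tiny labelled data frame used across the I/O tests.
tiny_df <- function() {
  data.frame(f1 = c(1, 3, 5), f2 = c(2, 4, 6), class = c("A", "B", "A"),
             stringsAsFactors = FALSE)
}

# A well-separated small synthetic problem for quick selector runs.
small_problem <- function() {
  fixture("small_problem", function() {
    g <- generate_synth(80, 30, 5, effect_size = 2.5, seed = 11,
                        name = "small")
    sds <- derive_seeds(42, 2)
    list(gen = g,
         evaluator = fitness_evaluator(g$dataset, elm_seed = sds[1],
                                       split_seed = sds[2]))
  })
}

# The 8-feature oracle problem: every one of the 255 non-empty masks is
# enumerated on a shared evaluator, so the exhaustive optimum is known and
# every later selector run on the same evaluator is a cache hit.
oracle_problem <- function() {
  fixture("oracle_problem", function() {
    g <- generate_synth(100, 8, 3, effect_size = 3, seed = 1,
                        name = "oracle8")
    sds <- derive_seeds(42, 2)
    ev <- fitness_evaluator(g$dataset, elm_seed = sds[1], split_seed = sds[2])
    masks <- as.matrix(expand.grid(rep(list(0:1), 8)))[-1, , drop = FALSE]
    fits <- apply(masks, 1, function(m) evaluate_mask(ev, m))
    list(gen = g, evaluator = ev, masks = masks, fits = fits,
         optimum = max(fits))
  })
}

expect_selection_result <- function(res) {
  expect_s3_class(res, "selection_result")
  expect_true(all(res$mask %in% c(0L, 1L)))
  expect_identical(res$selected_count, sum(res$mask == 1L))
  expect_true(all(diff(res$fitness_history) >= 0))
}
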