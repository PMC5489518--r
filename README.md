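# wolfselect

Wrapper feature selection for high-dimensional classification data —
expression-style matrices with tens of samples and thousands of features —
using the **elitist binary wolf search**: a swarm metaheuristic in which
each wolf's continuous position in `[-0.5, 1.5]^p` projects to a binary
feature mask, and a conserved "resource" economy rescales each wolf's step
size by how well it has been doing. The package is aimed at anyone
benchmarking subset selectors on omics-style matrices: it ships the elitist
search, the plain binary wolf search, binary PSO and continuous PSO under
one fitness contract, so comparisons hold the objective fixed.

## The method in brief

A pack of `P` wolves searches the box `[-0.5, 1.5]^p`; the mask is
`X_j = 1 iff 0.5 <= x_j < 1.5`. Fitness of a mask is the cross-validated
accuracy of an **extreme learning machine** (random hidden layer, uniform
on `[-1, 1]`; output weights by minimum-norm least squares) trained on the
masked columns, under fixed stratified splits so fitness is deterministic
and cacheable. Movement per iteration and wolf:

- prey: `x <- x + s · wP · rand[-1, 1]`
- attract (nearest better peer within Minkowski radius `r`):
  `x <- x + β₀ e^(−d²) (x' − x) · wP`
- escape (probability `1 − p_a`): jump to a random position at distance
  `> r`.

With `γ` the summed weight of wolves that improved this iteration and
`σ = ½ ln((1−γ)/γ)`, improvers' weights are multiplied by `e^σ`, the
rest by `e^(−σ)`, then renormalised to sum 1. Starved wolves
(`w < 1/(100P)`) are reborn at random positions with weight `1/P`;
hoarders (`w > ½`) are knocked down by a uniform draw. Each iteration's
worst mask enters a bounded FIFO memory and proposed moves matching a
stored mask are re-drawn. Full details and every resolved ambiguity are in
the vignette (`vignettes/wolf-search-feature-selection.Rmd`).

## Worked example

```r
library(wolfselect)

# 100 samples x 40 features, 5 informative at 2.5 noise-SDs, ground truth known
g <- generate_synth(n_samples = 100, n_features = 40, n_informative = 5,
                    effect_size = 2.5, seed = 1)

res <- wolf_select(g$dataset, method = "ebwsa", pop_size = 10,
                   max_iter = 30, seed = 42, folds = 5, repeats = 3)
res
#> <selection_result: ebwsa on 'synth'>
#>   24/40 features selected (60.00% of the dimension), best fitness 0.9700, seed 42
#>   final metrics: accuracy=0.923, kappa=0.847, precision=0.924, recall=0.923, dimension_pct=60.000

sum(res$mask[g$informative])   # informative features recovered
#> [1] 5

glance(res)                    # one-row tibble summary
tidy(res)                      # per-iteration trace (gamma, sigma, weights, ...)
autoplot(res)                  # best-so-far fitness curve
```

The printed numbers read as: the search kept 24 of 40 features (60% of the
dimension), its internal 3-fold wrapper fitness peaked at 0.97, and the
stricter repeated 5-fold evaluation of that mask gives accuracy 0.92 with
chance-corrected agreement (kappa) 0.85 — while all 5 planted informative
features were recovered.

Repeated-run comparisons in the shape of a benchmark table:

```r
rep <- run_experiment(g$dataset, methods = c("ebwsa", "wsa"), repeats = 5,
                      pop_size = 10, max_iter = 30, seed = 7, folds = 5)
glance(rep)    # method x metric, mean and sd over repeats
```

A thin command-line wrapper covers the same operations
(`inst/cli/wolfselect.R`; subcommands `select`, `experiment`, `synth`,
`evaluate`).

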