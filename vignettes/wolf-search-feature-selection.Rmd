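---
title: "Elitist binary wolf search for wrapper feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elitist binary wolf search for wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Expression-style datasets routinely pair a few dozen samples with thousands
to tens of thousands of features. Classifiers trained on the raw matrix are
unstable and slow, and most features are noise. Choosing the best feature
subset is a combinatorial problem — `2^p - 1` candidate masks — so
exhaustive search is hopeless beyond a handful of features, and wrapper
selection (scoring a subset by actually training a classifier on it) has to
be driven by a heuristic search.

`wolfselect` implements one such heuristic, the elitist binary wolf search,
together with the plain binary wolf search, binary PSO and continuous PSO
baselines, an extreme learning machine (ELM) wrapper fitness, the usual
classification metrics, and a synthetic generator with planted signal so
every claim in this vignette is checkable by the package's own tests.

## The search model

Each of `P` wolves carries a continuous position `x` in the box
`[-0.5, 1.5]^p`. The binary projection

    X_j = 1  iff  0.5 <= x_j < 1.5,   else 0

turns a position into a feature mask — each coordinate is a yes/no vote for
one feature. Distances between wolves use the Minkowski norm of order `mu`
(default 2). Per iteration each wolf:

1. **preys**: `x <- x + s * w * P * rand()`, `rand` uniform in `[-1, 1]`
   per component — an independent local step;
2. **is attracted** to its nearest better peer `x'` within the visual
   radius `r`: `x <- x + beta0 * exp(-d^2) * (x' - x) * w * P`, plus a small
   perturbation of magnitude `s * w * P` (switchable); if no better peer is
   visible it preys again;
3. **escapes** with probability `1 - p_a`: it jumps to a uniformly random
   position at Minkowski distance greater than `r` from where it stands.

`w` is the wolf's share of a conserved unit resource, and `w * P` floats
around 1, turning the fixed step size into an earned one — this is the
elitist economy. After the pack moves, with `gamma` the summed weight of
wolves whose fitness strictly improved this iteration:

    sigma = 0.5 * ln((1 - gamma) / gamma),   sigma = 0 at gamma in {0, 1}

improvers multiply their weight by `exp(sigma)`, the rest by `exp(-sigma)`,
and weights are renormalised to sum 1. When improvers hold less than half
the resource (`gamma < 0.5`, a harsh environment) `sigma > 0` and they are
rewarded; when they hold more than half, the flow reverses and the weak are
subsidised. A wolf starved below `1/(100 P)` is eliminated and reborn at a
random position with weight `1/P`; a wolf hoarding more than `1/2` has its
weight multiplied by a uniform draw. Finally the iteration's worst binary
position enters a bounded FIFO memory; any later proposed move whose mask
matches a stored entry is re-drawn (up to 10 attempts, then accepted and
counted), steering the pack away from known-bad regions.

The sign convention for `sigma` deserves a note: the two plausible forms
differ by a reciprocal inside the logarithm. We use
`ln((1 - gamma)/gamma)`, the form consistent with "improvers gain when they
hold less than half", and treat the opposite sign appearing in some
pseudocode renderings of this family of algorithms as a transcription slip.
The acceptance suite pins the behaviour: `sigma(0.25) = 0.5 ln 3 > 0`.

### Escape: jump, not step

The escape move is implemented as a jump *to* a redrawn position beyond the
visual radius, rather than a step of length `s * w * P` in a far direction.
A step scaled by `s * w * P` (around 0.15) can never satisfy the defining
constraint — displacement larger than `r` — in any dimension regime this
package targets, whereas the jump always can while bounds permit. The
minimum-length property is asserted over 1,000 seeded draws in the tests.

### Other resolved ambiguities

- **Evaluation count.** Fitness is evaluated once per wolf per iteration,
  at the final position after the prey/attract/escape sub-moves; memory
  checks still guard every sub-move. This keeps the wrapper cost at
  `P * T` classifier trainings per run (minus cache hits).
- **Peer choice.** Under attraction a wolf follows the *nearest* better
  peer within radius, ties broken by higher fitness then lower index.
- **First iteration.** `prev_fitness` is initialised to the initial
  fitness, so no wolf counts as improved before it has moved
  (`gamma = 0`, `sigma = 0`: a neutral start). Reborn wolves are treated
  the same way.
- **Clipping.** Positions are clipped to `[-0.5, 1.5 - 1e-9]` after every
  move so the half-open binarization band cannot flip a maximal component
  to 0.

## The wrapper fitness

Fitness of a mask is the mean validation accuracy of an ELM trained on the
masked columns: a single-hidden-layer network whose hidden weights and
biases are drawn once, uniform on `[-1, 1]`, and whose output layer is the
minimum-norm least-squares solution (SVD pseudo-inverse) against one-hot
targets. Inputs are standardised inside the model (constant columns map to
0) because a sigmoid hidden layer saturates on raw expression scales. The
hidden width defaults to `min(100, ceiling(n/2))`. The bound by *half* the
training-sample count is deliberate: an unregularised least-squares output
layer at `L ~ n` sits at the interpolation threshold, where training error
vanishes and validation accuracy collapses even on strongly separated
classes — exactly the fold sizes a 3-fold wrapper produces on 100–150
sample datasets. Keeping `L <= n/2` stays in the over-determined regime
where the random-feature fit generalises. Hidden parameters are drawn
neuron-major, so nested widths at one
seed share their leading neurons; that makes "residual never increases with
width" a testable exact property rather than a tendency.

Search-time fitness uses one stratified 3-fold split, fixed per evaluator,
with a fixed hidden seed: fitness is then a *deterministic function of the
mask*, which the evaluator caches. Without that the metaheuristic chases
classifier noise, and the cache would be meaningless. Reported results use
the stricter protocol of `final_evaluate()`: stratified 10-fold
cross-validation, repeated with distinct fold seeds, summarised as
mean ± SD of accuracy, Cohen's kappa, precision and recall (weighted by
class support by default; macro averaging is available). The gap between
the cheap search fitness and the strict final protocol is itself tested:
across random masks the two agree within 0.15 absolute.

The all-zero mask scores 0 without touching the classifier. It is not
repaired: escape and rebirth move wolves off it, and a configuration that
keeps the entire pack on empty masks for five consecutive iterations aborts
as pathological.

## The synthetic benchmark

`generate_synth()` emulates the shape regime of public expression
benchmarks — 60–200 samples, hundreds to thousands of features, binary
labels, a small informative subset — with known ground truth. Informative
features are class-conditional Gaussians separated by `effect_size`
noise-SDs; optional redundant features are unit-slope noisy copies
(`eps ~ N(0, 0.1 * noise_sd)`); everything else is independent noise;
column order is shuffled. It deliberately does *not* model microarray
normalisation artifacts, batch effects, heavy tails or gene-gene
correlation structure, so passing tests demonstrate correct search
behaviour and recovery of planted signal, not performance on real assays.

Default study conditions used by the tests: an 8-feature problem
(`n = 100`, 3 informative, `effect_size = 3`) small enough to enumerate all
255 masks — giving an exact global optimum the search must reach — and a
200-feature problem (`n = 150`, 10 informative, `effect_size = 2.5`) for
recovery, run at the published budget of 15 wolves and 100 iterations with
seeds 0–9. The acceptance script repeats these at a reduced number of
repetitions (5 oracle seeds, 3 recovery runs of 60 iterations), sizes
chosen so a single-CPU rerun of the whole pipeline stays comfortable.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pop_size` | 15 | wolves; the published comparison setting |
| `max_iter` | 100 | iterations; ditto |
| `visual_radius` | `0.2 * sqrt(p)` | attraction/escape scale; grows with dimension so the visual ball keeps a constant relative reach |
| `step_size` | 0.15 | base prey step, in position units (box is 2 wide) |
| `beta0` | 1 | attraction at zero distance |
| `escape_threshold` | 0.25 | escape fires when `rand > p_a`; small values mean frequent escapes and aggressive exploration |
| `memory_capacity` | 50 | worst positions remembered; long memories cost lookups |
| `memory_forget_count` | 1 | plain FIFO |
| `inertia`, `c1 = c2`, `v_max` | 0.8, 2, 4 | PSO/BPSO: published inertia, canonical acceleration and clamp |

The radius, step size, attraction base and escape threshold are not stated
by the source experiments; the defaults above were fixed once from the
geometry of the `[-0.5, 1.5]` box (a prey step of ~7% of the box, a radius
an order of magnitude larger) and are all exposed in the configuration and
echoed into every result for reproducibility.

## Reproducibility machinery

Every user-facing run takes one master seed. `derive_seeds()` fans it out
(seeded draw of 32-bit integers) to the search stream, the ELM hidden
layer, and the split generator, so components can be re-seeded
independently and a result is reconstructible from its `config_echo` plus
`seed` alone. Seed-isolated draws (`withr::with_seed`) keep the classifier
from perturbing the search stream. Results serialise to JSON at 17
significant digits, which round-trips doubles bit-exactly.

## Known limitations

- The wrapper optimises accuracy only; subset size is emergent, not
  penalised. On weak-signal data the selected mask can stay large.
- The memory stores binary projections, not continuous positions; two
  wolves at different continuous positions with the same mask are
  indistinguishable to it. That is intended — the mask is what fitness
  sees — but it means the memory cannot discourage continuous-space
  revisits within the same mask.
- With the default `escape_threshold = 0.25` the escape branch fires on
  roughly three quarters of wolf-iterations; exploration dominates until
  the weight economy concentrates step sizes on the elite. Raise `p_a` for
  a more exploitative search.
- The ELM is unregularised; with very wide layers and tiny folds the
  min-norm solution can be unstable. The `min(100, 2n)` width bound is the
  guard.

## What the tests pin down

Unit oracles (hand algebra for the weight economy, brute-force distance
sums, `MASS::ginv` against the package's own SVD solve), property checks
(weight conservation to 1e-9 per iteration, positions never leaving the
box, monotone best-so-far traces, FIFO memory semantics), an
exhaustive-search equivalence (the search must reach the enumerated global
optimum on 8 features in most seeds), planted-signal recovery at 200
features, and a reduction test: with the weight economy frozen and the
memory off, the elitist search's best-fitness distribution over 20 seeds is
statistically indistinguishable (Kolmogorov–Smirnov, `alpha = 0.01`) from
the independently implemented plain wolf search — the elitist machinery is
exactly the delta between the two code paths.
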