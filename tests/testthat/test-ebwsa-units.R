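test_that("binarization follows the half-open [0.5, 1.5) selection band", {
  expect_identical(binarize(c(0.7, -0.3, 0.49, 0.5)), c(1L, 0L, 0L, 1L))
  expect_identical(binarize(c(-0.5, 1.49)), c(0L, 1L))
  # out-of-box positions are clipped before projection by the movement code
  clipped <- wolfselect:::clip_position(2.7, -0.5, 1.5 - 1e-9)
  expect_identical(binarize(clipped), 1L)
})

test_that("minkowski distance matches hand values and a brute-force oracle", {
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), 2), 5)
  expect_equal(minkowski_distance(c(0, 0), c(1, 2), 1), 3)
  withr::with_seed(3, {
    a <- rnorm(50); b <- rnorm(50)
  })
  oracle <- function(a, b, mu) {
    acc <- 0
    for (k in seq_along(a)) acc <- acc + abs(a[k] - b[k])^mu
    acc^(1 / mu)
  }
  for (mu in c(1, 2, 3)) {
    expect_equal(minkowski_distance(a, b, mu), oracle(a, b, mu),
                 tolerance = 1e-12)
  }
  expect_error(minkowski_distance(1:3, 1:4), "length")
})

test_that("attraction pulls by beta0 * exp(-d^2) scaled by the weight share", {
  # 1-d: from 0 toward 1 at distance 1 -> lands at exp(-1)
  got <- attract_move(0, 1, beta0 = 1, wp = 1, s = 0.1, perturb = FALSE)
  expect_equal(got, exp(-1), tolerance = 1e-12)
  # zero weight share freezes the wolf (perturbation suppressed)
  expect_equal(attract_move(0.3, 1.2, wp = 0, perturb = FALSE), 0.3)
  # coincident wolves: zero displacement
  expect_equal(attract_move(c(0.2, 0.4), c(0.2, 0.4), perturb = FALSE),
               c(0.2, 0.4))
})

test_that("prey steps scale by s * w * P and respect the box", {
  # the move is exactly x + s*wp*rand with rand the next uniform [-1,1] draws,
  # so x = 0.2, s = 0.1, wp = 1 and a forced draw of 1 lands on 0.3
  x0 <- c(0.2, 0.6, -0.1)
  draw <- withr::with_seed(5, runif(3, -1, 1))
  got <- withr::with_seed(5, prey_move(x0, s = 0.1, wp = 1.5))
  expect_equal(got, x0 + 0.1 * 1.5 * draw, tolerance = 1e-15)
  # s = 0 keeps the position fixed
  withr::with_seed(2, expect_equal(prey_move(c(0.1, 0.9), s = 0, wp = 1),
                                   c(0.1, 0.9)))
  # positions stay inside [-0.5, 1.5) over many draws
  withr::with_seed(3, {
    for (i in 1:50) {
      p <- prey_move(runif(10, -0.5, 1.5), s = 5, wp = 2)
      expect_true(all(p >= -0.5 & p < 1.5))
    }
  })
})

test_that("escape jumps exceed the visual radius before clipping", {
  r <- 0.2 * sqrt(8)
  withr::with_seed(7, {
    far <- vapply(1:1000, function(i) {
      x <- runif(8, -0.5, 1.5)
      z <- escape_move(x, r = r, mu = 2)
      minkowski_distance(z, x, 2)
    }, numeric(1))
  })
  expect_true(all(far > r))
})

test_that("gamma sums the weights of strictly improved wolves", {
  w <- rep(0.2, 5)
  prev <- c(0.5, 0.5, 0.5, 0.5, 0.5)
  expect_equal(compute_gamma(w, c(0.4, 0.5, 0.5, 0.6, 0.7), prev), 0.4)
  expect_equal(compute_gamma(w, rep(0.4, 5), prev), 0)
  expect_equal(compute_gamma(w, rep(0.9, 5), prev), 1)
})

test_that("sigma follows 0.5*ln((1-gamma)/gamma) with neutral endpoints", {
  expect_equal(compute_sigma(0.5), 0)
  expect_equal(compute_sigma(0.25), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(compute_sigma(0.8), 0.5 * log(0.25), tolerance = 1e-12)
  expect_equal(compute_sigma(0), 0)
  expect_equal(compute_sigma(1), 0)
  expect_error(compute_sigma(1.2), "gamma")
})

test_that("the multiplicative weight update conserves the unit resource", {
  w <- rep(0.2, 5)
  improved <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  sigma <- compute_sigma(compute_gamma(w, improved * 1, rep(0, 5)))
  w2 <- update_weights(w, improved, sigma)
  expect_equal(w2[4], 0.25, tolerance = 1e-12)
  expect_equal(w2[1], 1 / 6, tolerance = 1e-12)
  expect_equal(sum(w2), 1, tolerance = 1e-12)
  expect_identical(update_weights(w, improved, 0), w)
})

test_that("weight bounds trigger rebirth below 1/(100P) and capping above 1/2", {
  w <- c(0.0009, rep((1 - 0.0009) / 9, 9))  # P = 10, first wolf starved
  out <- withr::with_seed(1, enforce_weight_bounds(w))
  expect_true(out$reborn[1])
  expect_false(any(out$reborn[-1]))
  expect_equal(sum(out$weights), 1, tolerance = 1e-12)
  # before renormalization the reborn weight is exactly 1/P
  pre <- w; pre[1] <- 1 / 10
  expect_equal(out$weights, pre / sum(pre), tolerance = 1e-12)

  w <- c(0.6, rep(0.4 / 4, 4))
  out <- withr::with_seed(2, enforce_weight_bounds(w))
  expect_true(out$capped[1])
  u <- withr::with_seed(2, runif(1))
  manual <- c(0.6 * u, rep(0.1, 4))
  expect_equal(out$weights, manual / sum(manual), tolerance = 1e-12)

  w <- rep(0.2, 5)  # nothing crosses a threshold
  out <- enforce_weight_bounds(w)
  expect_identical(out$weights, w)
  expect_false(any(out$reborn | out$capped))
})

test_that("the worst-position memory is a bounded FIFO with exact membership", {
  mem <- wolf_memory(capacity = 5, forget_count = 2)
  expect_false(memory_contains(mem, c(1, 0, 1)))  # empty: everything accepted
  vecs <- lapply(1:6, function(i) as.integer(intToBits(i)[1:4]))
  memory_record(mem, vecs[[1]])
  expect_true(memory_contains(mem, vecs[[1]]))
  for (i in 2:6) memory_record(mem, vecs[[i]])
  # 5 filled, sixth insert evicts the 2 oldest first: size 4, oldest 2 gone
  expect_identical(memory_size(mem), 4L)
  expect_false(memory_contains(mem, vecs[[1]]))
  expect_false(memory_contains(mem, vecs[[2]]))
  expect_true(all(vapply(3:6, function(i) memory_contains(mem, vecs[[i]]),
                         logical(1))))
  # capacity 0 disables the memory entirely
  off <- wolf_memory(capacity = 0)
  memory_record(off, c(1L, 1L))
  expect_false(memory_contains(off, c(1L, 1L)))
  expect_identical(memory_size(off), 0L)
})
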