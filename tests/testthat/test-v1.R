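test_that("V1 simple-cell kernels are zero-sum, antisymmetric, zero at origin", {
  p <- default_params
  for (th in c(0, pi / 7, pi / 3, 1.9, 4.1)) {
    v <- v1_simple_kernel(th, p$sigma, p)
    expect_lt(abs(sum(v)), 1e-10)
    expect_equal(v1_simple_kernel(th + pi, p$sigma, p), -v, tolerance = 1e-10)
    ctr <- (nrow(v) + 1) / 2
    expect_equal(v[ctr, ctr], 0)
  }
  expect_error(v1_simple_kernel(0, -1, p), "positive")
})

test_that("double-opponent stacks: linear zero case and flat-input silence", {
  zero <- opponent_set(rg = matrix(0, 20, 20), gr = matrix(0, 20, 20),
                       by = matrix(0, 20, 20), yb = matrix(0, 20, 20))
  st <- double_opponent_stack(zero, 1.1, default_params)
  for (ch in st) expect_equal(max(abs(ch)), 0)
  # spatially uniform opponent input: the derivative kernel integrates to
  # zero, so the response is zero (and trivially spatially constant)
  flat <- opponent_set(rg = matrix(0.3, 24, 24), gr = matrix(0, 24, 24),
                       by = matrix(0.3, 24, 24), yb = matrix(0, 24, 24))
  stf <- double_opponent_stack(flat, 1.1, default_params)
  expect_lt(max(abs(stf$rg)), 1e-10)
  expect_true(all(stf$rg >= 0))
})

test_that("a chromatic step edge drives rg maximally at the edge normal", {
  iso <- make_isoluminant_edge(c(64, 64))
  opp <- single_opponent(iso$image, default_params)
  st <- double_opponent_stack(opp, 1.1, default_params)
  th <- orientations_of(st$rg)
  # vertical edge: normal along x, i.e. theta = 0 or pi
  mid <- ceiling(64 / 2)
  prof <- st$rg[32, mid, ]
  best <- th[which.max(prof)]
  expect_true(min(abs(c(best, best - pi, best - 2 * pi))) < 1e-9)
})

test_that("MAX pooling dominates slices and ignores orientation order", {
  st <- withr::with_seed(3, array(stats::runif(16 * 16 * 6), c(16, 16, 6)))
  mp <- max_pool(st)
  for (i in 1:6) expect_true(all(mp >= st[, , i]))
  expect_equal(max_pool(st[, , c(4, 1, 6, 2, 3, 5)]), mp)
  expect_equal(max_pool(st[, , 2, drop = FALSE]), st[, , 2])
})

test_that("self-normalisation is bounded, guarded, and scale invariant", {
  # white wall: all-zero input passes with no numerical error
  z <- normalise_response(matrix(0, 8, 8), eps = 1e-8)
  expect_equal(z, matrix(0, 8, 8))
  # constant field a: a^2 / (a^2 + eps)
  a <- matrix(1, 8, 8)
  expect_equal(normalise_response(a, 1e-8)[1, 1], 1 / (1 + 1e-8))
  f <- random_field(seed = 8)
  n1 <- normalise_response(f, 1e-8)
  n10 <- normalise_response(10 * f, 1e-8)
  expect_lt(max(abs(n1 - n10)), 1e-7)
  expect_true(max(n1) < 1)
  expect_error(normalise_response(matrix(-1, 4, 4)), "non-negative")
})

test_that("normalised responses stay in [0, 1) across random stimuli", {
  for (seed in 1:5) {
    img <- random_image(48, 48, seed = seed)
    v1 <- v1_response(img, default_params)
    for (d in v1$D) {
      expect_true(min(d) >= 0)
      expect_true(max(d) < 1)
    }
  }
})

test_that("colour-orientation map is the across-channel maximum", {
  th <- orientation_set(6)
  mk <- function(seed) orientation_stack(
    withr::with_seed(seed, array(stats::runif(12 * 12 * 6), c(12, 12, 6))), th)
  stacks <- list(rg = mk(1), gr = mk(2), by = mk(3), yb = mk(4))
  cm <- colour_orientation_map(stacks)
  for (s in stacks) expect_true(all(cm >= s))
  expect_equal(unclass(colour_orientation_map(
    list(rg = stacks$rg, gr = stacks$rg, by = stacks$rg, yb = stacks$rg))),
    unclass(stacks$rg), ignore_attr = TRUE)
  expect_error(colour_orientation_map(stacks[1:3]), "channels")
})

test_that("tuning profiles track grating orientation within one probe step", {
  p <- default_params
  step <- 2 * pi / 36
  for (th0 in c(0, pi / 4, pi / 2, 3 * pi / 4)) {
    g <- make_grating(c(64, 64), orientation = th0, frequency = 0.1)
    prof <- tuning_profile(g$image, c(32, 32), 36, p)
    expect_equal(nrow(prof), 36)
    expect_true(all(prof$response >= 0 & prof$response < 1))
    best <- prof$theta[which.max(prof$response)]
    normal <- (th0 + pi / 2) %% pi
    d <- abs(((best - normal) + pi / 2) %% pi - pi / 2)
    expect_lte(d, step + 1e-9)
  }
  # no structure, no response
  flatp <- tuning_profile(flat_image(c(0.5, 0.5, 0.5)), c(16, 16), 36, p)
  expect_lt(max(flatp$response), 1e-6)
  expect_error(tuning_profile(flat_image(c(0.5, 0.5, 0.5)), c(40, 2), 36, p),
               "bounds")
})
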