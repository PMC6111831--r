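test_that("DOG+ kernel is a unit-mass annulus with the predicted peak radius", {
  wd <- dog_plus_kernel(1.1, 4)
  ctr <- (nrow(wd) + 1) / 2
  expect_equal(wd[ctr, ctr], 0)
  expect_equal(sum(wd), 1, tolerance = 1e-10)
  expect_true(all(wd >= 0))
  # independent 1-D oracle: the rectified radial difference of the two
  # normalised Gaussians peaks where the closed form is maximal
  f <- function(r, s = 1.1, rho = 4) {
    exp(-r^2 / (2 * (rho * s)^2)) / (2 * pi * (rho * s)^2) -
      exp(-r^2 / (2 * s^2)) / (2 * pi * s^2)
  }
  r_star <- stats::optimize(f, c(0.1, 15), maximum = TRUE)$maximum
  prof <- wd[ctr, ctr:ncol(wd)]
  r_grid <- which.max(prof) - 1
  expect_lt(abs(r_grid - r_star), 1)
  # rises from zero, then decays monotonically beyond the peak
  expect_true(all(diff(prof[seq_len(r_grid + 1)]) >= 0))
  expect_true(all(diff(prof[seq(r_grid + 1, length(prof))]) <= 0))
  expect_error(dog_plus_kernel(1.1, 0.4), "annulus")
  # strict mode reproduces the degenerate printed ratio: a centre blob
  wds <- dog_plus_kernel(1.1, 0.4, strict = TRUE)
  ctrs <- (nrow(wds) + 1) / 2
  expect_equal(which.max(wds), (ctrs - 1) * nrow(wds) + ctrs)
})

test_that("raised-cosine window has unit centre, zero corners, 4-fold symmetry", {
  w <- raised_cosine_window(11)
  expect_equal(dim(w), c(11L, 11L))
  expect_equal(w[6, 6], 1)
  expect_equal(w[1, 1], 0)
  expect_equal(w[1, 11], 0)
  expect_equal(w, t(w))
  expect_equal(w, w[11:1, 11:1])
  expect_error(raised_cosine_window(10), "odd")
})

test_that("local statistics: uniform input, contrast ordering, luminance order", {
  flat <- flat_image(c(0.6, 0.6, 0.6))
  ls <- local_statistics(flat)
  expect_equal(ls$L, matrix(0, 32, 32))  # rescale of a constant is zero
  expect_equal(ls$C, matrix(0, 32, 32))
  expect_equal(ls$L_raw, matrix(0.6, 32, 32), tolerance = 1e-12)
  # checkerboard has more local contrast than a smooth ramp of equal mean
  chk <- rgb_image(matrix(((row(matrix(0, 32, 32)) +
                              col(matrix(0, 32, 32))) %% 2) * 0.5 + 0.25,
                          32, 32))
  ramp <- rgb_image(matrix(seq(0.25, 0.75, length.out = 32), 32, 32,
                           byrow = TRUE))
  expect_gt(mean(local_statistics(chk)$C_raw),
            mean(local_statistics(ramp)$C_raw))
  # two uniform half-planes: the brighter half has larger raw L off-boundary
  tt <- make_two_tone_edge(c(32, 32))
  lr <- local_statistics(tt$image)$L_raw
  expect_gt(lr[16, 28], lr[16, 4])
})

test_that("feature modulation weights are convex, exact on uniform input", {
  wd <- dog_plus_kernel(1.1, 4)
  flatL <- matrix(0.4, 40, 40)
  fm <- feature_modulation_weights(flatL, flatL, wd, sigma1 = 0.05)
  expect_equal(fm$W_L, matrix(1, 40, 40), tolerance = 1e-10)
  expect_equal(fm$W_C, matrix(1, 40, 40), tolerance = 1e-10)
  # a centre pixel differing from an otherwise uniform field by sigma1
  # collects exp(-1/2) (the centre tap of W_d is zero)
  L <- matrix(0.05, 41, 41); L[21, 21] <- 0
  fm2 <- feature_modulation_weights(L, L, wd, sigma1 = 0.05)
  expect_equal(fm2$W_L[21, 21], exp(-1 / 2), tolerance = 1e-9)
  r <- random_field(40, 40, seed = 31)
  fm3 <- feature_modulation_weights(r, r, wd, 0.05)
  expect_true(all(fm3$W_L > 0 & fm3$W_L <= 1 + 1e-12))
  expect_error(feature_modulation_weights(L, L, wd, -1), "positive")
})

test_that("convolution-style weights match a direct nested-loop evaluation", {
  # independent oracle on a 16x16 image: literal double sum over the
  # surround support with mirror-reflected borders
  img <- random_image(16, 16, seed = 7)
  wd <- dog_plus_kernel(1.1, 4)
  ls <- local_statistics(img, raised_cosine_window(11))
  got <- feature_modulation_weights(ls$L, ls$C, wd, 0.05)
  oracle <- function(feat, wd, s1) {
    h <- nrow(feat); w <- ncol(feat)
    rr <- (nrow(wd) - 1) / 2
    reflect <- function(i, n) {
      # mirror with edge repeat, matching symmetric padding
      i <- ((i - 1) %% (2 * n)) + 1
      ifelse(i > n, 2 * n + 1 - i, i)
    }
    out <- matrix(0, h, w)
    for (x in 1:h) for (y in 1:w) {
      acc <- 0
      for (u in -rr:rr) for (v in -rr:rr) {
        k <- wd[u + rr + 1, v + rr + 1]
        if (k == 0) next
        fi <- feat[reflect(x + u, h), reflect(y + v, w)]
        acc <- acc + exp(-(feat[x, y] - fi)^2 / (2 * s1^2)) * k
      }
      out[x, y] <- acc
    }
    out
  }
  expect_equal(got$W_L, oracle(ls$L, wd, 0.05), tolerance = 1e-6)
  expect_equal(got$W_C, oracle(ls$C, wd, 0.05), tolerance = 1e-6)
})

test_that("orientation difference vanishes on uniform texture, obeys Eq form", {
  th <- orientation_set(6)
  flat_stack <- orientation_stack(array(0.3, c(32, 32, 6)), th)
  wd <- dog_plus_kernel(1.1, 4)
  od <- orientation_difference(flat_stack, 1.1, wd, 0.2)
  expect_equal(od$dtheta, matrix(0, 32, 32), tolerance = 1e-10)
  expect_equal(od$W_theta, matrix(1, 32, 32), tolerance = 1e-10)
  # the weight is exactly the Gaussian of the difference, pointwise
  st <- orientation_stack(withr::with_seed(41, array(stats::runif(32 * 32 * 6),
                                                     c(32, 32, 6))), th)
  od2 <- orientation_difference(st, 1.1, wd, 0.2)
  expect_equal(od2$W_theta, exp(-od2$dtheta^2 / (2 * 0.2^2)),
               tolerance = 1e-12)
  # scalar anchor: a difference of exactly sigma2 weighs exp(-1/2)
  expect_equal(exp(-0.2^2 / (2 * 0.2^2)), exp(-0.5))
})

test_that("orientation difference is higher on a texture boundary than inside", {
  ts <- make_textured_square(c(96, 96), side = 48, seed = 3)
  p <- default_params
  sw <- surround_weights(ts$image, p)
  perim <- ts$gt$consensus > 0
  interior <- matrix(FALSE, 96, 96); interior[30:67, 30:67] <- TRUE
  expect_gt(mean(sw$dtheta[perim]), mean(sw$dtheta[interior]))
  # all weight fields live in (0, 1]
  for (f in list(sw$W_L, sw$W_C, sw$W_theta)) {
    expect_true(all(f > 0 & f <= 1 + 1e-12))
  }
})

test_that("all weight fields equal 1 exactly on a globally uniform image", {
  flat <- flat_image(c(0.5, 0.5, 0.5), 40, 40)
  sw <- surround_weights(flat, default_params)
  expect_equal(sw$W_L, matrix(1, 40, 40), tolerance = 1e-9)
  expect_equal(sw$W_C, matrix(1, 40, 40), tolerance = 1e-9)
  expect_equal(sw$W_theta, matrix(1, 40, 40), tolerance = 1e-9)
})
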