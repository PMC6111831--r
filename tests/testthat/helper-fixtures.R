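# Shared helpers for the suite: small deterministic fields and images.

default_params <- model_params()

# A reproducible random field in [0, 1].
random_field <- function(h = 32, w = 32, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(h * w), h, w))
}

# A reproducible random RGB image.
random_image <- function(h = 32, w = 32, seed = 1) {
  withr::with_seed(seed, rgb_image(array(stats::runif(h * w * 3), c(h, w, 3))))
}

# A uniform colour image.
flat_image <- function(col, h = 32, w = 32) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- col[ch]
  rgb_image(px)
}
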