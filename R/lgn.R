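# Retina/LGN stage. The two are merged into one layer (their receptive
# fields are essentially alike): single-opponent, spatially low-pass colour
# channels feeding V1.

#' Single-opponent LGN responses
#'
#' Computes the red-green and blue-yellow opponent signals
#' `U_rg = I_r * G(sigma) + w I_g * G(sigma)` and
#' `U_by = I_b * G(sigma) + w I_y * G(sigma)` with the yellow component
#' `I_y = (I_r + I_g) / 2`, then splits each into a half-wave rectified on/off
#' pair: `rg = max(U_rg, 0)` (r-on/g-off), `gr = max(-U_rg, 0)` (r-off/g-on),
#' and likewise `by` / `yb`. The negative weight `w` makes the channels
#' antagonistic, so achromatic input with `w = -1` cancels exactly.
#'
#' @param img An [rgb_image()].
#' @param params A [model_params()] supplying `w`.
#' @param sigma Gaussian smoothing scale in pixels (CRF size of this layer).
#' @return An [opponent_set()].
#' @export
single_opponent <- function(img, params = model_params(),
                            sigma = params$sigma) {
  validate_params(params)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  g <- gaussian_kernel(sigma)
  br <- convolve2d(channel(img, "r"), g)
  bg <- convolve2d(channel(img, "g"), g)
  bb <- convolve2d(channel(img, "b"), g)
  byel <- (br + bg) / 2
  u_rg <- br + params$w * bg
  u_by <- bb + params$w * byel
  opponent_set(rg = hwr(u_rg), gr = hwr(-u_rg),
               by = hwr(u_by), yb = hwr(-u_by))
}

#' Check on/off complementarity of an opponent set
#'
#' A rectified on/off pair can never be active at the same pixel:
#' `rg * gr = 0` and `by * yb = 0` pointwise.
#'
#' @param set An [opponent_set()].
#' @param tol Numerical tolerance on the products.
#' @return `TRUE` iff both products vanish everywhere.
#' @export
opponent_identity_check <- function(set, tol = 1e-12) {
  max(set$rg * set$gr) <= tol && max(set$by * set$yb) <= tol
}
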