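# Full cascade: LGN -> V1 -> V2 at two scales, surround weights at the fine
# scale, multi-scale guided weight combination, and the final inhibited
# contour map.

# Run LGN -> V1 -> V2 at one scale, keeping every stage for reuse.
hierarchy_stages <- function(img, params, sigma,
                             no_v2 = FALSE, no_feedback = FALSE) {
  v1 <- v1_response(img, params, sigma)
  if (no_v2) {
    d <- Reduce(`+`, v1$D)
    mx <- max(d)
    if (mx > 1e-12) d <- d / mx else d[] <- 0
    return(list(v1 = v1, v2 = NULL, D = d))
  }
  v2 <- v2_pool(v1, params)
  d <- combine_feedforward_feedback(v2, feedback = !no_feedback)
  list(v1 = v1, v2 = v2, D = d)
}

#' Run the LGN -> V1 -> V2 hierarchy at one scale
#'
#' Returns the combined edge response `D` at scale `sigma`, rescaled to
#' `[0, 1]`. Ablations: `no_v2` stops at V1 (channel sum of normalised
#' complex-cell responses); `no_feedback` drops the across-channel feedback
#' maximum from the V2 combination.
#'
#' @param img An [rgb_image()].
#' @param params A [model_params()].
#' @param sigma CRF scale in pixels.
#' @param no_v2,no_feedback Ablation switches.
#' @return Matrix in `[0, 1]`.
#' @export
run_hierarchy <- function(img, params = model_params(),
                          sigma = params$sigma,
                          no_v2 = FALSE, no_feedback = FALSE) {
  hierarchy_stages(img, params, sigma, no_v2, no_feedback)$D
}

#' Multi-scale guided combination of the surround weights
#'
#' Where the coarse-minus-fine edge-energy difference is non-negative the
#' pixel behaves like internal texture (fine-scale detail absent at the
#' coarse scale is untrustworthy) and the strongest suppression weight is
#' taken, `max(W_theta, W_L, W_C)`; where it is negative the pixel behaves
#' like a contour and the weakest, `min(W_theta, W_L, W_C)`, applies. The
#' tie (difference exactly zero) falls to the texture branch.
#'
#' @param w_theta,w_l,w_c Modulation weight matrices.
#' @param delta_d Coarse-minus-fine response difference (`D(2 sigma) -
#'   D(sigma)`, both rescaled to `[0, 1]` beforehand).
#' @return Matrix of combined weights.
#' @export
combine_weights <- function(w_theta, w_l, w_c, delta_d) {
  if (!all(dim(w_theta) == dim(w_l)) || !all(dim(w_l) == dim(w_c)) ||
      !all(dim(w_c) == dim(delta_d)))
    stop("all fields must share a shape", call. = FALSE)
  hi <- pmax(w_theta, w_l, w_c)
  lo <- pmin(w_theta, w_l, w_c)
  ifelse(delta_d >= 0, hi, lo)
}

#' Final surround-inhibited contour response
#'
#' `CD = max(D - alpha * W * (D x W_d), 0)`: the fine-scale edge response
#' minus the weight-modulated, distance-pooled surround energy, half-wave
#' rectified. `alpha` is the texture attenuation factor; `alpha = 0` returns
#' `D` unchanged.
#'
#' @param d_fine Fine-scale response matrix in `[0, 1]`.
#' @param w Combined suppression weight matrix.
#' @param wd_kernel Annular kernel from [dog_plus_kernel()].
#' @param alpha Non-negative texture attenuation factor.
#' @return Non-negative matrix, pointwise `<= d_fine`.
#' @export
final_contour <- function(d_fine, w, wd_kernel, alpha = 1.0) {
  if (alpha < 0) stop("'alpha' must be non-negative", call. = FALSE)
  hwr(d_fine - alpha * w * convolve2d(d_fine, wd_kernel))
}

#' Detect contours in an image
#'
#' The complete detector: runs the LGN -> V1 -> V2 hierarchy at the fine
#' (`sigma`) and coarse (`scale_factor * sigma`) scales, forms the
#' edge-energy difference, computes the surround-modulation weights at the
#' fine scale, combines them under multi-scale guidance, and subtracts the
#' modulated surround inhibition ([final_contour()]).
#'
#' Ablations reproduce the component-wise variants: `no_v2` (stop at V1),
#' `no_feedback` (drop the V2 feedback maximum), `no_multiscale` (always the
#' maximal suppression weight, no two-scale guidance).
#'
#' @param img An [rgb_image()].
#' @param params A [model_params()].
#' @param no_v2,no_feedback,no_multiscale Ablation switches.
#' @param intermediates If `TRUE`, return every stage.
#' @return The contour response matrix (non-negative); with
#'   `intermediates = TRUE`, a list with `CD`, `D_fine`, `D_coarse`,
#'   `delta_d`, `W`, the surround weight maps, and the fine-scale stages.
#' @export
detect <- function(img, params = model_params(),
                   no_v2 = FALSE, no_feedback = FALSE,
                   no_multiscale = FALSE, intermediates = FALSE) {
  validate_params(params)
  fine <- hierarchy_stages(img, params, params$sigma, no_v2, no_feedback)
  coarse <- hierarchy_stages(img, params, params$scale_factor * params$sigma,
                             no_v2, no_feedback)
  delta_d <- coarse$D - fine$D
  theta_stack <- colour_orientation_map(
    lapply(fine$v1$stacks, normalise_stack, eps = params$eps))
  sw <- surround_weights(img, params, theta_stack = theta_stack)
  w <- if (no_multiscale) {
    pmax(sw$W_theta, sw$W_L, sw$W_C)
  } else {
    combine_weights(sw$W_theta, sw$W_L, sw$W_C, delta_d)
  }
  cd <- final_contour(fine$D, w, sw$W_d, params$alpha)
  if (!intermediates) return(cd)
  list(CD = cd, D_fine = fine$D, D_coarse = coarse$D, delta_d = delta_d,
       W = w, surround = sw, fine = fine, coarse = coarse,
       theta_stack = theta_stack)
}
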