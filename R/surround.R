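# Non-classical receptive field (NCRF) surround modulation: suppression
# weights built from distance (annular DOG+), local luminance, local
# contrast, and colour-orientation differences between centre and surround.

# Shift-accumulate engine shared by the feature-similarity weights: for every
# offset (u, v) in the kernel support, accumulate
# fun(field, shifted field) * kernel[u, v], with mirror-padded borders.
surround_accumulate <- function(field, kernel, fun) {
  rr <- (nrow(kernel) - 1) / 2; rc <- (ncol(kernel) - 1) / 2
  h <- nrow(field); w <- ncol(field)
  p <- mirror_pad(field, rr, rc)
  acc <- matrix(0, h, w)
  for (u in -rr:rr) {
    for (v in -rc:rc) {
      kk <- kernel[u + rr + 1, v + rc + 1]
      if (kk == 0) next
      shifted <- p[(1:h) + rr + u, (1:w) + rc + v]
      acc <- acc + fun(field, shifted) * kk
    }
  }
  acc
}

#' Local luminance and luminance contrast
#'
#' With the raised-cosine window `w` (sum `eta`) and greyscale projection
#' `I = 0.299 R + 0.587 G + 0.114 B`:
#' `L = (1/eta) I x w` (local mean luminance) and
#' `C = (1/eta) ((I - L)^2 / L^2) x w` (local normalised contrast), the
#' denominator floored at 1e-4 to guard dark regions. Both maps are then
#' linearly rescaled to `[0, 1]` (a constant map rescales to zero).
#'
#' @param img An [rgb_image()].
#' @param window Window matrix from [raised_cosine_window()].
#' @return List with rescaled `L`, `C` and the raw (pre-rescale) `L_raw`,
#'   `C_raw`.
#' @export
local_statistics <- function(img, window = raised_cosine_window(11)) {
  igrey <- greyscale(img)
  eta <- sum(window)
  l_raw <- convolve2d(igrey, window) / eta
  ratio <- (igrey - l_raw)^2 / pmax(l_raw^2, 1e-4)
  c_raw <- convolve2d(ratio, window) / eta
  list(L = rescale01(l_raw), C = rescale01(c_raw),
       L_raw = l_raw, C_raw = c_raw)
}

#' Luminance and contrast surround-modulation weights
#'
#' The modulation weight of each surround point on the centre decays as a
#' Gaussian of the feature difference, and surround points are distance-
#' weighted by the annular DOG+ kernel:
#' `W_L(x, y) = sum over surround (x_i, y_i) of
#'   exp(-(L(x,y) - L(x_i,y_i))^2 / (2 sigma1^2)) * W_d(x_i - x, y_i - y)`,
#' and the same for `W_C` with the contrast map. Because `W_d` sums to 1,
#' each weight is a convex combination in `(0, 1]`: 1 on feature-uniform
#' surrounds (maximal suppression), smaller where the surround differs from
#' the centre (suppression released on boundaries).
#'
#' @param L,C Rescaled local statistics from [local_statistics()].
#' @param wd_kernel Annular kernel from [dog_plus_kernel()].
#' @param sigma1 Attenuation scale of the feature difference.
#' @return List with matrices `W_L` and `W_C`, each in `(0, 1]`.
#' @export
feature_modulation_weights <- function(L, C, wd_kernel, sigma1 = 0.05) {
  if (sigma1 <= 0) stop("'sigma1' must be positive", call. = FALSE)
  sim <- function(s1) {
    force(s1)
    function(centre, surround) exp(-(centre - surround)^2 / (2 * s1^2))
  }
  list(W_L = surround_accumulate(L, wd_kernel, sim(sigma1)),
       W_C = surround_accumulate(C, wd_kernel, sim(sigma1)))
}

#' Colour-orientation difference and its modulation weight
#'
#' Per orientation, the centre mean is the Gaussian-weighted response
#' `theta_C,i = theta(., theta_i) x G(sigma)` (CRF scale) and the surround
#' mean is the DOG+-weighted response `theta_S,i = theta(., theta_i) x W_d`.
#' The orientation difference is the Euclidean norm of the N-vector of
#' centre-surround differences,
#' `dtheta = sqrt(sum_i (theta_C,i - theta_S,i)^2)`, and the modulation
#' weight is `W_theta = exp(-dtheta^2 / (2 sigma2^2))`: 1 on orientation-
#' uniform texture (maximal suppression), small across texture boundaries.
#'
#' @param theta_stack [orientation_stack()] from [colour_orientation_map()].
#' @param sigma CRF scale for the centre mean.
#' @param wd_kernel Annular kernel from [dog_plus_kernel()].
#' @param sigma2 Attenuation scale of the orientation difference.
#' @return List with matrices `dtheta` (>= 0) and `W_theta` (in `(0, 1]`).
#' @export
orientation_difference <- function(theta_stack, sigma, wd_kernel,
                                   sigma2 = 0.2) {
  if (sigma2 <= 0) stop("'sigma2' must be positive", call. = FALSE)
  g <- gaussian_kernel(sigma)
  n <- dim(theta_stack)[3]
  ss <- matrix(0, dim(theta_stack)[1], dim(theta_stack)[2])
  for (i in seq_len(n)) {
    sl <- theta_stack[, , i]
    ss <- ss + (convolve2d(sl, g) - convolve2d(sl, wd_kernel))^2
  }
  dtheta <- sqrt(ss)
  list(dtheta = dtheta, W_theta = exp(-dtheta^2 / (2 * sigma2^2)))
}

#' All surround-modulation weights for an image
#'
#' Convenience wrapper building `W_d`, the local statistics, `W_L`, `W_C`,
#' and `W_theta` (the latter from a supplied or freshly computed V1 colour
#' orientation map) at one scale.
#'
#' @param img An [rgb_image()].
#' @param params A [model_params()].
#' @param theta_stack Optional precomputed [colour_orientation_map()]; when
#'   `NULL` the V1 stage is run at `params$sigma`.
#' @return List with `W_d` (kernel), `L`, `C`, `W_L`, `W_C`, `dtheta`,
#'   `W_theta`.
#' @export
surround_weights <- function(img, params = model_params(),
                             theta_stack = NULL) {
  validate_params(params)
  wd <- dog_plus_kernel(params$sigma, params$rho_dog,
                        strict = params$strict_paper)
  stats_lc <- local_statistics(img, raised_cosine_window(params$window_size))
  flc <- feature_modulation_weights(stats_lc$L, stats_lc$C, wd,
                                    params$sigma1)
  if (is.null(theta_stack)) {
    v1 <- v1_response(img, params, params$sigma)
    theta_stack <- colour_orientation_map(
      lapply(v1$stacks, normalise_stack, eps = params$eps))
  }
  od <- orientation_difference(theta_stack, params$sigma, wd, params$sigma2)
  list(W_d = wd, L = stats_lc$L, C = stats_lc$C,
       W_L = flc$W_L, W_C = flc$W_C,
       dtheta = od$dtheta, W_theta = od$W_theta)
}
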