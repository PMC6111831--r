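#' Model parameters
#'
#' Builds the single validated record of every constant in the contour
#' detection cascade. Defaults follow the published operating point of the
#' model: `w = -0.8` (retina-to-ganglion connection weight), `sigma = 1.1` px
#' (classical receptive field scale), `k = 2` (V1/LGN receptive-field size
#' ratio), `lambda = 0.5` (V1 receptive-field aspect ratio), `n_orient = 6`
#' orientations, an 11x11 raised-cosine window for local statistics,
#' `sigma1 = 0.05` (luminance/contrast attenuation scale), `sigma2 = 0.2`
#' (colour-orientation attenuation scale), and texture attenuation factor
#' `alpha = 1`.
#'
#' @param w Retina-to-ganglion input weight, in `[-1, 0]`.
#' @param sigma Classical receptive field (CRF) scale in pixels.
#' @param k Ratio of V1 to LGN receptive field size.
#' @param lambda Aspect (length-to-width) ratio of the V1 simple-cell field.
#' @param n_orient Number of preferred orientations in the V1 bank.
#' @param rho_dog Ratio of NCRF to CRF diameter for the annular DOG+ surround.
#'   Must exceed 1 so the rectified difference of Gaussians is an annulus.
#' @param window_size Odd side length of the local-statistics window, pixels.
#' @param sigma1 Attenuation scale of the luminance/contrast modulation weights.
#' @param sigma2 Attenuation scale of the colour-orientation modulation weight.
#' @param alpha Texture attenuation factor multiplying the surround inhibition
#'   term; `alpha = 0` disables inhibition.
#' @param eps Normalisation floor guarding division in textureless regions.
#' @param sigma_prime Minor-to-major scale of the V2 elliptical pooling kernel;
#'   defaults to `2 * sigma` (2:1 elongation along the contour tangent).
#' @param scale_factor Coarse/fine scale ratio of the two-scale comparison.
#' @param eval_tol_frac Boundary-matching tolerance for precision/recall,
#'   as a fraction of the image diagonal.
#' @param strict_paper Logical; if `TRUE`, degenerate published constants are
#'   used verbatim (`rho_dog = 0.4`, product-form elliptical cross term) for
#'   demonstration of their behaviour. Not intended for detection.
#'
#' @return An object of class `"model_params"` (a validated named list).
#' @export
#' @examples
#' p <- model_params()
#' p$sigma
model_params <- function(w = -0.8, sigma = 1.1, k = 2, lambda = 0.5,
                         n_orient = 6, rho_dog = 4, window_size = 11,
                         sigma1 = 0.05, sigma2 = 0.2, alpha = 1.0,
                         eps = 1e-8, sigma_prime = NULL, scale_factor = 2,
                         eval_tol_frac = 0.0075, strict_paper = FALSE) {
  if (is.null(sigma_prime)) sigma_prime <- 2 * sigma
  p <- list(w = w, sigma = sigma, k = k, lambda = lambda,
            n_orient = n_orient, rho_dog = rho_dog,
            window_size = window_size, sigma1 = sigma1, sigma2 = sigma2,
            alpha = alpha, eps = eps, sigma_prime = sigma_prime,
            scale_factor = scale_factor, eval_tol_frac = eval_tol_frac,
            strict_paper = isTRUE(strict_paper))
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (!is.numeric(p$w) || p$w < -1 || p$w > 0)
    stop("'w' must lie in [-1, 0]", call. = FALSE)
  if (p$sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (p$k <= 0) stop("'k' must be positive", call. = FALSE)
  if (p$lambda <= 0) stop("'lambda' must be positive", call. = FALSE)
  if (p$n_orient < 2) stop("'n_orient' must be >= 2", call. = FALSE)
  if (!p$strict_paper && p$rho_dog <= 1)
    stop("'rho_dog' must exceed 1 (annular surround)", call. = FALSE)
  if (p$window_size %% 2 != 1)
    stop("'window_size' must be odd", call. = FALSE)
  if (p$sigma1 <= 0 || p$sigma2 <= 0)
    stop("'sigma1' and 'sigma2' must be positive", call. = FALSE)
  if (p$alpha < 0) stop("'alpha' must be non-negative", call. = FALSE)
  if (p$eps <= 0) stop("'eps' must be positive", call. = FALSE)
  if (p$sigma_prime <= 0) stop("'sigma_prime' must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Contour model parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-13s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Load model parameters from a YAML config file
#'
#' The file holds a flat mapping whose keys mirror [model_params()] arguments;
#' missing keys keep their defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file (e.g. from CLI flags).
#' @return A `"model_params"` object.
#' @export
load_params <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(model_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(list(...))] <- list(...)
  do.call(model_params, cfg)
}

#' Write model parameters to a YAML config file
#'
#' @param params A `"model_params"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  validate_params(params)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
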