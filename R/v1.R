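# V1 stage: double-opponent simple cells (oriented derivative-of-Gaussian
# filter bank over the opponent channels), complex cells (MAX pooling over
# orientation), and squared self-normalisation.

#' Double-opponent simple-cell orientation stacks
#'
#' For each channel the two sub-fields of the double-opponent receptive field
#' receive the LGN outputs of opposite polarity: for the rg channel,
#' `E_rg(theta) = hwr(S_rg+ x V) + hwr(S_rg- x (-V))` where `V` is the signed
#' oriented derivative kernel and `hwr` the half-wave rectification that
#' keeps cell responses non-negative. `S_rg-` is the gr field (and vice
#' versa); the by/yb pair is wired likewise. Because `V` sums to zero, a
#' spatially uniform opponent input produces exactly zero response at every
#' orientation (no structure, no response - the "white wall" that the
#' downstream normalisation floor guards).
#'
#' @param opp An [opponent_set()].
#' @param sigma CRF scale in pixels.
#' @param params A [model_params()]; `n_orient` sets the bank size.
#' @param n_orient Override for the number of orientations (used by the
#'   36-orientation tuning probe).
#' @return Named list of four [orientation_stack()]s (`rg`, `gr`, `by`, `yb`).
#' @export
double_opponent_stack <- function(opp, sigma = params$sigma,
                                  params = model_params(),
                                  n_orient = params$n_orient) {
  validate_params(params)
  stopifnot(inherits(opp, "opponent_set"))
  thetas <- orientation_set(n_orient)
  h <- nrow(opp$rg); w <- ncol(opp$rg)
  pairs <- list(rg = c("rg", "gr"), gr = c("gr", "rg"),
                by = c("by", "yb"), yb = c("yb", "by"))
  out <- lapply(pairs, function(p) array(0, c(h, w, n_orient)))
  for (i in seq_len(n_orient)) {
    v <- v1_simple_kernel(thetas[i], sigma, params)
    resp <- lapply(opp, convolve2d, kernel = v)
    for (ch in names(pairs)) {
      out[[ch]][, , i] <- hwr(resp[[pairs[[ch]][1]]]) +
        hwr(-resp[[pairs[[ch]][2]]])
    }
  }
  lapply(out, orientation_stack, orientations = thetas)
}

#' MAX pooling over orientations (complex cells)
#'
#' @param stack An [orientation_stack()].
#' @return Matrix of the pointwise maximum over orientation slices.
#' @export
max_pool <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3 || dim(stack)[3] < 1)
    stop("'stack' must be a non-empty H x W x N array", call. = FALSE)
  apply(stack, c(1, 2), max)
}

#' Squared self-normalisation of a response field
#'
#' `D = E^2 / (max(E^2) + eps)` with the maximum taken globally over the
#' field. The squaring sharpens strong edges against texture; the global
#' maximum makes the output scale-invariant and bounded in `[0, 1)`; `eps`
#' guards the all-zero ("white wall") case where no structure exists.
#'
#' @param field Non-negative numeric matrix.
#' @param eps Small positive floor.
#' @return Matrix in `[0, 1)`.
#' @export
normalise_response <- function(field, eps = 1e-8) {
  if (min(field) < 0)
    stop("'field' must be non-negative (post-rectification)", call. = FALSE)
  if (eps <= 0) stop("'eps' must be positive", call. = FALSE)
  sq <- field^2
  sq / (max(sq) + eps)
}

#' Unit-scale normalisation of an orientation stack
#'
#' Divides the whole stack by its global maximum (plus `eps`), putting the
#' orientation responses on a `[0, 1)` scale regardless of image contrast.
#' The linear form (no squaring) preserves the relative strength of moderate
#' responses, which the colour-orientation surround comparison relies on:
#' the attenuation scale `sigma2 = 0.2` downstream presupposes orientation
#' responses of this unit magnitude.
#'
#' @param stack An [orientation_stack()].
#' @param eps Small positive floor (white-wall guard).
#' @return An [orientation_stack()] with values in `[0, 1)`.
#' @export
normalise_stack <- function(stack, eps = 1e-8) {
  if (eps <= 0) stop("'eps' must be positive", call. = FALSE)
  orientation_stack(array(stack / (max(stack) + eps), dim(stack)),
                    orientations = orientations_of(stack))
}

#' Colour-orientation map
#'
#' Per orientation, takes the pointwise maximum of the complex-cell stacks
#' across the four opponent channels: the response of the locally dominant
#' colour orientation. For surround modulation the stacks should be
#' normalised first ([normalise_stack()]) so the orientation-difference
#' scale matches `sigma2`.
#'
#' @param stacks Named list of four [orientation_stack()]s
#'   (`rg`, `gr`, `by`, `yb`) sharing shape and orientations.
#' @return An [orientation_stack()].
#' @export
colour_orientation_map <- function(stacks) {
  need <- c("rg", "gr", "by", "yb")
  if (!all(need %in% names(stacks)))
    stop("stacks must contain channels rg, gr, by, yb", call. = FALSE)
  dims <- lapply(stacks[need], dim)
  if (length(unique(dims)) != 1)
    stop("channel stacks must share a shape", call. = FALSE)
  out <- pmax(stacks$rg, stacks$gr, stacks$by, stacks$yb)
  orientation_stack(array(out, dim(stacks$rg)),
                    orientations = orientations_of(stacks$rg))
}

#' Full V1 response at one scale
#'
#' Runs the LGN opponent stage (if given an image), the oriented
#' double-opponent bank, MAX pooling, and self-normalisation, returning all
#' intermediates needed downstream.
#'
#' @param x An [rgb_image()] or an [opponent_set()].
#' @param params A [model_params()].
#' @param sigma CRF scale in pixels.
#' @return An object of class `"v1_response"`: list with `stacks` (per-channel
#'   pre-normalisation orientation stacks), `E` (per-channel MAX-pooled
#'   fields), `D` (per-channel normalised fields, each in `[0, 1)`), `sigma`.
#' @export
v1_response <- function(x, params = model_params(), sigma = params$sigma) {
  opp <- if (inherits(x, "opponent_set")) x else
    single_opponent(x, params, sigma)
  stacks <- double_opponent_stack(opp, sigma, params)
  e <- lapply(stacks, max_pool)
  d <- lapply(e, normalise_response, eps = params$eps)
  structure(list(stacks = stacks, E = e, D = d, sigma = sigma),
            class = "v1_response")
}

#' Orientation tuning profile at one pixel
#'
#' Probes the V1 model with a dense orientation bank (default 36 preferred
#' directions) and reports the normalised response at a single pixel per
#' direction - the polar tuning curve of the model cell at that location.
#' The response per direction is the across-channel maximum (colour
#' orientation map), square-normalised by its global maximum.
#'
#' @param img An [rgb_image()].
#' @param pixel `c(row, col)`, 1-based, inside the image.
#' @param n_probe Number of probe orientations.
#' @param params A [model_params()].
#' @return Data frame with columns `theta` (radians) and `response`
#'   (in `[0, 1)`).
#' @export
tuning_profile <- function(img, pixel, n_probe = 36,
                           params = model_params()) {
  r <- pixel[1]; cl <- pixel[2]
  if (r < 1 || r > img$height || cl < 1 || cl > img$width)
    stop("'pixel' out of bounds", call. = FALSE)
  opp <- single_opponent(img, params)
  stacks <- double_opponent_stack(opp, params$sigma, params,
                                  n_orient = n_probe)
  th <- colour_orientation_map(stacks)
  sq <- th^2
  prof <- sq[r, cl, ] / (max(sq) + params$eps)
  data.frame(theta = orientations_of(th), response = as.numeric(prof))
}
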