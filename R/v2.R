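# V2 stage: elongated elliptical pooling of V1 responses along the local
# contour tangent, plus a single feedforward+feedback combination across the
# four opponent channels.

#' V2 elliptical pooling of V1 responses
#'
#' Each channel's normalised V1 field is pooled with an elliptical Gaussian
#' whose long axis follows the local edge tangent. Per pixel, the dominant
#' filter orientation (argmax of the channel's pre-normalisation stack) gives
#' the edge normal; pixels are quantised into the N orientation classes and
#' the channel is convolved once per class with the matching kernel, the
#' results recombined through the class masks. Because the elliptical
#' kernel's long (`sigma_prime`) axis is perpendicular to its `theta`
#' argument, passing the filter normal directly aligns pooling with the
#' contour, integrating collinear evidence.
#'
#' @param v1 A `"v1_response"` (see [v1_response()]).
#' @param params A [model_params()] supplying `sigma_prime`.
#' @return Named list of four non-negative matrices (`rg`, `gr`, `by`, `yb`).
#' @export
v2_pool <- function(v1, params = model_params()) {
  stopifnot(inherits(v1, "v1_response"))
  validate_params(params)
  thetas <- orientations_of(v1$stacks$rg)
  n <- length(thetas)
  kernels <- lapply(thetas, elliptical_kernel, sigma = v1$sigma,
                    sigma_prime = params$sigma_prime,
                    strict = params$strict_paper)
  out <- list()
  for (ch in names(v1$D)) {
    m <- argmax_orientation(v1$stacks[[ch]])
    acc <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(n)) {
      mask <- m == i
      if (!any(mask)) next
      acc <- acc + mask * convolve2d(v1$D[[ch]], kernels[[i]])
    }
    out[[ch]] <- hwr(acc)
  }
  out
}

#' Combine feedforward and feedback V2 information
#'
#' `D = sum over channels of V2_channel + max over channels of V2_channel`:
#' the channel sum is the feedforward edge evidence; the across-channel
#' pointwise maximum models the one-shot global-shape feedback from V2 to V1,
#' reinforcing whichever channel carries the contour. The result is rescaled
#' to `[0, 1]` by its global maximum so responses at different scales are
#' comparable.
#'
#' @param v2 Named list of four matrices (`rg`, `gr`, `by`, `yb`).
#' @param feedback If `FALSE`, drop the feedback maximum (ablation).
#' @param rescale If `FALSE`, return the raw combination.
#' @return A non-negative matrix (in `[0, 1]` when rescaled).
#' @export
combine_feedforward_feedback <- function(v2, feedback = TRUE,
                                         rescale = TRUE) {
  need <- c("rg", "gr", "by", "yb")
  if (!all(need %in% names(v2)))
    stop("v2 must contain channels rg, gr, by, yb", call. = FALSE)
  ff <- Reduce(`+`, v2[need])
  d <- if (feedback) ff + pmax(v2$rg, v2$gr, v2$by, v2$yb) else ff
  if (rescale) {
    mx <- max(d)
    # below the noise floor there is no structure to rescale (white wall)
    if (mx > 1e-12) d <- d / mx
  }
  d
}
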