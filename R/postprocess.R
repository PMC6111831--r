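# Contour refinement: orientation-guided non-maxima suppression and
# Canny-style hysteresis binarisation.

# Quantise an edge-normal angle (radians) to one of the four 8-connected
# axes and return the (dx, dy) step. dy is a row offset (downward).
normal_step <- function(theta) {
  a <- round((theta %% pi) / (pi / 4)) %% 4
  list(dx = c(1, 1, 0, -1)[a + 1], dy = c(0, 1, 1, 1)[a + 1])
}

#' Non-maxima suppression along the edge normal
#'
#' A pixel survives iff its value is `>=` both neighbours along the local
#' edge-normal direction (the per-pixel argmax orientation of `stack`,
#' quantised to 8-connectivity); suppressed pixels are set to zero. Values
#' outside the image count as zero, and ties survive (plateaus are left to
#' hysteresis).
#'
#' @param cd Non-negative response matrix.
#' @param stack [orientation_stack()] giving per-pixel dominant orientation
#'   (the filter normal).
#' @return Matrix of the same shape, zero at suppressed pixels.
#' @export
non_maxima_suppress <- function(cd, stack) {
  if (!all(dim(cd) == dim(stack)[1:2]))
    stop("'cd' and 'stack' must share a shape", call. = FALSE)
  thetas <- orientations_of(stack)
  m <- argmax_orientation(stack)
  h <- nrow(cd); w <- ncol(cd)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- cd
  keep <- matrix(FALSE, h, w)
  for (i in seq_along(thetas)) {
    sel <- m == i
    if (!any(sel)) next
    st <- normal_step(thetas[i])
    fwd <- p[(2:(h + 1)) + st$dy, (2:(w + 1)) + st$dx]
    bck <- p[(2:(h + 1)) - st$dy, (2:(w + 1)) - st$dx]
    keep <- keep | (sel & cd >= fwd & cd >= bck)
  }
  cd * keep
}

# Orientation-free ridge NMS used when no stack is available (e.g. when
# sweeping thresholds over an arbitrary response map): a pixel survives if
# it is >= both neighbours along the rows or along the columns.
nms_ridge <- function(cd) {
  h <- nrow(cd); w <- ncol(cd)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- cd
  ctr_r <- 2:(h + 1); ctr_c <- 2:(w + 1)
  horiz <- cd >= p[ctr_r, ctr_c - 1] & cd >= p[ctr_r, ctr_c + 1]
  vert <- cd >= p[ctr_r - 1, ctr_c] & cd >= p[ctr_r + 1, ctr_c]
  cd * (horiz | vert)
}

#' Hysteresis binarisation of a thinned response
#'
#' The high threshold is the `(1 - p)`-quantile of the positive response
#' values (so `p` is the candidate edge-pixel fraction); the low threshold is
#' `low_ratio` times the high one. Pixels at or above the high threshold seed
#' an 8-connected flood fill through pixels at or above the low threshold.
#'
#' @param thinned Non-negative response matrix (typically NMS output).
#' @param p Candidate edge-pixel fraction, in `(0, 1)`.
#' @param low_ratio Low/high threshold ratio.
#' @return Binary `{0, 1}` matrix.
#' @export
hysteresis_binarise <- function(thinned, p = 0.1, low_ratio = 0.4) {
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)", call. = FALSE)
  if (min(thinned) < 0)
    stop("'thinned' must be non-negative", call. = FALSE)
  pos <- thinned[thinned > 0]
  if (!length(pos)) return(matrix(0, nrow(thinned), ncol(thinned)))
  hi <- stats::quantile(pos, 1 - p, names = FALSE)
  lo <- low_ratio * hi
  strong <- thinned >= hi
  weak <- thinned >= lo & thinned > 0
  grown <- strong
  h <- nrow(thinned); w <- ncol(thinned)
  repeat {
    p2 <- matrix(FALSE, h + 2, w + 2)
    p2[2:(h + 1), 2:(w + 1)] <- grown
    dil <- matrix(FALSE, h, w)
    for (dy in -1:1) for (dx in -1:1) {
      dil <- dil | p2[(2:(h + 1)) + dy, (2:(w + 1)) + dx]
    }
    nxt <- dil & weak
    if (identical(nxt, grown)) break
    grown <- nxt
  }
  grown * 1
}
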