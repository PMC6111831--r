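#' RGB image container
#'
#' Wraps an `H x W x 3` numeric array of values in `[0, 1]`. Images must be at
#' least 16 pixels on a side so every filter in the cascade fits.
#'
#' @param pixels `H x W x 3` numeric array in `[0, 1]`, or an `H x W` matrix
#'   (replicated to three identical channels).
#' @return An object of class `"rgb_image"`.
#' @export
rgb_image <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("'pixels' must be an H x W x 3 array", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("image values must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image values must lie in [0, 1]", call. = FALSE)
  if (dim(pixels)[1] < 16 || dim(pixels)[2] < 16)
    stop("image must be at least 16 x 16", call. = FALSE)
  structure(list(pixels = pixels,
                 height = dim(pixels)[1], width = dim(pixels)[2]),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, range [%.3f, %.3f]>\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Channel accessor; ch in {"r","g","b"}.
channel <- function(img, ch) {
  img$pixels[, , match(ch, c("r", "g", "b"))]
}

#' Greyscale projection of an RGB image
#'
#' The ITU luma weighting `0.299 R + 0.587 G + 0.114 B`, the definition of
#' luminance used throughout the local-statistics stage and the isoluminant
#' stimulus construction.
#'
#' @param img An [rgb_image()].
#' @return An `H x W` numeric matrix.
#' @export
greyscale <- function(img) {
  0.299 * channel(img, "r") + 0.587 * channel(img, "g") +
    0.114 * channel(img, "b")
}

#' Orientation stack
#'
#' An `H x W x N` non-negative response tensor together with its orientation
#' list `theta_i = (i - 1) * 2 * pi / N`, evenly spaced over `[0, 2*pi)`.
#'
#' @param values `H x W x N` numeric array, `N >= 2`.
#' @param orientations Numeric vector of the N orientations in radians.
#' @return An object of class `"orientation_stack"` (the array, with an
#'   `orientations` attribute).
#' @export
orientation_stack <- function(values, orientations) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("'values' must be an H x W x N array", call. = FALSE)
  n <- dim(values)[3]
  if (n < 2 || length(orientations) != n)
    stop("need N >= 2 orientations matching the stack depth", call. = FALSE)
  if (any(diff(orientations) <= 0) || orientations[1] < 0 ||
      orientations[n] >= 2 * pi ||
      max(abs(diff(orientations) - 2 * pi / n)) > 1e-9)
    stop("orientations must be evenly spaced over [0, 2*pi)", call. = FALSE)
  if (min(values) < 0)
    stop("stack values must be non-negative (post-rectification)",
         call. = FALSE)
  structure(values, orientations = orientations, class = "orientation_stack")
}

orientations_of <- function(stack) attr(stack, "orientations")

# Evenly spaced orientations over the full circle.
orientation_set <- function(n) (seq_len(n) - 1) * 2 * pi / n

# Per-pixel index of the maximal orientation slice (ties -> lowest index).
argmax_orientation <- function(stack) {
  n <- dim(stack)[3]
  idx <- matrix(1L, dim(stack)[1], dim(stack)[2])
  best <- stack[, , 1]
  for (i in seq_len(n)[-1]) {
    sl <- stack[, , i]
    upd <- sl > best
    idx[upd] <- i
    best[upd] <- sl[upd]
  }
  idx
}

#' Opponent channel set
#'
#' The four half-wave rectified single-opponent response fields:
#' `rg` (r-on/g-off), `gr` (r-off/g-on), `by` (b-on/y-off), `yb` (b-off/y-on).
#'
#' @param rg,gr,by,yb Non-negative numeric matrices of a common shape.
#' @return An object of class `"opponent_set"` (a named list).
#' @export
opponent_set <- function(rg, gr, by, yb) {
  chans <- list(rg = rg, gr = gr, by = by, yb = yb)
  dims <- lapply(chans, dim)
  if (length(unique(dims)) != 1)
    stop("all four channels must share a shape", call. = FALSE)
  if (any(vapply(chans, min, 0) < 0))
    stop("opponent channels must be non-negative", call. = FALSE)
  structure(chans, class = "opponent_set")
}

#' Boundary ground truth
#'
#' One or more binary annotator masks plus their consensus (pixelwise mean).
#'
#' @param maps A list of `H x W` matrices strictly in `{0, 1}`, or a single
#'   such matrix.
#' @return An object of class `"boundary_gt"` with elements `maps` and
#'   `consensus`.
#' @export
boundary_gt <- function(maps) {
  if (is.matrix(maps)) maps <- list(maps)
  if (!length(maps)) stop("need at least one annotator mask", call. = FALSE)
  for (m in maps) {
    if (!is.matrix(m) || !all(m %in% c(0, 1)))
      stop("every mask must be a strict {0,1} matrix", call. = FALSE)
  }
  if (length(unique(lapply(maps, dim))) != 1)
    stop("all masks must share a shape", call. = FALSE)
  consensus <- Reduce(`+`, maps) / length(maps)
  structure(list(maps = maps, consensus = consensus), class = "boundary_gt")
}
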