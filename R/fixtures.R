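# Synthetic stimuli with exact boundary ground truth. Every generator is a
# pure function of its arguments (seed included), so fixtures are rebuilt
# identically at test time instead of being stored.

#' Achromatic sinusoidal grating
#'
#' Bars run along `orientation`; luminance varies along the perpendicular.
#' A grating is pure (oriented) texture, so its ground truth is empty.
#'
#' @param size `c(H, W)` in pixels.
#' @param orientation Bar direction in radians, `[0, pi)`.
#' @param frequency Cycles per pixel, in `(0, 0.5)` (Nyquist).
#' @param contrast Michelson contrast in `[0, 1]` about mid-grey.
#' @param phase Phase offset in radians.
#' @param seed Unused (the grating is fully parametric); kept so all
#'   generators share a calling convention.
#' @return `list(image = rgb_image, gt = boundary_gt)`.
#' @export
make_grating <- function(size = c(64, 64), orientation = 0, frequency = 0.1,
                         contrast = 0.8, phase = 0, seed = 1) {
  if (frequency <= 0 || frequency >= 0.5)
    stop("'frequency' must lie in (0, 0.5) cycles/pixel", call. = FALSE)
  if (orientation < 0 || orientation >= pi)
    stop("'orientation' must lie in [0, pi)", call. = FALSE)
  if (contrast < 0 || contrast > 1)
    stop("'contrast' must lie in [0, 1]", call. = FALSE)
  h <- size[1]; w <- size[2]
  x <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  y <- matrix(seq_len(h) - 1, h, w)
  u <- -x * sin(orientation) + y * cos(orientation)  # perpendicular coord
  lum <- 0.5 + 0.5 * contrast * sin(2 * pi * frequency * u + phase)
  list(image = rgb_image(lum),
       gt = boundary_gt(matrix(0, h, w)))
}

# Accumulate an anti-aliased bar (line segment) into a weight canvas by
# bilinear splatting of densely sampled points along the segment.
splat_bar <- function(acc, x0, y0, theta, len) {
  h <- nrow(acc); w <- ncol(acc)
  ts <- seq(-len / 2, len / 2, by = 0.25)
  px <- x0 + ts * cos(theta)
  py <- y0 + ts * sin(theta)
  fx <- floor(px); fy <- floor(py)
  wx <- px - fx; wy <- py - fy
  for (corner in 1:4) {
    cx <- fx + (corner == 2 | corner == 4)
    cy <- fy + (corner >= 3)
    wt <- (1 - abs(px - cx)) * (1 - abs(py - cy))
    ok <- cx >= 1 & cx <= w & cy >= 1 & cy <= h
    if (any(ok)) {
      ij <- cbind(cy[ok], cx[ok])
      acc[ij] <- pmax(acc[ij], wt[ok])
    }
  }
  acc
}

# Oriented-bar texture: bright anti-aliased bars on a canvas, with per-bar
# orientation chosen by a region labelling of the bar centre.
bar_texture <- function(h, w, region, theta_by_region, density, bar_len) {
  n_bars <- max(1L, round(density * h * w / bar_len))
  acc <- matrix(0, h, w)
  cx <- stats::runif(n_bars, 1, w)
  cy <- stats::runif(n_bars, 1, h)
  for (b in seq_len(n_bars)) {
    reg <- region[max(1, min(h, round(cy[b]))), max(1, min(w, round(cx[b])))]
    acc <- splat_bar(acc, cx[b], cy[b], theta_by_region[reg], bar_len)
  }
  pmin(acc, 1)
}

#' Textured square: an orientation-defined region boundary
#'
#' Oriented-bar texture at angle `theta_in` inside a centred square and
#' `theta_out` outside, on a mid-grey background. Bar density and length are
#' equal in both regions, so the boundary is carried by orientation alone.
#' Ground truth is the square's 1-pixel perimeter.
#'
#' @param size `c(H, W)`.
#' @param side Side of the centred square; needs an 8-pixel margin.
#' @param theta_in,theta_out Bar orientations (radians); must differ mod pi.
#' @param density Expected bar-pixel fraction (bars per pixel x length).
#' @param bar_len Bar length in pixels.
#' @param bar_amp Bar brightness increment above the 0.5 background.
#' @param seed RNG seed; same seed, same stimulus.
#' @return `list(image = rgb_image, gt = boundary_gt)`.
#' @export
make_textured_square <- function(size = c(96, 96), side = 48,
                                 theta_in = pi / 2, theta_out = 0,
                                 density = 0.08, bar_len = 7,
                                 bar_amp = 0.45, seed = 1) {
  h <- size[1]; w <- size[2]
  if (abs((theta_in - theta_out) %% pi) < 1e-12)
    stop("'theta_in' and 'theta_out' must differ (mod pi): no boundary exists",
         call. = FALSE)
  r0 <- floor((h - side) / 2) + 1; r1 <- r0 + side - 1
  c0 <- floor((w - side) / 2) + 1; c1 <- c0 + side - 1
  if (r0 < 9 || c0 < 9 || r1 > h - 8 || c1 > w - 8)
    stop("square must fit with an 8-pixel margin", call. = FALSE)
  region <- matrix(1L, h, w)
  region[r0:r1, c0:c1] <- 2L
  tex <- withr::with_seed(seed,
    bar_texture(h, w, region, c(theta_out, theta_in), density, bar_len))
  lum <- pmin(0.5 + bar_amp * tex, 1)
  gt <- matrix(0, h, w)
  gt[r0:r1, c(c0, c1)] <- 1
  gt[c(r0, r1), c0:c1] <- 1
  list(image = rgb_image(lum), gt = boundary_gt(gt))
}

# Luminance of an RGB triple under the ITU greyscale weights.
luma <- function(col) sum(c(0.299, 0.587, 0.114) * col)

#' Isoluminant colour edge
#'
#' Left/right halves filled with two colours rescaled to a common luminance
#' (the lower of the two), so the boundary is purely chromatic: the greyscale
#' projection is flat to within 1e-6. Ground truth is the vertical midline.
#'
#' @param size `c(H, W)`.
#' @param col_left,col_right RGB triples in `[0, 1]`.
#' @param seed Unused; kept for the shared generator convention.
#' @return `list(image = rgb_image, gt = boundary_gt)`.
#' @export
make_isoluminant_edge <- function(size = c(64, 64),
                                  col_left = c(1, 0, 0),
                                  col_right = c(0, 1, 0), seed = 1) {
  yl <- luma(col_left); yr <- luma(col_right)
  if (yl <= 0 || yr <= 0)
    stop("colour luminances cannot be matched inside the gamut", call. = FALSE)
  y <- min(yl, yr)
  cl <- col_left * (y / yl); cr <- col_right * (y / yr)
  if (max(cl, cr) > 1 + 1e-12)
    stop("colour luminances cannot be matched inside the gamut", call. = FALSE)
  h <- size[1]; w <- size[2]
  mid <- ceiling(w / 2)
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    px[, seq_len(mid), ch] <- cl[ch]
    px[, seq(mid + 1, w), ch] <- cr[ch]
  }
  gt <- matrix(0, h, w); gt[, mid] <- 1
  list(image = rgb_image(px), gt = boundary_gt(gt))
}

#' Two-tone luminance edge
#'
#' Left/right halves at two grey levels (or colours); ground truth is the
#' vertical midline. The luminance-driven counterpart of
#' [make_isoluminant_edge()].
#'
#' @param size `c(H, W)`.
#' @param col_left,col_right RGB triples in `[0, 1]`.
#' @param seed Unused; kept for the shared generator convention.
#' @return `list(image = rgb_image, gt = boundary_gt)`.
#' @export
make_two_tone_edge <- function(size = c(64, 64),
                               col_left = c(0.25, 0.25, 0.25),
                               col_right = c(0.75, 0.75, 0.75), seed = 1) {
  h <- size[1]; w <- size[2]
  mid <- ceiling(w / 2)
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    px[, seq_len(mid), ch] <- col_left[ch]
    px[, seq(mid + 1, w), ch] <- col_right[ch]
  }
  gt <- matrix(0, h, w); gt[, mid] <- 1
  list(image = rgb_image(px), gt = boundary_gt(gt))
}

#' Cluttered scene: salient region boundaries embedded in texture
#'
#' Emulates the structure of a natural scene at desk scale: 2-4 rectangular
#' "objects" whose base tone differs from the mid-grey background (so their
#' perimeters are salient first-order contours), each filled with disorderly
#' internal bar texture (random per-bar orientations - the clutter the
#' surround inhibition should suppress), a sparsely textured background, and
#' one isoluminant red/green patch contributing a purely chromatic boundary.
#' Ground truth is the union of the region perimeters (the texture bars,
#' being surface detail, are not boundaries).
#'
#' @param size `c(H, W)`.
#' @param n_shapes Number of toned, textured rectangles (2-4).
#' @param density,bar_len Interior texture parameters as in
#'   [make_textured_square()]; the background uses half this density.
#' @param seed RNG seed.
#' @return `list(image = rgb_image, gt = boundary_gt)`.
#' @export
make_cluttered_scene <- function(size = c(128, 128), n_shapes = 3,
                                 density = 0.08, bar_len = 7, seed = 1) {
  if (n_shapes < 2 || n_shapes > 4)
    stop("'n_shapes' must be 2-4", call. = FALSE)
  h <- size[1]; w <- size[2]
  withr::with_seed(seed, {
    region <- matrix(1L, h, w)   # 1 = background
    gt <- matrix(0, h, w)
    tones <- c(0.5, rep(0, n_shapes))
    boxes <- list()
    for (s in seq_len(n_shapes)) {
      # rejection-sample a box that does not touch the earlier ones
      for (try in 1:100) {
        sh <- sample(seq(24, min(40, h - 20)), 1)
        sw <- sample(seq(24, min(40, w - 20)), 1)
        r0 <- sample(seq(9, h - 8 - sh), 1)
        c0 <- sample(seq(9, w - 8 - sw), 1)
        r1 <- r0 + sh - 1; c1 <- c0 + sw - 1
        clear <- all(region[max(1, r0 - 4):min(h, r1 + 4),
                            max(1, c0 - 4):min(w, c1 + 4)] == 1L)
        if (clear) break
      }
      region[r0:r1, c0:c1] <- s + 1L
      boxes[[s]] <- c(r0, r1, c0, c1)
      gt[r0:r1, c(c0, c1)] <- 1
      gt[c(r0, r1), c0:c1] <- 1
      # object tone alternates dark/bright around the 0.5 background
      tones[s + 1] <- if (s %% 2 == 1) 0.3 else 0.7
    }
    lum <- tones[region]
    dim(lum) <- c(h, w)
    # disorderly texture: every bar gets its own random orientation;
    # background texture is sparser than object interiors
    n_in <- max(1L, round(density * h * w / bar_len))
    acc <- matrix(0, h, w)
    cx <- stats::runif(n_in, 1, w); cy <- stats::runif(n_in, 1, h)
    keep <- region[cbind(pmax(1, pmin(h, round(cy))),
                         pmax(1, pmin(w, round(cx))))] > 1L |
      stats::runif(n_in) < 0.5
    ang <- stats::runif(n_in, 0, pi)
    for (b in which(keep)) acc <- splat_bar(acc, cx[b], cy[b], ang[b], bar_len)
    tex <- pmin(acc, 1)
    # bars contrast with their region, but stay weaker than the region
    # boundaries themselves: the contours are the salient structure
    sign_tex <- ifelse(lum > 0.5, -1, 1)
    lum <- pmin(pmax(lum + sign_tex * 0.15 * tex, 0), 1)
    px <- array(rep(lum, 3), c(h, w, 3))
    # isoluminant patch: red/green halves at the background luminance
    ph <- 20; pw <- 20
    for (try in 1:100) {
      pr0 <- sample(seq(9, h - 8 - ph), 1); pc0 <- sample(seq(9, w - 8 - pw), 1)
      pr1 <- pr0 + ph - 1; pc1 <- pc0 + pw - 1
      if (all(region[max(1, pr0 - 4):min(h, pr1 + 4),
                     max(1, pc0 - 4):min(w, pc1 + 4)] == 1L)) break
    }
    y0 <- min(luma(c(1, 0, 0)), luma(c(0, 1, 0)))  # gamut-feasible match
    red <- c(1, 0, 0) * (y0 / luma(c(1, 0, 0)))
    grn <- c(0, 1, 0) * (y0 / luma(c(0, 1, 0)))
    midc <- pc0 + pw %/% 2 - 1
    for (ch in 1:3) {
      px[pr0:pr1, pc0:midc, ch] <- red[ch]
      px[pr0:pr1, (midc + 1):pc1, ch] <- grn[ch]
    }
    gt[pr0:pr1, midc] <- 1
    gt[pr0:pr1, c(pc0, pc1)] <- 1
    gt[c(pr0, pr1), pc0:pc1] <- 1
    list(image = rgb_image(pmin(pmax(px, 0), 1)), gt = boundary_gt(gt))
  })
}

#' Build a stimulus from a declarative spec
#'
#' Dispatches on `kind` to the matching generator; the spec is the complete
#' recipe, so the same spec always reproduces the identical stimulus.
#'
#' @param kind One of `"grating"`, `"textured_square"`, `"isoluminant_edge"`,
#'   `"two_tone_edge"`, `"cluttered_scene"`.
#' @param ... Arguments passed to the generator.
#' @return `list(image = rgb_image, gt = boundary_gt)`.
#' @export
make_stimulus <- function(kind, ...) {
  gen <- switch(kind,
                grating = make_grating,
                textured_square = make_textured_square,
                isoluminant_edge = make_isoluminant_edge,
                two_tone_edge = make_two_tone_edge,
                cluttered_scene = make_cluttered_scene,
                stop("unknown stimulus kind: ", kind, call. = FALSE))
  gen(...)
}
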