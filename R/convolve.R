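# Shared coordinate convention: matrices are indexed [row, col] with the
# origin at the top-left; x increases rightward (columns), y downward (rows);
# angles are measured counter-clockwise from the +x axis. Kernels are stored
# as matrices whose centre element is the (0, 0) offset.

#' Isotropic Gaussian smoothing kernel
#'
#' Square kernel of odd side `2*ceiling(3*sigma) + 1` (3-sigma truncation),
#' renormalised to sum exactly 1.
#'
#' @param sigma Standard deviation in pixels; must be positive.
#' @return A square numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("'sigma' must be a positive scalar", call. = FALSE)
  r <- ceiling(3 * sigma)
  d <- seq(-r, r)
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  g / sum(g)
}

# Mirror (symmetric) padding: the edge row/column is repeated, so a constant
# field stays constant under any kernel that sums to 1.
mirror_pad <- function(field, rr, rc) {
  h <- nrow(field); w <- ncol(field)
  if (rr >= h || rc >= w)
    stop("kernel radius exceeds field size; image too small for this filter",
         call. = FALSE)
  ri <- c(rev(seq_len(rr)), seq_len(h), h + 1 - seq_len(rr))
  ci <- c(rev(seq_len(rc)), seq_len(w), w + 1 - seq_len(rc))
  field[ri, ci, drop = FALSE]
}

#' Two-dimensional filtering with mirror-padded borders
#'
#' Cross-correlates a field with an odd-sided kernel (the kernel is not
#' flipped; every kernel in the cascade is either symmetric or generated per
#' orientation over the full circle, which makes correlation and convolution
#' interchangeable). Borders are handled by mirror (reflect) padding so that
#' constant fields are fixed points of any unit-sum kernel. The computation
#' runs in the Fourier domain.
#'
#' @param field Numeric matrix.
#' @param kernel Numeric matrix with odd side lengths.
#' @return A matrix of the same dimension as `field`.
#' @export
convolve2d <- function(field, kernel) {
  if (!is.matrix(field) || !is.numeric(field))
    stop("'field' must be a numeric matrix", call. = FALSE)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh %% 2 != 1 || kw %% 2 != 1)
    stop("kernel must have odd side lengths", call. = FALSE)
  h <- nrow(field); w <- ncol(field)
  rr <- (kh - 1) / 2; rc <- (kw - 1) / 2
  if (rr == 0 && rc == 0) return(field * kernel[1, 1])
  p <- mirror_pad(field, rr, rc)
  kemb <- matrix(0, nrow(p), ncol(p))
  kemb[seq_len(kh), seq_len(kw)] <- kernel
  cc <- Re(stats::fft(stats::fft(p) * Conj(stats::fft(kemb)),
                      inverse = TRUE)) / length(p)
  cc[seq_len(h), seq_len(w), drop = FALSE]
}

#' Linearly rescale a field to `[0, 1]`
#'
#' A field that is constant (up to floating-point convolution noise) maps
#' to all zeros rather than amplifying that noise.
#'
#' @param field Numeric matrix or array.
#' @return Rescaled object of the same shape.
#' @export
rescale01 <- function(field) {
  lo <- min(field); hi <- max(field)
  if (hi - lo <= 1e-12 * max(1, abs(hi)))
    return(array(0, dim(field)))
  (field - lo) / (hi - lo)
}

# Half-wave rectification: max(v, 0), the non-negativity of firing rates.
hwr <- function(v) pmax(v, 0)

#' Oriented V1 simple-cell kernel (first derivative of Gaussian)
#'
#' The receptive field is an anisotropic Gaussian of width `k*sigma` and
#' aspect ratio `lambda`, rotated to preferred orientation `theta`, and
#' differentiated along its rotated x-axis:
#' `V = -x_t / (k^2 sigma^2) * f(x, y, theta, sigma)` with
#' `x_t = x cos(theta) + y sin(theta)`. The kernel is odd along `x_t`, so its
#' entries sum to zero and it responds to edges whose normal is `theta`.
#' Side length is `2*ceiling(3*k*sigma) + 1`.
#'
#' @param theta Preferred orientation in radians.
#' @param sigma CRF scale in pixels.
#' @param params A [model_params()] object supplying `k` and `lambda`.
#' @return A square numeric matrix with zero sum.
#' @export
v1_simple_kernel <- function(theta, sigma, params = model_params()) {
  validate_params(params)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  k <- params$k; lambda <- params$lambda
  r <- ceiling(3 * k * sigma)
  d <- seq(-r, r)
  x <- matrix(d, 2 * r + 1, 2 * r + 1, byrow = TRUE)  # columns: x rightward
  y <- matrix(d, 2 * r + 1, 2 * r + 1)                # rows: y downward
  xt <- x * cos(theta) + y * sin(theta)
  yt <- -x * sin(theta) + y * cos(theta)
  f <- exp(-(xt^2 + (lambda * yt)^2) / (2 * (k * sigma)^2)) /
    (2 * pi * (k * sigma)^2)
  -xt / (k^2 * sigma^2) * f
}

#' Annular DOG+ surround kernel
#'
#' Half-wave rectified difference of two unit-mass Gaussians,
#' `max(G(rho*sigma) - G(sigma), 0)`, L1-normalised. With `rho > 1` this is an
#' annulus: zero at the centre, a positive ring peaking near the classical
#' receptive field border, decaying outward - the distance weighting of the
#' non-classical surround (whose diameter is 2-5 times the CRF's).
#'
#' @param sigma CRF scale in pixels.
#' @param rho Surround/centre scale ratio; must exceed 1 unless `strict` is
#'   `TRUE` (then a centre-blob kernel is produced for demonstration).
#' @param strict Allow `rho <= 1` (degenerate, non-annular) kernels.
#' @return A square non-negative matrix summing to 1.
#' @export
dog_plus_kernel <- function(sigma, rho = 4, strict = FALSE) {
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (!strict && rho <= 1)
    stop("'rho' must exceed 1: the rectified surround must be an annulus",
         call. = FALSE)
  r <- ceiling(3 * max(rho, 1) * sigma)
  d <- seq(-r, r)
  r2 <- outer(d^2, d^2, "+")
  g_out <- exp(-r2 / (2 * (rho * sigma)^2)) / (2 * pi * (rho * sigma)^2)
  g_in <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  kk <- hwr(g_out - g_in)
  s <- sum(kk)
  if (s <= 0) stop("degenerate DOG+ kernel (empty support)", call. = FALSE)
  kk / s
}

#' Raised-cosine local window
#'
#' `w(r) = (cos(pi * r / R) + 1) / 2` for Euclidean distance `r` from the
#' window centre, with `R = (window_size - 1) / 2 + 1`; zero outside `r < R`.
#' The centre value is 1 and the corners are 0.
#'
#' @param window_size Odd side length in pixels.
#' @return A square non-negative matrix; its sum is the normaliser `eta`.
#' @export
raised_cosine_window <- function(window_size = 11) {
  if (window_size %% 2 != 1)
    stop("'window_size' must be odd", call. = FALSE)
  rad <- (window_size - 1) / 2
  R <- rad + 1
  d <- seq(-rad, rad)
  r <- sqrt(outer(d^2, d^2, "+"))
  w <- (cos(pi * r / R) + 1) / 2
  w[r >= R] <- 0
  w
}

#' Elliptical Gaussian pooling kernel (V2 receptive field)
#'
#' `f(x, y) = exp(-(a x^2 - 2 b x y + c y^2))` with
#' `a = cos^2(theta)/(2 sigma^2) + sin^2(theta)/(2 sigma_prime^2)`,
#' `b = -sin(2 theta)/(4 sigma^2) + sin(2 theta)/(4 sigma_prime^2)`,
#' `c = sin^2(theta)/(2 sigma^2) + cos^2(theta)/(2 sigma_prime^2)`,
#' renormalised to sum 1. At `theta = 0` the `sigma_prime` (long) axis lies
#' along y; passing the V1 filter normal as `theta` therefore aligns the long
#' axis with the edge tangent, pooling evidence along the contour.
#'
#' @param theta Orientation in radians of the `sigma` axis.
#' @param sigma Short-axis scale in pixels.
#' @param sigma_prime Long-axis scale in pixels.
#' @param strict If `TRUE`, use the degenerate product-form cross term
#'   `c = sin^2(theta)/(2 sigma^2) * cos^2(theta)/(2 sigma_prime^2)` for
#'   demonstration of its (dimensionally inconsistent) behaviour.
#' @return A square non-negative matrix summing to 1.
#' @export
elliptical_kernel <- function(theta, sigma, sigma_prime, strict = FALSE) {
  if (sigma <= 0 || sigma_prime <= 0)
    stop("scales must be positive", call. = FALSE)
  a <- cos(theta)^2 / (2 * sigma^2) + sin(theta)^2 / (2 * sigma_prime^2)
  b <- -sin(2 * theta) / (4 * sigma^2) + sin(2 * theta) / (4 * sigma_prime^2)
  cc <- if (strict) {
    sin(theta)^2 / (2 * sigma^2) * cos(theta)^2 / (2 * sigma_prime^2)
  } else {
    sin(theta)^2 / (2 * sigma^2) + cos(theta)^2 / (2 * sigma_prime^2)
  }
  r <- ceiling(3 * max(sigma, sigma_prime))
  d <- seq(-r, r)
  x <- matrix(d, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  y <- matrix(d, 2 * r + 1, 2 * r + 1)
  kk <- exp(-(a * x^2 - 2 * b * x * y + cc * y^2))
  kk / sum(kk)
}
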