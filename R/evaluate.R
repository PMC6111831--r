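# Boundary-detection evaluation: distance-tolerant one-to-one matching,
# precision/recall/F-measure, threshold sweeps, and average precision.

#' Match predicted and ground-truth boundary pixels
#'
#' Greedy nearest-first one-to-one matching: candidate (prediction, ground
#' truth) pairs within Euclidean distance `tol` are accepted in order of
#' increasing distance, each pixel matching at most once. The consensus map
#' is binarised at 0.5 (annotator majority). Ties in distance break on pixel
#' order, so the count is deterministic.
#'
#' @param pred Binary `{0, 1}` prediction matrix.
#' @param gt A [boundary_gt()] or a binary matrix.
#' @param tol Matching tolerance in pixels (`>= 0`).
#' @return List with counts `TP`, `FP`, `FN` and rates `P`, `R`, `F`
#'   (zero-denominator cases reported as 0).
#' @export
match_boundaries <- function(pred, gt, tol = 2) {
  if (tol < 0) stop("'tol' must be non-negative", call. = FALSE)
  gtm <- if (inherits(gt, "boundary_gt")) (gt$consensus >= 0.5) * 1 else gt
  if (!all(dim(pred) == dim(gtm)))
    stop("'pred' and ground truth must share a shape", call. = FALSE)
  pc <- which(pred > 0, arr.ind = TRUE)
  gc <- which(gtm > 0, arr.ind = TRUE)
  np <- nrow(pc); ng <- nrow(gc)
  tp <- 0L
  if (np > 0 && ng > 0) {
    d2 <- outer(pc[, 1], gc[, 1], "-")^2 + outer(pc[, 2], gc[, 2], "-")^2
    cand <- which(d2 <= tol^2 + 1e-9)
    if (length(cand)) {
      ord <- cand[order(d2[cand])]
      pi_ <- (ord - 1) %% np + 1
      gi_ <- (ord - 1) %/% np + 1
      pm <- logical(np); gm <- logical(ng)
      for (k in seq_along(ord)) {
        i <- pi_[k]; j <- gi_[k]
        if (!pm[i] && !gm[j]) {
          pm[i] <- TRUE; gm[j] <- TRUE; tp <- tp + 1L
        }
      }
    }
  }
  fp <- np - tp; fn <- ng - tp
  p <- if (np > 0) tp / np else 0
  r <- if (ng > 0) tp / ng else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(TP = tp, FP = fp, FN = fn, P = p, R = r, F = f)
}

#' Precision-recall curve of a response map
#'
#' Optionally thins the response once (orientation-free ridge NMS), then
#' sweeps `n_thresholds` evenly spaced levels over `(0, max]`, binarises,
#' matches against the ground truth at tolerance `tol`, and reports P, R, F
#' per level, the best F with its threshold, and the average precision
#' (trapezoidal area under P(R), anchored at R = 0 with the precision of the
#' strictest level).
#'
#' @param response Non-negative response matrix (any scale; thresholds span
#'   its range).
#' @param gt A [boundary_gt()] or binary matrix.
#' @param n_thresholds Number of threshold levels.
#' @param tol Matching tolerance in pixels.
#' @param thin Apply ridge NMS before thresholding.
#' @return An object of class `"pr_curve"`: list with `curve` (data frame
#'   `threshold`, `P`, `R`, `F`), `AP`, `best_F`, `best_threshold`.
#' @export
pr_curve <- function(response, gt, n_thresholds = 25, tol = 2, thin = TRUE) {
  if (min(response) < 0)
    stop("'response' must be non-negative", call. = FALSE)
  resp <- if (thin) nms_ridge(response) else response
  mx <- max(resp)
  if (mx <= 0) {
    curve <- data.frame(threshold = numeric(0), P = numeric(0),
                        R = numeric(0), F = numeric(0))
    return(structure(list(curve = curve, AP = 0, best_F = 0,
                          best_threshold = NA_real_), class = "pr_curve"))
  }
  # decreasing thresholds: recall is non-decreasing down the sweep
  ths <- seq(mx, mx / n_thresholds, length.out = n_thresholds)
  rows <- lapply(ths, function(t) {
    m <- match_boundaries((resp >= t) * 1, gt, tol)
    data.frame(threshold = t, P = m$P, R = m$R, F = m$F)
  })
  curve <- do.call(rbind, rows)
  best <- which.max(curve$F)
  o <- order(curve$R, curve$P)
  rr <- c(0, curve$R[o]); pp <- c(curve$P[o][1], curve$P[o])
  ap <- sum(diff(rr) * (utils::head(pp, -1) + utils::tail(pp, -1)) / 2)
  structure(list(curve = curve, AP = ap, best_F = curve$F[best],
                 best_threshold = curve$threshold[best]),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve: %d levels, best F = %.4f at t = %.4f, AP = %.4f>\n",
              nrow(x$curve), x$best_F,
              ifelse(is.na(x$best_threshold), NA, x$best_threshold), x$AP))
  invisible(x)
}

#' Default matching tolerance for an image size
#'
#' The de-facto boundary-benchmark convention: a fixed fraction of the image
#' diagonal.
#'
#' @param size `c(H, W)`.
#' @param frac Fraction of the diagonal.
#' @return Tolerance in pixels.
#' @export
eval_tolerance <- function(size, frac = 0.0075) {
  frac * sqrt(sum(size[1:2]^2))
}
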