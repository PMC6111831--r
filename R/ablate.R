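#' Component ablation report
#'
#' Runs the full detector and its three component ablations (`no_v2`,
#' `no_feedback`, `no_multiscale`) plus the raw fine-scale hierarchy output
#' on one image, and tabulates the best-threshold F-measure and AP of each
#' against the ground truth.
#'
#' @param img An [rgb_image()].
#' @param gt A [boundary_gt()] or binary matrix.
#' @param params A [model_params()].
#' @param tol Matching tolerance in pixels; defaults to
#'   `eval_tolerance(dim, params$eval_tol_frac)`.
#' @param n_thresholds Threshold levels per P-R sweep.
#' @return Data frame with columns `variant`, `best_F`, `AP`.
#' @export
ablation_report <- function(img, gt, params = model_params(), tol = NULL,
                            n_thresholds = 25) {
  if (is.null(tol))
    tol <- eval_tolerance(c(img$height, img$width), params$eval_tol_frac)
  variants <- list(
    full = detect(img, params),
    no_v2 = detect(img, params, no_v2 = TRUE),
    no_feedback = detect(img, params, no_feedback = TRUE),
    no_multiscale = detect(img, params, no_multiscale = TRUE),
    fine_scale_only = run_hierarchy(img, params)
  )
  rows <- lapply(names(variants), function(nm) {
    pr <- pr_curve(variants[[nm]], gt, n_thresholds = n_thresholds,
                   tol = tol)
    data.frame(variant = nm, best_F = pr$best_F, AP = pr$AP)
  })
  do.call(rbind, rows)
}
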