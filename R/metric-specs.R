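# Registry of the ten image quality metrics: identity, direction,
# reference requirement, required input range and availability constraints
# across the pre-processing grid.

ALL_METRICS <- c("ssim", "psnr", "fsim", "vif", "lpips",
                 "tg", "aes", "ngs", "ie", "ge")

#' Metric specification registry
#'
#' One row per metric, recording its direction (whether larger values mean
#' better quality), whether it needs a reference image, the input range it
#' requires, and on which cells of the pre-processing grid it is available.
#'
#' FSIM, VIF and the perceptual feature distance (`lpips`) require inputs
#' on a specific range, so they are only available under min-max or
#' percentile normalization; and because they are computed across the
#' entire image matrix (frequency-domain and pyramid operations), they are
#' unavailable under the `"mask"` mode, which restricts aggregation to an
#' irregular pixel set. All other metrics are available everywhere.
#'
#' @param metrics Optional character vector to subset/reorder; defaults to
#'   all ten metrics: `ssim`, `psnr`, `fsim`, `vif`, `lpips` (reference-
#'   based) and `tg`, `aes`, `ngs`, `ie`, `ge` (reference-free).
#' @return A tibble with columns `metric`, `direction`
#'   (`"higher_better"`/`"lower_better"`), `requires_reference`,
#'   `required_range` (list column: `NULL` or `c(lo, hi)`),
#'   `allowed_norm_modes` and `allowed_mask_modes` (list columns).
#' @export
metric_specs <- function(metrics = NULL) {
  restricted_norm <- list(c("minmax", "percentile"))
  restricted_mask <- list(c("none", "multiply"))
  all_norm <- list(NORM_MODES)
  all_mask <- list(MASK_MODES)
  specs <- tibble::tibble(
    metric = ALL_METRICS,
    direction = c("higher_better", "higher_better", "higher_better",
                  "higher_better", "lower_better",
                  "higher_better", "higher_better", "higher_better",
                  "lower_better", "lower_better"),
    requires_reference = c(rep(TRUE, 5), rep(FALSE, 5)),
    required_range = list(NULL, NULL, c(0, 1), c(0, 1), c(-1, 1),
                          NULL, NULL, NULL, NULL, NULL),
    allowed_norm_modes = c(all_norm, all_norm, restricted_norm,
                           restricted_norm, restricted_norm,
                           rep(all_norm, 5)),
    allowed_mask_modes = c(all_mask, all_mask, restricted_mask,
                           restricted_mask, restricted_mask,
                           rep(all_mask, 5)))
  if (!is.null(metrics)) {
    metrics <- tolower(metrics)
    unknown <- setdiff(metrics, specs$metric)
    if (length(unknown) > 0) {
      moqam_abort(paste0("unknown metric(s): ", paste(unknown, collapse = ", ")),
                  "moqam_config_error")
    }
    specs <- specs[match(metrics, specs$metric), ]
  }
  specs
}

#' Check a metric's availability under a configuration
#'
#' @param metric Metric name.
#' @param config A [pipeline_config()].
#' @return `TRUE` if available, otherwise a character reason
#'   (machine-readable: `"range requirement: ..."` or
#'   `"mask-mode requirement: ..."`).
#' @export
metric_available <- function(metric, config) {
  spec <- metric_specs(metric)
  if (!config$norm_mode %in% spec$allowed_norm_modes[[1]]) {
    return(sprintf("range requirement: %s needs norm_mode in {%s}, got '%s'",
                   metric, paste(spec$allowed_norm_modes[[1]], collapse = ", "),
                   config$norm_mode))
  }
  if (!config$mask_mode %in% spec$allowed_mask_modes[[1]]) {
    return(sprintf("mask-mode requirement: %s needs mask_mode in {%s}, got '%s'",
                   metric, paste(spec$allowed_mask_modes[[1]], collapse = ", "),
                   config$mask_mode))
  }
  TRUE
}
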