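# Orchestration: run the slice-wise metric pipeline over a volume under
# one pipeline_config and reduce to one value per metric; batch evaluation
# over a dataset produces the long-form study table consumed by the
# agreement module.

#' Reduce per-slice metric values to a single value
#'
#' `"mean"` averages the non-missing per-slice values; `"worst"` takes the
#' minimum for higher-is-better metrics and the maximum for
#' lower-is-better ones (the most degraded slice). Missing values
#' (degenerate slices) are skipped.
#'
#' @param values Numeric vector of per-slice values (may contain `NA`).
#' @param reduction `"mean"` or `"worst"`.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return Scalar.
#' @export
reduce_series <- function(values, reduction = c("mean", "worst"),
                          direction = c("higher_better", "lower_better")) {
  reduction <- canon_mode(reduction[1], "reduction")
  direction <- match.arg(direction)
  v <- values[!is.na(values)]
  if (length(v) == 0) {
    moqam_abort("all per-slice values are missing; nothing to reduce",
                "moqam_degenerate_error")
  }
  switch(reduction,
         mean = mean(v),
         worst = if (direction == "higher_better") min(v) else max(v))
}

# Compute every requested metric on one prepared slice pair.
# Gradient/edge maps are shared across the gradient-based metrics.
slice_metrics <- function(pair, specs, dynamic_range = NULL,
                          extractor = NULL) {
  img <- pair$image
  ref <- pair$reference
  dom <- pair$domain
  vals <- stats::setNames(rep(NA_real_, nrow(specs)), specs$metric)
  need_g <- any(specs$metric %in% c("tg", "aes", "ngs", "ge"))
  g <- if (need_g) gradient_magnitude(img) else NULL
  for (m in specs$metric) {
    vals[m] <- withCallingHandlers(
      switch(m,
        ssim = ssim(img, ref, dynamic_range = dynamic_range, domain = dom),
        psnr = psnr(img, ref, domain = dom),
        fsim = fsim(img, ref),
        vif = vif(img, ref),
        lpips = perceptual_distance(rescale_for_metric(img, "lpips"),
                                    rescale_for_metric(ref, "lpips"),
                                    extractor = extractor %||% feature_extractor()),
        tg = mean(domain_values(g^2, dom)),
        aes = avg_edge_strength(img, domain = dom),
        ngs = {
          gd <- domain_values(g, dom); s <- sum(gd)
          if (s <= 0) NA_real_ else sum((gd / s)^2)
        },
        ie = image_entropy(img, domain = dom),
        ge = {
          gd <- domain_values(g, dom)
          root_energy_entropy(gd)
        }),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  vals
}

#' Evaluate all metrics on one volume under one configuration
#'
#' Runs the full pipeline: slice selection (10% brain-voxel rule),
#' volume-wise normalization, mask-mode application, per-metric range
#' rescaling, per-slice metric computation and slice reduction. The
#' availability contract is enforced per metric before any computation:
#' metrics whose range or mask-mode requirement is violated yield a row
#' with `available = FALSE` and a machine-readable reason rather than a
#' number.
#'
#' @param vol [image_volume()] under evaluation.
#' @param reference Optional reference [image_volume()]; required for the
#'   reference-based metrics in `specs`.
#' @param mask Optional [brain_mask()]; required unless `mask_mode` is
#'   `"none"`.
#' @param specs A [metric_specs()] tibble (default: all ten metrics).
#' @param config A [pipeline_config()].
#' @param extractor [feature_extractor()] for the perceptual distance.
#' @return A tibble with one row per metric: `image_id`, `metric`,
#'   `mask_mode`, `norm_mode`, `reduction`, `value`, `available`, `reason`,
#'   `n_slices`, `direction`.
#' @export
evaluate_volume <- function(vol, reference = NULL, mask = NULL,
                            specs = metric_specs(),
                            config = pipeline_config(),
                            extractor = feature_extractor()) {
  stopifnot(inherits(vol, "image_volume"))
  if (any(specs$requires_reference) && is.null(reference)) {
    moqam_abort(sprintf(
      "reference-based metric(s) requested without a reference image: %s",
      paste(specs$metric[specs$requires_reference], collapse = ", ")),
      "moqam_config_error")
  }
  if (config$mask_mode != "none" && is.null(mask)) {
    moqam_abort(sprintf("mask_mode '%s' requires a brain mask", config$mask_mode),
                "moqam_config_error")
  }
  avail <- vapply(specs$metric, function(m) {
    a <- metric_available(m, config)
    if (isTRUE(a)) NA_character_ else a
  }, character(1))
  live <- specs[is.na(avail), ]

  indices <- if (!is.null(mask)) select_slices(mask, config)
             else seq_len(n_slices_along(vol$data, config$slice_axis))
  n_used <- stats::setNames(rep(0L, nrow(specs)), specs$metric)
  values <- stats::setNames(rep(NA_real_, nrow(specs)), specs$metric)
  reasons <- stats::setNames(avail, specs$metric)

  if (nrow(live) > 0) {
    nvol <- normalize_volume(vol, mask, config)
    nref <- if (!is.null(reference)) normalize_volume(reference, mask, config)
            else NULL
    pairs <- apply_mask_mode(nvol, nref, mask, config, indices = indices)
    # dynamic range for SSIM: intensity range of the normalized reference
    # over the evaluation domain (about 1 after min-max/percentile)
    L <- NULL
    if ("ssim" %in% live$metric) {
      dom3 <- if (config$mask_mode != "none") mask$data else
        array(TRUE, dim(nvol$data))
      L <- diff(range(nref$data[dom3]))
      if (L <= 0) L <- 1
    }
    per_slice <- vapply(pairs, slice_metrics, numeric(nrow(live)),
                        specs = live, dynamic_range = L, extractor = extractor)
    per_slice <- matrix(per_slice, nrow = nrow(live),
                        dimnames = list(live$metric, NULL))
    for (m in live$metric) {
      v <- per_slice[m, ]
      n_used[m] <- sum(!is.na(v))
      if (n_used[m] == 0L) {
        reasons[m] <- "degenerate input: all slice values missing"
      } else {
        values[m] <- reduce_series(v, config$reduction,
                                   specs$direction[specs$metric == m])
      }
    }
  }
  tibble::tibble(
    image_id = vol$id,
    metric = specs$metric,
    mask_mode = config$mask_mode,
    norm_mode = config$norm_mode,
    reduction = config$reduction,
    value = unname(values),
    available = is.na(reasons),
    reason = unname(reasons),
    n_slices = unname(n_used),
    direction = specs$direction)
}

rec_field <- function(rec, name) {
  if (!name %in% names(rec)) return(NULL)
  v <- rec[[name]]
  if (is.list(v)) v[[1]] else if (is.na(v) || !nzchar(v)) NULL else v
}

resolve_record <- function(rec) {
  getv <- function(obj, path, ...) {
    if (!is.null(obj)) return(obj)
    if (is.null(path)) return(NULL)
    read_volume(path, ...)
  }
  vol <- getv(rec_field(rec, "image"), rec_field(rec, "image_path"),
              id = rec$image_id)
  if (is.null(vol)) {
    moqam_abort(sprintf("no image or image_path for '%s'", rec$image_id),
                "moqam_input_error")
  }
  vol$id <- rec$image_id  # manifest id is authoritative for the study table
  ref <- getv(rec_field(rec, "reference"), rec_field(rec, "reference_path"))
  list(vol = vol, ref = ref, rec = rec)
}

#' Evaluate a dataset over one or more configurations
#'
#' Takes a manifest tibble — one row per image with columns `image_id` and
#' either list-columns `image`/`reference`/`mask` holding volumes and
#' masks, or path columns `image_path`/`reference_path`/`mask_path` — and
#' evaluates every metric under every configuration. Per-image failures
#' are recorded as unavailable rows (with the error message as reason) and
#' the batch continues.
#'
#' @param manifest Manifest tibble as described above; `image_id` must be
#'   unique. Extra columns (e.g. `subject`, `severity`) are carried
#'   through.
#' @param specs A [metric_specs()] tibble.
#' @param configs A [pipeline_config()] or list of them.
#' @param extractor [feature_extractor()] for the perceptual distance.
#' @return Long-form study tibble: one row per (image, metric, config)
#'   with the [evaluate_volume()] columns plus `config` (fingerprint) and
#'   any carried manifest columns; deterministic row order.
#' @export
evaluate_dataset <- function(manifest, specs = metric_specs(),
                             configs = pipeline_config(),
                             extractor = feature_extractor()) {
  stopifnot(is.data.frame(manifest), "image_id" %in% names(manifest))
  if (anyDuplicated(manifest$image_id)) {
    moqam_abort("manifest image_id values must be unique", "moqam_input_error")
  }
  if (inherits(configs, "pipeline_config")) configs <- list(configs)
  carried <- setdiff(names(manifest),
                     c("image", "reference", "mask",
                       "image_path", "reference_path", "mask_path"))
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    res <- tryCatch({
      r <- resolve_record(rec)
      mask <- rec_field(rec, "mask")
      if (is.null(mask)) {
        mp <- rec_field(rec, "mask_path")
        if (!is.null(mp)) mask <- read_mask(mp, r$vol)
      }
      purrr::map(configs, function(cfg) {
        evaluate_volume(r$vol, r$ref, mask, specs = specs, config = cfg,
                        extractor = extractor) |>
          dplyr::mutate(config = config_fingerprint(cfg), .after = "metric")
      }) |> dplyr::bind_rows()
    }, error = function(e) {
      purrr::map(configs, function(cfg) {
        tibble::tibble(
          image_id = rec$image_id, metric = specs$metric,
          config = config_fingerprint(cfg),
          mask_mode = cfg$mask_mode, norm_mode = cfg$norm_mode,
          reduction = cfg$reduction, value = NA_real_, available = FALSE,
          reason = paste0("error: ", conditionMessage(e)),
          n_slices = 0L, direction = specs$direction)
      }) |> dplyr::bind_rows()
    })
    dplyr::left_join(res, manifest[i, carried, drop = FALSE], by = "image_id")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("moqam_study_table", class(out))
  out
}
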