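mask_with_fractions <- function(frac, n = 20) {
  # slice k has round(frac[k]*n^2) brain pixels
  arr <- array(FALSE, c(n, n, length(frac)))
  for (k in seq_along(frac)) {
    npx <- round(frac[k] * n * n)
    if (npx > 0) arr[, , k][seq_len(npx)] <- TRUE
  }
  brain_mask(arr)
}

test_that("slice selection implements the 10% brain-voxel rule", {
  m <- mask_with_fractions(c(0.05, 0.20, 0.15))
  expect_equal(select_slices(m, pipeline_config()), c(2L, 3L))
  # full mask keeps every slice; threshold zero keeps every slice
  full <- brain_mask(array(TRUE, c(20, 20, 4)))
  expect_equal(select_slices(full, pipeline_config()), 1:4)
  expect_equal(
    select_slices(m, pipeline_config(brain_fraction_threshold = 0)), 1:3)
  expect_error(
    select_slices(m, pipeline_config(brain_fraction_threshold = 0.5)),
    class = "moqam_empty_selection_error")
})

test_that("raising the slice threshold never adds indices", {
  set.seed(42)
  for (rep in 1:5) {
    m <- mask_with_fractions(runif(8, 0, 0.4))
    prev <- NULL
    for (th in c(0, 0.1, 0.2, 0.3)) {
      idx <- tryCatch(
        select_slices(m, pipeline_config(brain_fraction_threshold = th)),
        moqam_empty_selection_error = function(e) integer(0))
      if (!is.null(prev)) expect_true(all(idx %in% prev))
      prev <- idx
    }
  }
})

test_that("normalization modes follow their closed forms", {
  arr <- array(2, c(8, 8, 8))
  arr[1:2, 1, 1] <- c(4, 6)
  vol <- image_volume(arr)
  mm <- normalize_volume(vol, config = pipeline_config(mask_mode = "none",
                                                       norm_mode = "minmax"))
  expect_equal(sort(unique(as.vector(mm$data))), c(0, 0.5, 1))
  expect_equal(range(mm$data), c(0, 1))

  ms <- normalize_volume(vol, config = pipeline_config(mask_mode = "none",
                                                       norm_mode = "meanstd"))
  expect_equal(mean(ms$data), 0, tolerance = 1e-8)
  expect_equal(sd(ms$data), 1, tolerance = 1e-8)

  idn <- normalize_volume(vol, config = pipeline_config(norm_mode = "none"))
  expect_identical(idn$data, vol$data)
})

test_that("percentile normalization rescales by the 1st/99.9th percentiles and clips", {
  set.seed(7)
  arr <- array(runif(20^3, 10, 90), c(20, 20, 20))
  arr[1, 1, 1] <- 1e4  # extreme outlier
  vol <- image_volume(arr)
  cfg <- pipeline_config(mask_mode = "none", norm_mode = "percentile")
  out <- normalize_volume(vol, config = cfg)$data
  p <- quantile(arr, c(0.01, 0.999), names = FALSE)
  expect_equal(range(out), c(0, 1))
  expect_equal(out[1, 1, 1], 1)  # outlier above p99.9 clips to 1
  i <- c(5, 5, 5)
  expect_equal(out[5, 5, 5],
               min(max((arr[5, 5, 5] - p[1]) / (p[2] - p[1]), 0), 1))
})

test_that("degenerate constant volumes are rejected under scaling normalizations", {
  vol <- image_volume(array(3, c(8, 8, 8)))
  for (nm in c("minmax", "meanstd", "percentile")) {
    expect_error(
      normalize_volume(vol, config = pipeline_config(mask_mode = "none",
                                                     norm_mode = nm)),
      class = "moqam_degenerate_error")
  }
})

test_that("min-max and mean-std are invariant to positive affine input transforms", {
  ph <- cached_phantom()
  cfg_list <- list(pipeline_config(norm_mode = "minmax"),
                   pipeline_config(norm_mode = "meanstd"))
  shifted <- image_volume(3.7 * ph$volume$data + 120, id = "affine")
  for (cfg in cfg_list) {
    a <- normalize_volume(ph$volume, ph$mask, cfg)$data
    b <- normalize_volume(shifted, ph$mask, cfg)$data
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("normalization statistics use the mask domain when the mask is in play", {
  ph <- cached_phantom()
  cfg <- pipeline_config(mask_mode = "multiply", norm_mode = "minmax")
  out <- normalize_volume(ph$volume, ph$mask, cfg)$data
  expect_equal(range(out[ph$mask$data]), c(0, 1))
})

test_that("mask modes shape the slice stream and evaluation domain correctly", {
  ph <- cached_phantom()
  vol <- ph$volume; mask <- ph$mask
  idx <- select_slices(mask, pipeline_config())

  none <- apply_mask_mode(vol, vol, mask, pipeline_config(mask_mode = "none"),
                          indices = idx)
  expect_identical(none[[1]]$image, vol$data[, , idx[1]])
  expect_null(none[[1]]$domain)

  mult <- apply_mask_mode(vol, vol, mask, pipeline_config(mask_mode = "multiply"),
                          indices = idx)
  bg <- !mask$data[, , idx[1]]
  expect_true(all(mult[[1]]$image[bg] == 0))
  expect_null(mult[[1]]$domain)

  mm <- apply_mask_mode(vol, vol, mask, pipeline_config(mask_mode = "mask"),
                        indices = idx)
  expect_identical(mm[[1]]$image, vol$data[, , idx[1]])
  for (k in seq_along(idx)) {
    expect_equal(sum(mm[[k]]$domain), sum(mask$data[, , idx[k]]))
  }
  expect_error(apply_mask_mode(vol, NULL, NULL, pipeline_config(mask_mode = "multiply")),
               class = "moqam_config_error")
})

test_that("metric range rescaling maps [0,1] onto each required range", {
  sl <- matrix(c(0, 0.5, 1, 0.25), 2, 2)
  lp <- rescale_for_metric(sl, "lpips")
  expect_equal(lp, matrix(c(-1, 0, 1, -0.5), 2, 2))
  expect_identical(rescale_for_metric(sl, "tg"), sl)     # no range requirement
  expect_identical(rescale_for_metric(sl, "fsim"), sl)   # [0,1] convention
})

test_that("published vocabulary is accepted case-insensitively in configs", {
  cfg <- pipeline_config("Multiply", "Percentile", "Worst")
  expect_equal(config_fingerprint(cfg), "multiply-percentile-worst")
  cfg2 <- pipeline_config("No Mask", "Mean-Std", "Mean")
  expect_equal(config_fingerprint(cfg2), "none-meanstd-mean")
  expect_error(pipeline_config("bogus"), class = "moqam_config_error")
})

test_that("histogram report: identity gives overlap 1; min-max is outlier-sensitive", {
  ph <- cached_phantom()
  rep_id <- histogram_report(ph$volume, ph$volume, ph$mask)
  expect_equal(rep_id$overlap, rep(1, 4))

  # a large constant offset is removed by min-max: overlap stays 1
  off <- image_volume(ph$volume$data + 500, id = "offset")
  rep_off <- histogram_report(off, ph$volume, ph$mask)
  expect_equal(rep_off$overlap[rep_off$norm_mode == "minmax"], 1, tolerance = 1e-12)

  # one extreme outlier inside the mask degrades min-max but not percentile
  out_arr <- ph$volume$data
  out_arr[which(ph$mask$data)[1]] <- 50 * max(out_arr)
  outlier <- image_volume(out_arr, id = "outlier")
  rep_out <- histogram_report(outlier, ph$volume, ph$mask)
  ov <- setNames(rep_out$overlap, rep_out$norm_mode)
  expect_lt(ov["minmax"], ov["percentile"])
})
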