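test_that("slice reduction respects the metric direction", {
  v <- c(0.9, 0.8, 0.95)
  expect_equal(reduce_series(v, "worst", "higher_better"), 0.8)
  expect_equal(reduce_series(c(1.2, 1.5, 1.3), "worst", "lower_better"), 1.5)
  expect_equal(reduce_series(v, "mean", "higher_better"), mean(v))
  expect_equal(reduce_series(c(0.9, NA, 0.8), "mean", "higher_better"), 0.85)
  expect_error(reduce_series(c(NA_real_, NA_real_), "mean", "higher_better"),
               class = "moqam_degenerate_error")
})

test_that("the full pipeline returns identity values on a self-pair", {
  ph <- cached_phantom()
  res <- suppressWarnings(
    evaluate_volume(ph$volume, ph$volume, ph$mask,
                    config = pipeline_config("Multiply", "Percentile", "Worst")))
  val <- setNames(res$value, res$metric)
  expect_equal(unname(val["ssim"]), 1)
  expect_equal(unname(val["fsim"]), 1)
  expect_equal(unname(val["vif"]), 1, tolerance = 1e-6)
  expect_equal(unname(val["lpips"]), 0)
  expect_identical(unname(val["psnr"]), Inf)
  expect_true(all(res$available))
  expect_true(all(res$n_slices > 0))
})

test_that("availability contract: range-restricted metrics are withheld, not computed", {
  ph <- cached_phantom()
  for (nm in c("meanstd", "none")) {
    res <- suppressWarnings(
      evaluate_volume(ph$volume, ph$volume, ph$mask,
                      config = pipeline_config("multiply", nm, "worst")))
    blocked <- res[res$metric %in% c("fsim", "vif", "lpips"), ]
    expect_true(all(!blocked$available))
    expect_true(all(grepl("range requirement", blocked$reason)))
    open <- res[res$metric %in% c("ssim", "psnr", "tg", "ie"), ]
    expect_true(all(open$available))
  }
  res_mask <- suppressWarnings(
    evaluate_volume(ph$volume, ph$volume, ph$mask,
                    config = pipeline_config("mask", "percentile", "worst")))
  blocked <- res_mask[res_mask$metric %in% c("fsim", "vif", "lpips"), ]
  expect_true(all(!blocked$available))
  expect_true(all(grepl("mask-mode requirement", blocked$reason)))
})

test_that("requesting reference-based metrics without a reference is a config error", {
  ph <- cached_phantom()
  expect_error(
    evaluate_volume(ph$volume, NULL, ph$mask, specs = metric_specs("ssim")),
    class = "moqam_config_error")
  expect_error(
    evaluate_volume(ph$volume, NULL, ph$mask, specs = metric_specs("ssim")),
    "ssim")
  # reference-free only: no reference needed
  res <- evaluate_volume(ph$volume, NULL, ph$mask, specs = metric_specs("tg"))
  expect_true(res$available)
})

test_that("psnr decreases along a motion severity ladder through the pipeline", {
  ph <- cached_phantom()
  vals <- sapply(c(0, 1, 2), function(s) {
    cv <- corrupt(ph$volume, corruption_spec("motion", severity = s, seed = 5))
    res <- suppressWarnings(
      evaluate_volume(cv, ph$volume, ph$mask, specs = metric_specs("psnr")))
    res$value
  })
  expect_true(all(diff(vals) < 0))
})

test_that("worst is never better than mean, per metric direction", {
  ph <- cached_phantom()
  cv <- corrupt(ph$volume, corruption_spec("motion", severity = 1, seed = 6))
  res_m <- suppressWarnings(evaluate_volume(
    cv, ph$volume, ph$mask, config = pipeline_config("multiply", "percentile", "mean")))
  res_w <- suppressWarnings(evaluate_volume(
    cv, ph$volume, ph$mask, config = pipeline_config("multiply", "percentile", "worst")))
  j <- dplyr::inner_join(res_m[c("metric", "value", "direction")],
                         res_w[c("metric", "value")],
                         by = "metric", suffix = c("_mean", "_worst"))
  j <- j[!is.na(j$value_mean), ]
  hi <- j$direction == "higher_better"
  expect_true(all(j$value_worst[hi] <= j$value_mean[hi] + 1e-12))
  expect_true(all(j$value_worst[!hi] >= j$value_mean[!hi] - 1e-12))
  # reduction changes the scalar, never the availability
  expect_equal(res_m$available, res_w$available)
})

test_that("dataset evaluation has full cardinality, determinism and availability rows", {
  ph1 <- cached_phantom(seed = 0)
  ph2 <- cached_phantom(seed = 1)
  manifest <- tibble::tibble(
    image_id = c("a", "b"),
    image = list(ph1$volume, ph2$volume),
    reference = list(ph1$volume, ph2$volume),
    mask = list(ph1$mask, ph2$mask))
  specs <- metric_specs(c("ssim", "fsim"))
  configs <- list(pipeline_config("multiply", "percentile", "worst"),
                  pipeline_config("multiply", "meanstd", "worst"))
  t1 <- suppressWarnings(evaluate_dataset(manifest, specs, configs))
  expect_equal(nrow(t1), 2 * 2 * 2)
  t2 <- suppressWarnings(evaluate_dataset(manifest, specs, configs))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # invalid config yields "not available" rows, not dropped rows
  fsim_ms <- t1[t1$metric == "fsim" & t1$norm_mode == "meanstd", ]
  expect_equal(nrow(fsim_ms), 2)
  expect_true(all(!fsim_ms$available))
  expect_error(
    evaluate_dataset(manifest[c(1, 1), ], specs, configs), "unique")
})

test_that("per-image failures become error rows while the batch continues", {
  ph <- cached_phantom()
  manifest <- tibble::tibble(
    image_id = c("good", "bad"),
    image = list(ph$volume, NULL),
    image_path = c(NA, "/nonexistent/file.nii"),
    reference = list(ph$volume, ph$volume),
    mask = list(ph$mask, ph$mask))
  res <- suppressWarnings(
    evaluate_dataset(manifest, metric_specs("ssim"), pipeline_config()))
  expect_equal(nrow(res), 2)
  expect_true(res$available[res$image_id == "good"])
  expect_false(res$available[res$image_id == "bad"])
  expect_match(res$reason[res$image_id == "bad"], "error")
})
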