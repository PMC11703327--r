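test_that("phantom generation is deterministic and brain-like in its proportions", {
  p1 <- make_phantom(shape = c(32, 32, 32), seed = 4)
  p2 <- make_phantom(shape = c(32, 32, 32), seed = 4)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$mask$data, p2$mask$data)
  # background dominates; brain mask is a minority of voxels
  expect_lt(mean(p1$mask$data), 0.4)
  expect_gt(mean(p1$volume$data == 0), 0.3)
  # end slices carry too little brain for the 10% rule
  idx <- select_slices(p1$mask, pipeline_config())
  expect_false(1L %in% idx)
  expect_false(dim(p1$mask$data)[3] %in% idx)
  expect_error(make_phantom(shape = c(16, 32, 32)), "at least 32")
})

test_that("corruption at severity zero is bit-exact and otherwise deterministic", {
  ph <- cached_phantom()
  for (kind in c("motion", "noise", "blur")) {
    out <- corrupt(ph$volume, corruption_spec(kind, severity = 0, seed = 1))
    expect_identical(out$data, ph$volume$data)
  }
  a <- corrupt(ph$volume, corruption_spec("motion", severity = 1, seed = 2))
  b <- corrupt(ph$volume, corruption_spec("motion", severity = 1, seed = 2))
  expect_identical(a$data, b$data)
  c_ <- corrupt(ph$volume, corruption_spec("motion", severity = 1, seed = 3))
  expect_false(identical(a$data, c_$data))
  expect_true(all(a$data >= 0))  # magnitude image
})

test_that("motion corruption degrades psnr monotonically and conserves energy", {
  ph <- cached_phantom()
  k <- dim(ph$volume$data)[3] %/% 2
  vals <- sapply(c(0.5, 1, 2), function(s) {
    cv <- corrupt(ph$volume, corruption_spec("motion", severity = s, seed = 7))
    psnr(cv$data[, , k], ph$volume$data[, , k])
  })
  expect_true(all(diff(vals) < 0))
  cv <- corrupt(ph$volume, corruption_spec("motion", severity = 2, seed = 7))
  ratio <- sum(cv$data^2) / sum(ph$volume$data^2)
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.2)
})

test_that("noise and blur corruption behave as specified", {
  ph <- cached_phantom()
  nz <- corrupt(ph$volume, corruption_spec("noise", severity = 1, seed = 8))
  expect_gt(sd(nz$data - ph$volume$data), 0)
  expect_true(all(nz$data >= 0))
  bl <- corrupt(ph$volume, corruption_spec("blur", severity = 1, seed = 8))
  expect_lt(tenengrad(bl$data[, , 16]), tenengrad(ph$volume$data[, , 16]))
})

test_that("simulated raters track severity and agree perfectly without noise", {
  sev <- rep(c(0, 0.5, 1, 2), each = 10)
  rt0 <- simulate_raters(sev, noise_sd = 0, seed = 0)
  expect_true(all(rt0$scores[sev == 0, ] == 5))
  expect_equal(krippendorff_alpha(rt0)$alpha, 1)
  # moderate noise: fused scores still strongly anti-correlated with severity
  rt <- simulate_raters(sev, noise_sd = 0.35, seed = 1)
  fused <- fuse_scores(rt)
  rho <- cor(fused$score, -sev, method = "spearman")
  expect_gte(rho, 0.9)
  # radiologists carry double weight
  expect_equal(unname(rt$weights), c(2, 2, 1, 1))
})

test_that("study generation has the right cardinality and reproducible outputs", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  st1 <- generate_study(n_subjects = 3, severities = c(0, 1, 2), seed = 11,
                        shape = c(32, 32, 32), out_dir = dir1)
  expect_equal(nrow(st1$manifest), 9)
  expect_equal(dplyr::n_distinct(st1$manifest$mask_path), 3)
  expect_true(all(file.exists(st1$manifest$image_path)))
  man <- readr::read_csv(file.path(dir1, "manifest.csv"), show_col_types = FALSE)
  expect_equal(nrow(man), 9)

  st2 <- generate_study(n_subjects = 3, severities = c(0, 1, 2), seed = 11,
                        shape = c(32, 32, 32), out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "raters.csv")),
                   readLines(file.path(dir2, "raters.csv")))
  man2 <- readr::read_csv(file.path(dir2, "manifest.csv"), show_col_types = FALSE)
  expect_identical(man[c("image_id", "subject", "severity")],
                   man2[c("image_id", "subject", "severity")])
  expect_identical(st1$manifest$image[[5]]$data, st2$manifest$image[[5]]$data)
})

test_that("correlation signs propagate: higher-better positive, lower-better negative", {
  # motion study: SSIM (higher better) positive, GE (lower better) negative
  st <- generate_study(n_subjects = 6, severities = c(0, 1, 2), seed = 12,
                       shape = c(32, 32, 32))
  tab <- suppressWarnings(
    evaluate_dataset(st$manifest, specs = metric_specs(c("ssim", "ge"))))
  fused <- fuse_scores(st$raters)
  cors <- correlate(tab, fused)
  rho <- setNames(cors$rho, cors$metric)
  expect_gt(rho["ssim"], 0)
  expect_lt(rho["ge"], 0)
  expect_true(all(cors$significant))

  # image entropy moves in its worse-quality direction (upward) under
  # additive noise on raw slices, consistent with its lower-is-better reading
  ph <- cached_phantom(seed = 12)
  sl <- ph$volume$data[, , 16]
  ie_clean <- image_entropy(sl)
  ie_noisy <- sapply(c(0.5, 1, 2), function(s) {
    nz <- corrupt(ph$volume, corruption_spec("noise", severity = s, seed = 5))
    image_entropy(nz$data[, , 16])
  })
  expect_true(all(diff(c(ie_clean, ie_noisy)) > 0))
})
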