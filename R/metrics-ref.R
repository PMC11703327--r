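# Reference-based metrics: SSIM, PSNR, FSIM, VIF and a perceptual feature
# distance. SSIM/PSNR accept an arbitrary evaluation domain; FSIM, VIF and
# the perceptual distance operate on whole slices (frequency-domain /
# pyramid operations), which is why they are unavailable in "mask" mode.

check_pair <- function(slice, ref_slice) {
  if (!identical(dim(slice), dim(ref_slice))) {
    moqam_abort("image and reference slices have different shapes",
                "moqam_input_error")
  }
}

#' Structural similarity index (SSIM)
#'
#' Mean over local Gaussian-weighted patches of
#' `(2*mu1*mu2 + c1) * (2*cov + c2) / ((mu1^2 + mu2^2 + c1) * (var1 + var2 + c2))`
#' with `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` for dynamic range `L`.
#' Windows are 11x11 with Gaussian weighting (sigma 1.5); the local map is
#' computed on fully interior windows and averaged over the evaluation
#' domain. 1 indicates perfect similarity.
#'
#' @param slice,ref_slice 2D numeric matrices of equal shape.
#' @param dynamic_range Dynamic range `L`; defaults to the reference
#'   slice's intensity range.
#' @param domain Optional logical matrix restricting the evaluation domain.
#' @param window_size,window_sigma Gaussian window parameters.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(slice, ref_slice, dynamic_range = NULL, domain = NULL,
                 window_size = 11, window_sigma = 1.5) {
  check_pair(slice, ref_slice)
  L <- dynamic_range %||% diff(range(ref_slice))
  if (!is.finite(L) || L <= 0) {
    moqam_abort("SSIM dynamic range must be positive", "moqam_degenerate_error")
  }
  w <- gaussian_kernel(window_size, window_sigma)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  f <- function(m) conv2_valid(m, w)
  mu1 <- f(slice); mu2 <- f(ref_slice)
  v1 <- f(slice^2) - mu1^2
  v2 <- f(ref_slice^2) - mu2^2
  cv <- f(slice * ref_slice) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
  if (!is.null(domain)) {
    b <- (window_size - 1) / 2
    dc <- domain[(b + 1):(nrow(domain) - b), (b + 1):(ncol(domain) - b)]
    if (!any(dc)) {
      rlang::warn("no evaluation-domain pixels with fully interior windows; SSIM is NA")
      return(NA_real_)
    }
    return(mean(map[dc]))
  }
  mean(map)
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' `10 * log10(max(ref)^2 / MSE)` in decibels, with the peak term taken as
#' the maximum of the reference slice over the evaluation domain (not a
#' fixed nominal dynamic range). Identical inputs give `+Inf` with a
#' warning.
#'
#' @inheritParams ssim
#' @return Scalar in dB (`+Inf` for identical slices).
#' @export
psnr <- function(slice, ref_slice, domain = NULL) {
  check_pair(slice, ref_slice)
  rv <- domain_values(ref_slice, domain)
  peak <- max(rv)
  if (all(rv == 0)) {
    moqam_abort("reference slice is all zero over the domain; PSNR undefined",
                "moqam_degenerate_error")
  }
  mse <- mean((domain_values(slice, domain) - rv)^2)
  if (mse == 0) {
    rlang::warn("identical slices: PSNR is +Inf")
    return(Inf)
  }
  10 * log10(peak^2 / mse)
}

# ---- phase congruency (log-Gabor filter bank) --------------------------

# Monogenic-style 2D phase congruency with 4 scales x 4 orientations of
# log-Gabor filters, phase-deviation energy, frequency-spread weighting and
# a noise threshold estimated from the smallest-scale filter response
# (Rayleigh model). Returns a per-pixel map in [0, 1].
phase_congruency <- function(im, nscale = 4, norient = 4, min_wavelength = 6,
                             mult = 2, sigma_onf = 0.55, k = 2,
                             cutoff = 0.5, g = 10, epsilon = 1e-4) {
  nr <- nrow(im); nc <- ncol(im)
  fx <- (seq_len(nc) - 1 - floor(nc / 2)) / nc
  fy <- (seq_len(nr) - 1 - floor(nr / 2)) / nr
  ux <- matrix(fx, nr, nc, byrow = TRUE)
  uy <- matrix(fy, nr, nc)
  ishift <- function(m) {
    ri <- c((floor(nr / 2) + 1):nr, 1:floor(nr / 2))
    ci <- c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))
    m[ri, ci]
  }
  ux <- ishift(ux); uy <- ishift(uy)
  radius <- sqrt(ux^2 + uy^2)
  radius[1, 1] <- 1
  theta <- atan2(-uy, ux)
  sintheta <- sin(theta); costheta <- cos(theta)
  lp <- 1 / (1 + (radius / 0.45)^30)  # low-pass to suppress corner frequencies

  log_gabor <- lapply(seq_len(nscale), function(s) {
    fo <- 1 / (min_wavelength * mult^(s - 1))
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigma_onf)^2)) * lp
    lg[1, 1] <- 0
    lg
  })
  theta_sigma <- pi / norient / 1.2
  IM <- fft(im)
  total_energy <- matrix(0, nr, nc)
  total_sum_an <- matrix(0, nr, nc)
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    eo <- vector("list", nscale)
    sum_e <- sum_o <- sum_an <- matrix(0, nr, nc)
    max_an <- NULL; tau <- NULL
    for (s in seq_len(nscale)) {
      filt <- log_gabor[[s]] * spread
      eo[[s]] <- fft(IM * filt, inverse = TRUE) / (nr * nc)
      an <- Mod(eo[[s]])
      sum_an <- sum_an + an
      sum_e <- sum_e + Re(eo[[s]])
      sum_o <- sum_o + Im(eo[[s]])
      if (s == 1) {
        tau <- median(an) / sqrt(log(4))
        max_an <- an
      } else {
        max_an <- pmax(max_an, an)
      }
    }
    x_energy <- sqrt(sum_e^2 + sum_o^2) + epsilon
    mean_e <- sum_e / x_energy
    mean_o <- sum_o / x_energy
    energy <- matrix(0, nr, nc)
    for (s in seq_len(nscale)) {
      re <- Re(eo[[s]]); io <- Im(eo[[s]])
      energy <- energy + re * mean_e + io * mean_o - abs(re * mean_o - io * mean_e)
    }
    # Rayleigh-model noise threshold from the smallest-scale response
    total_tau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sigma <- total_tau * sqrt((4 - pi) / 2)
    t_noise <- (noise_mean + k * noise_sigma) / 1.7
    energy <- pmax(energy - t_noise, 0)
    width <- (sum_an / (max_an + epsilon) - 1) / (nscale - 1)
    weight <- 1 / (1 + exp(g * (cutoff - width)))
    total_energy <- total_energy + weight * energy
    total_sum_an <- total_sum_an + sum_an
  }
  total_energy / (total_sum_an + epsilon)
}

scharr_gradient <- function(m) {
  kx <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), 3, 3, byrow = TRUE) / 16
  gx <- filt2(m, t(kx))
  gy <- filt2(m, kx)
  sqrt(gx^2 + gy^2)
}

# average-pool by integer factor f, truncating trailing pixels
down_pool <- function(m, f) {
  if (f <= 1) return(m)
  nr <- floor(nrow(m) / f) * f
  nc <- floor(ncol(m) / f) * f
  m <- m[seq_len(nr), seq_len(nc)]
  ri <- rep(seq_len(nr / f), each = f)
  ci <- rep(seq_len(nc / f), each = f)
  t(rowsum(t(rowsum(m, ri)), ci)) / f^2
}

fsim_range_check <- function(slice, ref_slice) {
  lo <- min(slice, ref_slice); hi <- max(slice, ref_slice)
  if (lo < -1e-9 || hi > 255 + 1e-6) {
    moqam_abort(
      "inputs must lie in [0, 1] or [0, 255]; normalize with min-max or percentile first",
      "moqam_availability_error")
  }
  # [0, 1] convention is mapped to [0, 255] so the standard constants apply
  if (hi <= 1 + 1e-9) 255 else 1
}

#' Feature similarity index (FSIM)
#'
#' Image similarity from the phase congruency of the frequency
#' representation (which responds to sharp light-dark transitions perceived
#' as edges) combined with gradient-magnitude similarity for contrast
#' invariance. Per-pixel similarities of the two maps are multiplied and
#' averaged with phase-congruency weighting. Ranges from 0 to 1, with 1
#' for identical images.
#'
#' Phase congruency uses a log-Gabor bank (4 scales, 4 orientations);
#' gradients use the Scharr operator; stability constants are the standard
#' `T1 = 0.85`, `T2 = 160` on the `[0, 255]` intensity convention (inputs
#' on `[0, 1]` are rescaled internally).
#'
#' @param slice,ref_slice 2D matrices in `[0, 1]` or `[0, 255]`.
#' @return Scalar in `[0, 1]`.
#' @export
fsim <- function(slice, ref_slice) {
  check_pair(slice, ref_slice)
  sc <- fsim_range_check(slice, ref_slice)
  x <- slice * sc
  y <- ref_slice * sc
  f <- max(1, round(min(dim(x)) / 256))
  x <- down_pool(x, f); y <- down_pool(y, f)
  pc1 <- phase_congruency(x)
  pc2 <- phase_congruency(y)
  g1 <- scharr_gradient(x)
  g2 <- scharr_gradient(y)
  t1 <- 0.85; t2 <- 160
  s_pc <- (2 * pc1 * pc2 + t1) / (pc1^2 + pc2^2 + t1)
  s_g <- (2 * g1 * g2 + t2) / (g1^2 + g2^2 + t2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

#' Visual information fidelity (VIF)
#'
#' Ratio of the mutual information the distorted image conveys about the
#' (Gaussian-scale-mixture modelled) source to the information the
#' reference conveys, accumulated over four scales of a Gaussian pyramid
#' in the pixel domain with an additive-noise channel model (variance
#' floor `sigma_nsq`). Equals 1 for identical images and exceeds 1 when
#' the test image carries more information than the reference (e.g. a
#' clean image scored against a noisy reference).
#'
#' @param slice,ref_slice 2D matrices in `[0, 1]` or `[0, 255]`; `slice`
#'   is the image under test, `ref_slice` the reference.
#' @param sigma_nsq Visual-noise variance on the `[0, 255]` convention
#'   (default 2).
#' @return Nonnegative scalar.
#' @export
vif <- function(slice, ref_slice, sigma_nsq = 2) {
  check_pair(slice, ref_slice)
  sc <- fsim_range_check(slice, ref_slice)
  dist <- slice * sc
  ref <- ref_slice * sc
  if (sd(ref) == 0) {
    moqam_abort("zero-variance reference; VIF undefined", "moqam_degenerate_error")
  }
  eps <- 1e-10
  num <- den <- 0
  for (scale in 1:4) {
    n <- 2^(4 - scale + 1) + 1
    win <- gaussian_kernel(n, n / 5)
    if (scale > 1) {
      ref <- conv2_valid(ref, win)
      dist <- conv2_valid(dist, win)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2)]
      dist <- dist[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2)]
    }
    if (min(dim(ref)) < n) break
    f <- function(m) conv2_valid(m, win)
    mu1 <- f(ref); mu2 <- f(dist)
    s1 <- pmax(f(ref^2) - mu1^2, 0)
    s2 <- pmax(f(dist^2) - mu2^2, 0)
    s12 <- f(ref * dist) - mu1 * mu2
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0
    sv[s1 < eps] <- s2[s1 < eps]
    s1[s1 < eps] <- 0
    g[s2 < eps] <- 0
    sv[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]
    g[g < 0] <- 0
    sv[sv <= eps] <- eps
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  if (den == 0) {
    moqam_abort("reference carries no information at any scale; VIF undefined",
                "moqam_degenerate_error")
  }
  num / den
}

# ---- perceptual feature distance ---------------------------------------

#' Bundled deterministic convolutional feature extractor
#'
#' A small random-weight convolutional network (Gaussian `He`-scaled
#' weights drawn from `seed`, ReLU activations, 2x2 mean pooling) whose
#' multi-layer feature maps drive [perceptual_distance()]. Random deep
#' features are a recognized basis for perceptual distances; the extractor
#' is fully reproducible from its seed and requires no weight download.
#' Values are on the extractor's own scale and are not comparable to
#' published LPIPS numbers from pretrained AlexNet/VGG backbones (which
#' can be plugged in through the same interface).
#'
#' @param seed Integer seed for the weights.
#' @param channels Output channels per layer.
#' @param kernel_size Square kernel size.
#' @return An object of class `feature_extractor` with fields `weights`,
#'   `descriptor` and `seed`.
#' @export
feature_extractor <- function(seed = 0, channels = c(8, 16, 32), kernel_size = 3) {
  seeds <- split_seed(seed, length(channels))
  in_ch <- c(1, channels[-length(channels)])
  weights <- purrr::map(seq_along(channels), function(l) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seeds[l])
    fan_in <- kernel_size^2 * in_ch[l]
    array(rnorm(kernel_size^2 * in_ch[l] * channels[l]) * sqrt(2 / fan_in),
          dim = c(kernel_size, kernel_size, in_ch[l], channels[l]))
  })
  structure(list(weights = weights,
                 descriptor = sprintf("moqam-randcnn/seed=%d/ch=%s/k=%d", seed,
                                      paste(channels, collapse = "-"), kernel_size),
                 seed = seed),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor> %s (%d layers)\n", x$descriptor,
              length(x$weights)))
  invisible(x)
}

#' Extract multi-layer feature maps from a slice
#'
#' @param extractor A [feature_extractor()].
#' @param slice 2D numeric matrix.
#' @return List of 3D arrays (height x width x channels), one per layer.
#' @export
extract_features <- function(extractor, slice) {
  stopifnot(inherits(extractor, "feature_extractor"))
  act <- array(slice, dim = c(dim(slice), 1))
  out <- vector("list", length(extractor$weights))
  for (l in seq_along(extractor$weights)) {
    w <- extractor$weights[[l]]
    kd <- dim(w)[1]
    oh <- dim(act)[1] - kd + 1
    ow <- dim(act)[2] - kd + 1
    if (oh < 2 || ow < 2) {
      moqam_abort("slice too small for the feature extractor", "moqam_input_error")
    }
    nxt <- array(0, dim = c(oh, ow, dim(w)[4]))
    for (oc in seq_len(dim(w)[4])) {
      acc <- matrix(0, oh, ow)
      for (ic in seq_len(dim(w)[3])) {
        acc <- acc + conv2_valid(act[, , ic], w[, , ic, oc])
      }
      nxt[, , oc] <- pmax(acc, 0)  # ReLU
    }
    # 2x2 mean pooling
    ph <- floor(dim(nxt)[1] / 2); pw <- floor(dim(nxt)[2] / 2)
    pooled <- array(0, dim = c(ph, pw, dim(nxt)[3]))
    for (oc in seq_len(dim(nxt)[3])) {
      pooled[, , oc] <- down_pool(nxt[, , oc], 2)
    }
    out[[l]] <- pooled
    act <- pooled
  }
  out
}

#' Perceptual feature distance
#'
#' LPIPS-style distance: feature maps from each layer of the extractor are
#' unit-normalized across channels at every pixel, squared differences are
#' averaged over pixels and channels, and layer contributions are summed.
#' 0 for identical images, increasing with decreasing similarity.
#'
#' @param slice,ref_slice 2D matrices on `[-1, 1]` (use
#'   [rescale_for_metric()]).
#' @param extractor A [feature_extractor()]; default seed 0.
#' @return Nonnegative scalar.
#' @export
perceptual_distance <- function(slice, ref_slice,
                                extractor = feature_extractor()) {
  check_pair(slice, ref_slice)
  f1 <- extract_features(extractor, slice)
  f2 <- extract_features(extractor, ref_slice)
  eps <- 1e-10
  unitnorm <- function(f) {
    nrm <- sqrt(apply(f^2, c(1, 2), sum)) + eps
    f / array(nrm, dim = dim(f))
  }
  total <- 0
  for (l in seq_along(f1)) {
    d <- unitnorm(f1[[l]]) - unitnorm(f2[[l]])
    total <- total + mean(apply(d^2, c(1, 2), mean))
  }
  total
}
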