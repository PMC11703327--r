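# Synthetic study generation: brain-like phantoms, graded corruption
# (k-space motion ghosting, Gaussian noise, Gaussian blur) and simulated
# multi-rater Likert scores, so the full evaluation study runs with no
# external data. Every operation is a pure function of (inputs, seed); all
# randomness in a study flows from one master seed via drawn sub-seeds.

#' Generate a brain-like phantom volume and its brain mask
#'
#' An ellipsoidal head with a bright skull rim, an internal brain
#' compartment (the mask), nested structures (ventricles, deep-gray blobs)
#' and smooth random texture, on a zero background. The head is placed
#' centrally, so peripheral slices carry little or no brain and the 10%
#' brain-voxel slice filter excludes them; the background occupies the
#' majority of voxels, as in real skull-stripped brain acquisitions.
#'
#' @param shape Grid dimensions, each at least 32 (default `c(64, 64, 32)`).
#' @param seed Integer seed for the texture and structure jitter.
#' @param spacing Voxel size in mm.
#' @param id Identifier for the volume (mask gets `<id>-mask`).
#' @return List with elements `volume` ([image_volume()]) and `mask`
#'   ([brain_mask()]).
#' @export
make_phantom <- function(shape = c(64, 64, 32), seed = 0,
                         spacing = c(3, 3, 4), id = "phantom") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L)) {
    moqam_abort("phantom shape must have three dimensions of at least 32",
                "moqam_input_error")
  }
  seeds <- split_seed(seed, 2)
  # normalized coordinates in [-1, 1] per axis
  cx <- lapply(shape, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  X <- array(rep(cx[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(cx[[2]], each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(cx[[3]], each = shape[1] * shape[2]), shape)
  ell <- function(c0, semi) ((X - c0[1]) / semi[1])^2 +
    ((Y - c0[2]) / semi[2])^2 + ((Z - c0[3]) / semi[3])^2
  head_r <- sqrt(ell(c(0, 0, 0), c(0.82, 0.92, 0.78)))
  brain_r <- sqrt(ell(c(0, 0, 0), c(0.62, 0.72, 0.55)))
  vol <- array(0, shape)
  vol[head_r <= 1] <- 60                         # scalp/CSF band
  vol[head_r <= 1 & head_r > 0.88] <- 220        # bright skull rim
  brain <- brain_r <= 1
  vol[brain] <- 110                              # brain parenchyma
  # cortical band slightly brighter than deep tissue
  vol[brain & brain_r > 0.8] <- 130
  # ventricles: two dark ellipsoids
  lv <- ell(c(-0.16, 0.05, 0), c(0.10, 0.26, 0.16)) <= 1 |
    ell(c(0.16, 0.05, 0), c(0.10, 0.26, 0.16)) <= 1
  vol[lv & brain] <- 30
  # deep gray blobs
  dg <- ell(c(-0.3, -0.18, 0.05), c(0.13, 0.13, 0.14)) <= 1 |
    ell(c(0.3, -0.18, 0.05), c(0.13, 0.13, 0.14)) <= 1 |
    ell(c(0, 0.42, -0.05), c(0.16, 0.14, 0.15)) <= 1
  vol[dg & brain] <- 150
  # smooth random texture inside the head only
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seeds[1])
  tex <- gauss_smooth_3d(array(rnorm(prod(shape)), shape), 1.5)
  tex <- tex / sd(tex)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  vol[head_r <= 1] <- vol[head_r <= 1] + 12 * tex[head_r <= 1]
  vol <- pmax(vol, 0)
  list(volume = image_volume(vol, spacing = spacing, id = id),
       mask = brain_mask(brain, id = paste0(id, "-mask")))
}

#' Specify a corruption to apply to a volume
#'
#' @param kind `"motion"` (k-space inconsistency ghosting from discrete
#'   rigid movement events), `"noise"` (additive Gaussian) or `"blur"`
#'   (Gaussian smoothing).
#' @param severity Nonnegative severity; 0 reproduces the input
#'   bit-exactly. Severity 1 corresponds to the per-kind unit amounts
#'   below.
#' @param seed Integer seed.
#' @param n_events Movement events per unit severity (motion).
#' @param max_rotation_deg In-plane rotation per unit severity, degrees.
#' @param max_translation_mm In-plane translation per unit severity, mm.
#' @param noise_sigma_rel Gaussian sigma per unit severity, relative to the
#'   intensity range (noise).
#' @param blur_sigma_vox Gaussian sigma per unit severity, voxels (blur).
#' @return Object of class `corruption_spec`.
#' @export
corruption_spec <- function(kind = c("motion", "noise", "blur"), severity = 1,
                            seed = 0, n_events = 3, max_rotation_deg = 3,
                            max_translation_mm = 3, noise_sigma_rel = 0.05,
                            blur_sigma_vox = 1) {
  kind <- match.arg(kind)
  if (severity < 0) moqam_abort("severity must be nonnegative", "moqam_input_error")
  structure(list(kind = kind, severity = severity, seed = seed,
                 n_events = n_events, max_rotation_deg = max_rotation_deg,
                 max_translation_mm = max_translation_mm,
                 noise_sigma_rel = noise_sigma_rel,
                 blur_sigma_vox = blur_sigma_vox),
            class = "corruption_spec")
}

# In-plane rigid resampling of every slice: rotation (degrees, about the
# slice centre) plus translation (voxels), bilinear interpolation,
# zero fill outside.
rigid_inplane <- function(arr, angle_deg, shift_vox) {
  d <- dim(arr)
  th <- angle_deg * pi / 180
  ci <- (d[1] + 1) / 2; cj <- (d[2] + 1) / 2
  I <- matrix(seq_len(d[1]), d[1], d[2]) - ci
  J <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cj
  # inverse mapping: source coords for each target pixel
  si <- cos(th) * I + sin(th) * J - shift_vox[1] + ci
  sj <- -sin(th) * I + cos(th) * J - shift_vox[2] + cj
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  ok <- i0 >= 1 & i0 < d[1] & j0 >= 1 & j0 < d[2]
  out <- array(0, d)
  idx <- function(ii, jj, k) cbind(ii[ok], jj[ok], k)
  for (k in seq_len(d[3])) {
    sl <- matrix(0, d[1], d[2])
    v00 <- arr[idx(i0, j0, k)]
    v10 <- arr[idx(i0 + 1, j0, k)]
    v01 <- arr[idx(i0, j0 + 1, k)]
    v11 <- arr[idx(i0 + 1, j0 + 1, k)]
    sl[ok] <- v00 * (1 - fi[ok]) * (1 - fj[ok]) + v10 * fi[ok] * (1 - fj[ok]) +
      v01 * (1 - fi[ok]) * fj[ok] + v11 * fi[ok] * fj[ok]
    out[, , k] <- sl
  }
  out
}

# slice-wise 2D FFT along the third axis
fft_slices <- function(arr, inverse = FALSE) {
  d <- dim(arr)
  out <- array(complex(real = 0), d)
  for (k in seq_len(d[3])) {
    f <- fft(arr[, , k], inverse = inverse)
    out[, , k] <- if (inverse) f / (d[1] * d[2]) else f
  }
  out
}

#' Corrupt a volume with graded motion, noise or blur
#'
#' Motion emulates rigid-motion k-space inconsistency: discrete movement
#' events assign contiguous phase-encode segments (first in-plane axis) of
#' each slice's k-space the signal of a rotated/translated object,
#' producing the ghosting/ringing artifacts characteristic of head motion.
#' The first segment always carries the unmoved object. Output is the
#' magnitude image (nonnegative). Noise adds Gaussian noise (sigma
#' proportional to severity and intensity range); blur applies 3D Gaussian
#' smoothing.
#'
#' @param vol An [image_volume()].
#' @param spec A [corruption_spec()]; `severity = 0` returns `vol`
#'   unchanged, bit-exactly.
#' @return Corrupted [image_volume()] (id suffixed with the kind and
#'   severity).
#' @export
corrupt <- function(vol, spec) {
  stopifnot(inherits(vol, "image_volume"), inherits(spec, "corruption_spec"))
  if (spec$severity == 0) return(vol)
  out_id <- sprintf("%s_%s-%g", vol$id, spec$kind, spec$severity)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  x <- vol$data
  data <- switch(spec$kind,
    noise = {
      sdv <- spec$severity * spec$noise_sigma_rel * diff(range(x))
      abs(x + array(rnorm(length(x), sd = sdv), dim(x)))
    },
    blur = gauss_smooth_3d(x, spec$severity * spec$blur_sigma_vox),
    motion = {
      d <- dim(x)
      # a fixed motion trajectory whose amplitude scales with severity:
      # the same seed yields the same event pattern at every severity
      n_ev <- max(1L, round(spec$n_events))
      rot <- runif(n_ev, -1, 1) * spec$max_rotation_deg * spec$severity
      shift_mm <- matrix(runif(2 * n_ev, -1, 1), n_ev, 2) *
        spec$max_translation_mm * spec$severity
      shift_vox <- sweep(shift_mm, 2, vol$spacing[1:2], "/")
      # event onsets along the phase-encode axis (axis 1); line 1 (the DC
      # row in unshifted FFT order) always carries the unmoved object
      onsets <- sort(sample(2:d[1], n_ev))
      ks <- fft_slices(x)
      for (e in seq_len(n_ev)) {
        moved <- rigid_inplane(x, rot[e], shift_vox[e, ])
        km <- fft_slices(moved)
        # contiguous phase-encode segment acquired after event e
        from <- onsets[e]
        to <- if (e < n_ev) onsets[e + 1] - 1L else d[1]
        ks[from:to, , ] <- km[from:to, , ]
      }
      Mod(fft_slices(ks, inverse = TRUE))
    })
  image_volume(data, spacing = vol$spacing, id = out_id, header = vol$header)
}

#' Simulate a multi-rater Likert score table
#'
#' Latent quality `q = 5 - slope * severity`, clipped to `[1, 5]`; each
#' rater observes `q` plus zero-mean Gaussian noise (radiographers with
#' twice the radiologist noise, reflecting less reading experience),
#' rounded to the 1-5 Likert grid. Radiologists carry weight 2 and
#' radiographers weight 1 for [fuse_scores()]. Scores correlate negatively
#' with severity by construction.
#'
#' @param severities Nonnegative severities, one per image; names become
#'   image ids (default `img-<i>`).
#' @param n_radiologists,n_radiographers Panel composition (default 2 + 2).
#' @param noise_sd Radiologist score noise SD (radiographers get twice
#'   this); 0 gives perfectly agreeing raters.
#' @param seed Integer seed.
#' @param slope Latent quality loss per unit severity (default 2, so the
#'   default severity ladder 0/0.5/1/2 spans scores 5 down to 1).
#' @return A [rater_table()].
#' @export
simulate_raters <- function(severities, n_radiologists = 2, n_radiographers = 2,
                            noise_sd = 0.35, seed = 0, slope = 2) {
  if (any(severities < 0) || noise_sd < 0) {
    moqam_abort("severities and noise_sd must be nonnegative", "moqam_input_error")
  }
  ids <- names(severities) %||% paste0("img-", seq_along(severities))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  q <- pmin(pmax(5 - slope * severities, 1), 5)
  n_r <- n_radiologists + n_radiographers
  sds <- c(rep(noise_sd, n_radiologists), rep(2 * noise_sd, n_radiographers))
  scores <- vapply(seq_len(n_r), function(r) {
    round(pmin(pmax(q + rnorm(length(q), sd = sds[r]), 1), 5))
  }, numeric(length(q)))
  scores <- matrix(scores, nrow = length(q),
                   dimnames = list(ids, c(
                     sprintf("radiologist%d", seq_len(n_radiologists)),
                     sprintf("radiographer%d", seq_len(n_radiographers)))))
  rater_table(scores, weights = c(rep(2, n_radiologists),
                                  rep(1, n_radiographers)))
}

#' Generate a complete synthetic evaluation study
#'
#' For each subject: one phantom reference, its brain mask, and one
#' motion-corrupted image per severity in the ladder (severity 0 is an
#' exact copy of the reference). Simulated raters score every image from
#' its severity. When `out_dir` is given, volumes and masks are written as
#' NIfTI, the manifest and rater tables as CSV, in the schemas consumed by
#' [evaluate_dataset()] and [correlate()]; regeneration from the same seed
#' is byte-identical.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param severities Severity ladder (default `c(0, 0.5, 1, 2)`).
#' @param seed Master seed; all sub-seeds are drawn from it.
#' @param shape Phantom grid (default `c(64, 64, 32)`).
#' @param kind Corruption kind (default `"motion"`).
#' @param noise_sd Rater noise, see [simulate_raters()].
#' @param out_dir Optional output directory.
#' @return Object of class `synthetic_study`: list with `manifest` (tibble:
#'   `image_id`, `subject`, `severity`, plus list-columns `image`,
#'   `reference`, `mask`, and path columns when written), `raters` (a
#'   [rater_table()]) and `seed`.
#' @export
generate_study <- function(n_subjects = 10, severities = c(0, 0.5, 1, 2),
                           seed = 0, shape = c(64, 64, 32), kind = "motion",
                           noise_sd = 0.35, out_dir = NULL) {
  if (n_subjects < 1) moqam_abort("n_subjects must be >= 1", "moqam_input_error")
  seeds <- split_seed(seed, 2 * n_subjects + 1)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sub_id <- sprintf("sub-%02d", s)
    ph <- make_phantom(shape = shape, seed = seeds[s], id = paste0(sub_id, "_ref"))
    for (v in seq_along(severities)) {
      sev <- severities[v]
      img_id <- sprintf("%s_sev-%g", sub_id, sev)
      # one motion trajectory per subject; severity scales its amplitude
      cvol <- corrupt(ph$volume,
                      corruption_spec(kind, severity = sev,
                                      seed = seeds[n_subjects + s]))
      cvol$id <- img_id
      rows[[length(rows) + 1]] <- tibble::tibble(
        image_id = img_id, subject = sub_id, severity = sev,
        image = list(cvol), reference = list(ph$volume), mask = list(ph$mask))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  sev_vec <- stats::setNames(manifest$severity, manifest$image_id)
  raters <- simulate_raters(sev_vec, noise_sd = noise_sd,
                            seed = seeds[2 * n_subjects + 1])
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      moqam_abort(sprintf("cannot create output directory %s", out_dir),
                  "moqam_io_error")
    }
    manifest$image_path <- file.path(out_dir, paste0(manifest$image_id, ".nii.gz"))
    manifest$reference_path <- file.path(
      out_dir, paste0(manifest$subject, "_ref.nii.gz"))
    manifest$mask_path <- file.path(
      out_dir, paste0(manifest$subject, "_mask.nii.gz"))
    for (i in seq_len(nrow(manifest))) {
      write_volume(manifest$image[[i]], manifest$image_path[i])
    }
    for (sub in unique(manifest$subject)) {
      i <- match(sub, manifest$subject)
      write_volume(manifest$reference[[i]], manifest$reference_path[i])
      write_mask(manifest$mask[[i]], manifest$mask_path[i],
                 spacing = manifest$reference[[i]]$spacing)
    }
    readr::write_csv(
      manifest[c("image_id", "subject", "severity",
                 "image_path", "reference_path", "mask_path")],
      file.path(out_dir, "manifest.csv"), progress = FALSE)
    write_rater_table(raters, file.path(out_dir, "raters.csv"))
  }
  structure(list(manifest = manifest, raters = raters, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d images (%d subjects x %d severities), seed %d\n",
              nrow(x$manifest), dplyr::n_distinct(x$manifest$subject),
              dplyr::n_distinct(x$manifest$severity), x$seed))
  invisible(x)
}
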