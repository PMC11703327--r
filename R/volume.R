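# Image volumes and brain masks: lightweight containers around 3D arrays
# with voxel spacing and (optional) NIfTI orientation metadata carried
# opaquely, plus NIfTI read/write via RNifti.

#' Create an image volume
#'
#' An `image_volume` is the unit of evaluation: a 3D scalar field of finite
#' intensities on a voxel grid, with per-axis voxel spacing in millimetres
#' and an identifier. Orientation metadata from a source NIfTI file, when
#' present, is carried along opaquely and restored on write.
#'
#' @param data 3D numeric array of finite intensities; every dimension must
#'   be at least 8 voxels for the slice-wise metrics to be meaningful.
#' @param spacing Numeric length-3, strictly positive voxel size in mm.
#' @param id Character identifier.
#' @param header Optional NIfTI header (as returned by
#'   [RNifti::niftiHeader()]) preserved across a write/read round trip.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), id = "volume", header = NULL) {
  data <- squeeze_to_3d(data, id)
  if (!all(is.finite(data))) {
    moqam_abort(sprintf("volume '%s' contains non-finite voxels", id),
                "moqam_input_error")
  }
  if (any(dim(data) < 8L)) {
    moqam_abort(sprintf("volume '%s' has a dimension below 8 voxels (%s)",
                        id, paste(dim(data), collapse = "x")),
                "moqam_input_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    moqam_abort("spacing must be three strictly positive voxel sizes (mm)",
                "moqam_input_error")
  }
  structure(list(data = data, spacing = spacing, id = id, header = header),
            class = "image_volume")
}

squeeze_to_3d <- function(data, id) {
  d <- dim(data)
  if (is.null(d) || length(d) < 3L) {
    moqam_abort(sprintf("'%s' must have at least 3 dimensions", id),
                "moqam_input_error")
  }
  if (length(d) > 3L) {
    if (any(d[-(1:3)] != 1L)) {
      moqam_abort(sprintf("'%s' is %dD with non-singleton trailing dimensions",
                          id, length(d)),
                  "moqam_input_error")
    }
    d <- d[1:3]
  }
  # plain double array: drop any reader-specific attributes
  array(as.double(data), d)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume '%s'> %s voxels, spacing %s mm\n", x$id,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Create a brain mask
#'
#' A binary volume on the same grid as the image it accompanies; it defines
#' the evaluation domain for masked metric computation. Input values are
#' binarized at 0.5 so interpolated masks from upstream registration are
#' tolerated.
#'
#' @param data 3D numeric/logical array.
#' @param id Character identifier.
#' @return An object of class `brain_mask`; `data` is a logical array.
#' @export
brain_mask <- function(data, id = "mask") {
  data <- squeeze_to_3d(data, id)
  bin <- data > 0.5
  if (!any(bin)) {
    moqam_abort(sprintf("mask '%s' has no nonzero voxels", id),
                "moqam_input_error")
  }
  structure(list(data = bin, id = id), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask '%s'> %s voxels, %d in mask (%.1f%%)\n", x$id,
              paste(dim(x$data), collapse = "x"), sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

#' @export
dim.brain_mask <- function(x) dim(x$data)

#' Read a volume from a NIfTI file
#'
#' Reads a NIfTI-1/2 image, squeezes singleton trailing dimensions (e.g. a
#' 4D file holding a single 3D volume) and validates that all voxels are
#' finite. Spacing and orientation metadata are preserved.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param id Identifier; defaults to the file name without extension.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path)) {
    moqam_abort(sprintf("file not found: %s", path), "moqam_input_error")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    moqam_abort(sprintf("cannot read NIfTI file %s: %s",
                                        path, conditionMessage(e)),
                                "moqam_input_error")
                  })
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  hdr <- RNifti::niftiHeader(img)
  spacing <- RNifti::pixdim(img)[1:3]
  vol <- tryCatch(
    image_volume(unclass(as.array(img)), spacing = spacing, id = id, header = hdr),
    error = function(e) {
      moqam_abort(sprintf("invalid volume in %s: %s", path, conditionMessage(e)),
                  "moqam_input_error")
    })
  vol
}

#' Write a volume to a NIfTI file
#'
#' @param vol An [image_volume()].
#' @param path Destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data, reference = vol$header)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a brain mask matched to a volume
#'
#' @param path Path to a NIfTI mask file.
#' @param volume The [image_volume()] the mask accompanies; shapes must match.
#' @return A [brain_mask()].
#' @export
read_mask <- function(path, volume) {
  stopifnot(inherits(volume, "image_volume"))
  m <- read_volume(path, id = sub("\\.nii(\\.gz)?$", "", basename(path)))
  if (!identical(dim(m$data), dim(volume$data))) {
    moqam_abort(sprintf(
      "mask %s shape (%s) does not match volume '%s' shape (%s)",
      path, paste(dim(m$data), collapse = "x"), volume$id,
      paste(dim(volume$data), collapse = "x")),
      "moqam_grid_error")
  }
  brain_mask(m$data, id = m$id)
}

#' Write a brain mask to a NIfTI file
#' @param mask A [brain_mask()].
#' @param path Destination path.
#' @param spacing Voxel spacing to record, in mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(mask, "brain_mask"))
  img <- RNifti::asNifti(array(as.double(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
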