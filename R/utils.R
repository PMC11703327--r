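# Internal numeric helpers shared across metric implementations.

#' @importFrom stats quantile rnorm sd median fft
#' @importFrom rlang abort warn .data %||%
NULL

moqam_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "moqam_error"))
}

#' 2D Gaussian kernel
#' @noRd
gaussian_kernel <- function(size, sigma) {
  stopifnot(size %% 2 == 1, sigma > 0)
  r <- (size - 1) / 2
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Replicate-pad a matrix by `p` pixels on every side
#' @noRd
pad_replicate <- function(m, p) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- c(rep(1L, p), seq_len(n1), rep(n1, p))
  ci <- c(rep(1L, p), seq_len(n2), rep(n2, p))
  m[ri, ci, drop = FALSE]
}

#' Exact "valid"-shape 2D convolution by kernel shift-and-add
#'
#' True convolution (kernel flipped); exact summation, no FFT round-off,
#' fast for the small kernels used throughout (3x3 to 17x17).
#' @noRd
conv2_valid <- function(m, k) {
  ka <- nrow(k); kb <- ncol(k)
  or_ <- nrow(m) - ka + 1L
  oc <- ncol(m) - kb + 1L
  if (or_ < 1 || oc < 1) {
    moqam_abort("kernel larger than image in convolution", "moqam_input_error")
  }
  kf <- k[ka:1, kb:1, drop = FALSE]
  out <- matrix(0, or_, oc)
  for (a in seq_len(ka)) {
    for (b in seq_len(kb)) {
      if (kf[a, b] != 0) {
        out <- out + kf[a, b] * m[a:(a + or_ - 1L), b:(b + oc - 1L)]
      }
    }
  }
  out
}

#' Same-size 2D filtering with replicate boundary handling
#'
#' All kernels used here are either symmetric or consumed through the
#' gradient magnitude, where the convolution flip is immaterial.
#' @noRd
filt2 <- function(m, k) {
  p <- (nrow(k) - 1) / 2
  conv2_valid(pad_replicate(m, p), k)
}

#' Separable 3D Gaussian smoothing (replicate boundaries)
#' @noRd
gauss_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    a <- aperm(a, c(axis, setdiff(1:3, axis)))
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    idx <- c(rep(1L, r), seq_len(d[1]), rep(d[1], r))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, d[1], ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[j:(j + d[1] - 1L), , drop = FALSE]
    }
    a <- array(out, d)
    aperm(a, order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

#' Extract a 2D slice from a 3D array along an axis
#' @noRd
take_slice <- function(arr, index, axis = 3L) {
  switch(axis,
         `1` = arr[index, , ],
         `2` = arr[, index, ],
         `3` = arr[, , index])
}

n_slices_along <- function(arr, axis = 3L) dim(arr)[axis]

#' Draw reproducible sub-seeds from a master seed without disturbing
#' the caller's RNG stream more than once
#' @noRd
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
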