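# Reference-free sharpness/entropy metrics: Tenengrad (TG), average edge
# strength (AES), normalized gradient squared (NGS), image entropy (IE)
# and gradient entropy (GE), plus the shared gradient and edge operators.
# All are computed slice-wise over an evaluation domain (full slice or
# mask-positive pixels).

domain_values <- function(m, domain = NULL) {
  if (is.null(domain)) as.vector(m) else m[domain]
}

#' Gradient magnitude of a slice
#'
#' `g = sqrt(gx^2 + gy^2)` with the chosen difference operator. The Sobel
#' kernels are normalized (divided by 8) so a unit-slope intensity ramp has
#' unit gradient magnitude, matching central differences.
#'
#' @param slice 2D numeric matrix, at least 3x3.
#' @param operator `"sobel"` (default) or `"central"` differences.
#' @return Matrix of nonnegative gradient magnitudes, same shape as
#'   `slice`, with attribute `operator`.
#' @export
gradient_magnitude <- function(slice, operator = c("sobel", "central")) {
  operator <- match.arg(operator)
  if (nrow(slice) < 3 || ncol(slice) < 3) {
    moqam_abort("slice must be at least 3x3 for gradients", "moqam_input_error")
  }
  if (operator == "sobel") {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  } else {
    kx <- matrix(c(0, 0, 0, -0.5, 0, 0.5, 0, 0, 0), 3, 3, byrow = TRUE)
  }
  # kx differentiates along columns (j); its transpose along rows (i)
  gx <- filt2(slice, t(kx))
  gy <- filt2(slice, kx)
  g <- sqrt(gx^2 + gy^2)
  attr(g, "operator") <- operator
  g
}

#' Detect edges with a Canny-style detector
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, then hysteresis with thresholds at the
#' given percentiles of the positive gradient magnitudes.
#'
#' @param slice 2D numeric matrix.
#' @param sigma Smoothing standard deviation in pixels (default 1).
#' @param percentiles Hysteresis thresholds as percentiles of the nonzero
#'   gradient magnitudes (default `c(70, 90)`).
#' @return Logical matrix of edge pixels.
#' @export
detect_edges <- function(slice, sigma = 1, percentiles = c(70, 90)) {
  k <- gaussian_kernel(2 * ceiling(3 * sigma) + 1, sigma)
  sm <- filt2(slice, k)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  gx <- filt2(sm, t(kx))
  gy <- filt2(sm, kx)
  g <- sqrt(gx^2 + gy^2)
  pos <- g[g > 0]
  if (length(pos) == 0) return(matrix(FALSE, nrow(slice), ncol(slice)))
  th <- quantile(pos, probs = percentiles / 100, names = FALSE)
  # non-maximum suppression: compare with the two neighbours along the
  # gradient direction, quantized to 0/45/90/135 degrees
  ang <- atan2(gy, gx) %% pi
  sector <- (floor(ang / (pi / 4) + 0.5)) %% 4
  n1 <- nrow(g); n2 <- ncol(g)
  gp <- matrix(0, n1 + 2, n2 + 2)
  gp[2:(n1 + 1), 2:(n2 + 1)] <- g
  shift <- function(di, dj) gp[2:(n1 + 1) + di, 2:(n2 + 1) + dj]
  # sector 0: gradient along i (rows); 2: along j; 1/3 diagonals
  nb <- list(`0` = list(shift(-1, 0), shift(1, 0)),
             `1` = list(shift(-1, 1), shift(1, -1)),
             `2` = list(shift(0, -1), shift(0, 1)),
             `3` = list(shift(-1, -1), shift(1, 1)))
  keep <- matrix(FALSE, n1, n2)
  for (s in 0:3) {
    sel <- sector == s
    pair <- nb[[as.character(s)]]
    keep[sel] <- g[sel] >= pair[[1]][sel] & g[sel] >= pair[[2]][sel]
  }
  strong <- keep & g >= th[2]
  weak <- keep & g >= th[1]
  # hysteresis: grow strong edges through weak pixels (8-connectivity)
  edges <- strong
  repeat {
    ep <- matrix(FALSE, n1 + 2, n2 + 2)
    ep[2:(n1 + 1), 2:(n2 + 1)] <- edges
    dil <- ep[1:n1, 2:(n2 + 1)] | ep[3:(n1 + 2), 2:(n2 + 1)] |
      ep[2:(n1 + 1), 1:n2] | ep[2:(n1 + 1), 3:(n2 + 2)] |
      ep[1:n1, 1:n2] | ep[1:n1, 3:(n2 + 2)] |
      ep[3:(n1 + 2), 1:n2] | ep[3:(n1 + 2), 3:(n2 + 2)]
    grown <- edges | (weak & dil)
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

#' Tenengrad sharpness
#'
#' Mean squared gradient magnitude over the evaluation domain; larger
#' values indicate sharper images with more prominent edges.
#'
#' @param slice 2D numeric matrix.
#' @param domain Optional logical matrix restricting the evaluation domain.
#' @param operator Gradient operator, see [gradient_magnitude()].
#' @return Nonnegative scalar.
#' @export
tenengrad <- function(slice, domain = NULL, operator = "sobel") {
  g <- gradient_magnitude(slice, operator)
  mean(domain_values(g^2, domain))
}

#' Average edge strength
#'
#' Mean squared gradient magnitude restricted to detected edge pixels
#' within the evaluation domain. When no edges are detected (e.g. a
#' constant slice) the result is `NA` with a warning — degenerate slices
#' are skipped during reduction, never silently zero.
#'
#' @inheritParams tenengrad
#' @param edge_sigma,edge_percentiles Edge-detector parameters, see
#'   [detect_edges()].
#' @return Nonnegative scalar or `NA`.
#' @export
avg_edge_strength <- function(slice, domain = NULL, operator = "sobel",
                              edge_sigma = 1, edge_percentiles = c(70, 90)) {
  g <- gradient_magnitude(slice, operator)
  e <- detect_edges(slice, sigma = edge_sigma, percentiles = edge_percentiles)
  if (!is.null(domain)) e <- e & domain
  if (!any(e)) {
    rlang::warn("no edge pixels detected; average edge strength is NA")
    return(NA_real_)
  }
  mean(g[e]^2)
}

#' Normalized gradient squared
#'
#' Gradient magnitudes are normalized by their sum over the evaluation
#' domain and the squares summed: `sum((g / sum(g))^2)`. Invariant to
#' positive intensity scaling; equals `1/N` for `N` equal gradients.
#'
#' @inheritParams tenengrad
#' @return Nonnegative scalar or `NA` when the total gradient is zero.
#' @export
ngs <- function(slice, domain = NULL, operator = "sobel") {
  g <- domain_values(gradient_magnitude(slice, operator), domain)
  s <- sum(g)
  if (s <= 0) {
    rlang::warn("zero total gradient; normalized gradient squared is NA")
    return(NA_real_)
  }
  sum((g / s)^2)
}

# Shannon-type entropy of root-energy-normalized values:
# -sum(y * ln y) with y = x / sqrt(sum(x^2)), 0*ln(0) := 0.
root_energy_entropy <- function(x) {
  e <- sum(x^2)
  if (e <= 0) return(NA_real_)
  y <- x / sqrt(e)
  y <- y[y > 0]
  -sum(y * log(y))
}

#' Image entropy
#'
#' Entropy of root-energy-normalized pixel intensities
#' (`y = x / sqrt(sum(x^2))`). Lower values indicate more ordered
#' intensities, typically associated with higher quality. Intensities must
#' be nonnegative; after mean-std normalization (which creates negatives)
#' the absolute value is used.
#'
#' @inheritParams tenengrad
#' @return Nonnegative scalar or `NA` for an all-zero domain.
#' @export
image_entropy <- function(slice, domain = NULL) {
  x <- abs(domain_values(slice, domain))
  h <- root_energy_entropy(x)
  if (is.na(h)) rlang::warn("all-zero domain; image entropy is NA")
  h
}

#' Gradient entropy
#'
#' Entropy of root-energy-normalized gradient magnitudes
#' (`z = g / sqrt(sum(g^2))`). Lower values indicate more structured,
#' concentrated edges.
#'
#' @inheritParams tenengrad
#' @return Nonnegative scalar or `NA` for a zero-gradient domain.
#' @export
gradient_entropy <- function(slice, domain = NULL, operator = "sobel") {
  g <- domain_values(gradient_magnitude(slice, operator), domain)
  h <- root_energy_entropy(g)
  if (is.na(h)) rlang::warn("zero-gradient domain; gradient entropy is NA")
  h
}
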