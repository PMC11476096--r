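#' Convert RGB planes to grayscale
#'
#' Pixel-wise weighted sum of the three channels. The default weights are
#' the BT.601 luma coefficients (0.299, 0.587, 0.114), the convention used
#' by most numerical environments' `rgb2gray`.
#'
#' @param r,g,b Equal-shaped numeric matrices, or pass an `rgb_planes`
#'   object (as returned by [load_image()]) as `r` and omit `g`, `b`.
#' @param weights Length-3 non-negative weights summing to 1.
#' @return A `gray_image` with provenance `"raw"`.
#' @examples
#' gray <- to_grayscale(matrix(255, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4))
#' gray[1, 1] # 0.299 * 255
#' @export
to_grayscale <- function(r, g = NULL, b = NULL,
                         weights = c(0.299, 0.587, 0.114)) {
  if (inherits(r, "rgb_planes")) {
    g <- r$g; b <- r$b; r <- r$r
  }
  if (is.null(g) || is.null(b)) input_error("need all three channel planes")
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b))) {
    dimension_error(sprintf(
      "channel shapes differ: %s vs %s vs %s",
      paste(dim(r), collapse = "x"), paste(dim(g), collapse = "x"),
      paste(dim(b), collapse = "x")))
  }
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    config_error("'weights' must be three non-negative values summing to 1")
  }
  gray_image(weights[1L] * r + weights[2L] * g + weights[3L] * b,
             provenance = "raw")
}

#' Min-max normalize image intensities to \[0, 1\]
#'
#' Affine rescaling `(I - min(I)) / (max(I) - min(I))`. The map is strictly
#' monotone, so the ordering of pixel values is preserved; the output range
#' is exactly \[0, 1\].
#'
#' @param img `gray_image` or numeric matrix with at least two distinct
#'   values.
#' @return A `gray_image` with provenance `"normalized"`.
#' @export
minmax_normalize <- function(img) {
  m <- as_pixels(img)
  rng <- range(m)
  if (diff(rng) == 0) {
    degenerate_error(
      "cannot min-max normalize a constant image (max equals min)")
  }
  out <- (m - rng[1L]) / diff(rng)
  # guard against last-place rounding so the normalized invariant is exact
  out[out < 0] <- 0
  out[out > 1] <- 1
  gray_image(out, provenance = "normalized")
}

#' Smoothing kernel specification
#'
#' The pre-derivative low-pass filter. The default is a 3 x 3 unit-sum box
#' (moving average); a discretized isotropic Gaussian is available. Border
#' pixels are padded by edge replication (default) or mirroring, so no
#' spurious gradients are introduced at the frame.
#'
#' @param kind `"box"` or `"gaussian"`.
#' @param window Odd window width in pixels; `window = 1` is the identity.
#' @param sigma Gaussian standard deviation in pixels. Defaults to the
#'   common rule `0.3 * ((window - 1)/2 - 1) + 0.8`.
#' @param border `"replicate"` (nearest edge pixel) or `"reflect"`
#'   (mirror about the edge).
#' @return A `smoothing_spec` object.
#' @export
smoothing_spec <- function(kind = c("box", "gaussian"), window = 3L,
                           sigma = NULL, border = c("replicate", "reflect")) {
  kind <- match.arg(kind)
  border <- match.arg(border)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    config_error("'window' must be an odd positive integer")
  }
  if (kind == "gaussian") {
    if (is.null(sigma)) sigma <- 0.3 * ((window - 1) / 2 - 1) + 0.8
    if (!is.numeric(sigma) || sigma <= 0) {
      config_error("'sigma' must be a positive number")
    }
  } else {
    sigma <- NULL
  }
  structure(list(kind = kind, window = window, sigma = sigma,
                 border = border),
            class = "smoothing_spec")
}

smoothing_kernel <- function(spec) {
  w <- spec$window
  if (spec$kind == "box") {
    return(matrix(1 / (w * w), w, w))
  }
  r <- (w - 1L) / 2L
  d <- (-r):r
  k <- exp(-outer(d^2, d^2, `+`) / (2 * spec$sigma^2))
  k / sum(k)
}

# Pad by `r` pixels on each side. replicate: clamp indices to the edge;
# reflect: mirror about the edge pixel (no edge duplication).
pad_matrix <- function(m, r, border) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- (1L - r):(nr + r)
  ci <- (1L - r):(nc + r)
  fix <- function(i, n) {
    if (border == "replicate") pmin(pmax(i, 1L), n)
    else { # reflect
      i <- ifelse(i < 1L, 2L - i, i)
      ifelse(i > n, 2L * n - i, i)
    }
  }
  m[fix(ri, nr), fix(ci, nc), drop = FALSE]
}

#' Smooth an image with a unit-sum kernel
#'
#' Linear convolution with the kernel from `spec`. Because the kernel sums
#' to one, constant regions are preserved exactly.
#'
#' @param img `gray_image` or numeric matrix.
#' @param spec A [smoothing_spec()].
#' @return A `gray_image` with provenance `"filtered"` (or the input
#'   unchanged when `window = 1`).
#' @export
smooth_image <- function(img, spec = smoothing_spec()) {
  if (!inherits(spec, "smoothing_spec")) {
    config_error("'spec' must be a smoothing_spec")
  }
  m <- as_pixels(img)
  w <- spec$window
  if (w == 1L) return(img)
  if (w > nrow(m) || w > ncol(m)) {
    config_error(sprintf(
      "smoothing window %d exceeds image size %d x %d", w, nrow(m), ncol(m)))
  }
  k <- smoothing_kernel(spec)
  r <- (w - 1L) / 2L
  padded <- pad_matrix(m, r, spec$border)
  out <- matrix(0, nrow(m), ncol(m))
  for (dy in 0:(w - 1L)) {
    for (dx in 0:(w - 1L)) {
      out <- out + k[dy + 1L, dx + 1L] *
        padded[(1L + dy):(nrow(m) + dy), (1L + dx):(ncol(m) + dx)]
    }
  }
  gray_image(out, provenance = "filtered")
}
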