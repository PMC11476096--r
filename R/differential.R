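#' Directional partial derivative of an image
#'
#' Finite-difference partial derivative along one axis. The x axis runs
#' along columns and the y axis along rows. First order uses central
#' differences `(f[i+1] - f[i-1]) / 2` in the interior with one-sided
#' differences at the two border lines; second order uses
#' `f[i+1] - 2 f[i] + f[i-1]` in the interior with the adjacent interior
#' value replicated at the border. Both stencils are exact for
#' polynomials up to their order.
#'
#' @param img `gray_image` or numeric matrix, at least 3 x 3.
#' @param axis `"x"` (columns) or `"y"` (rows).
#' @param order 1 or 2. No mixed derivatives are computed.
#' @return Numeric matrix of the same shape as `img`.
#' @export
partial_derivative <- function(img, axis = c("x", "y"), order = 1L) {
  axis <- match.arg(axis)
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) config_error("'order' must be 1 or 2")
  m <- as_pixels(img)
  if (nrow(m) < 3L || ncol(m) < 3L) {
    dimension_error("derivatives require an image of at least 3 x 3")
  }
  if (axis == "y") return(t(diff_cols(t(m), order)))
  diff_cols(m, order)
}

# derivative along columns of m (the x axis)
diff_cols <- function(m, order) {
  n <- ncol(m)
  d <- matrix(0, nrow(m), n)
  if (order == 1L) {
    d[, 2:(n - 1L)] <- (m[, 3:n] - m[, 1:(n - 2L)]) / 2
    d[, 1L] <- m[, 2L] - m[, 1L]
    d[, n] <- m[, n] - m[, n - 1L]
  } else {
    d[, 2:(n - 1L)] <- m[, 3:n] - 2 * m[, 2:(n - 1L)] + m[, 1:(n - 2L)]
    d[, 1L] <- d[, 2L]
    d[, n] <- d[, n - 1L]
  }
  d
}

sobel_gradients <- function(m) {
  # smoothed derivative: [1 2 1]/4 transverse x [-1 0 1]/2 longitudinal,
  # on a replicate-padded image, so magnitudes match central differences
  # on separable smooth fields
  p <- pad_matrix(m, 1L, "replicate")
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dy, dx) p[(1L + dy):(nr + dy), (1L + dx):(nc + dx)]
  smooth_y <- (sh(0L, 0L) + 2 * sh(1L, 0L) + sh(2L, 0L)) / 4
  smooth_x <- (sh(0L, 0L) + 2 * sh(0L, 1L) + sh(0L, 2L)) / 4
  p_sy <- pad_matrix(smooth_y, 1L, "replicate")
  p_sx <- pad_matrix(smooth_x, 1L, "replicate")
  shy <- function(dy, dx) p_sy[(1L + dy):(nr + dy), (1L + dx):(nc + dx)]
  shx <- function(dy, dx) p_sx[(1L + dy):(nr + dy), (1L + dx):(nc + dx)]
  list(gx = (shy(1L, 2L) - shy(1L, 0L)) / 2,
       gy = (shx(2L, 1L) - shx(0L, 1L)) / 2,
       gxx = shy(1L, 2L) - 2 * shy(1L, 1L) + shy(1L, 0L),
       gyy = shx(2L, 1L) - 2 * shx(1L, 1L) + shx(0L, 1L))
}

#' Non-directional first-derivative magnitude
#'
#' The combined first-derivative filter
#' `sqrt((dI/dx)^2 + (dI/dy)^2)`, i.e. the gradient magnitude. Direction
#' information is deliberately discarded.
#'
#' @param img `gray_image` or numeric matrix, at least 3 x 3.
#' @param scheme `"central"` (default) or `"sobel"` (smoothed stencil).
#' @return Non-negative matrix of the same shape as `img`.
#' @export
first_derivative_magnitude <- function(img, scheme = c("central", "sobel")) {
  scheme <- match.arg(scheme)
  m <- as_pixels(img)
  if (scheme == "sobel") {
    g <- sobel_gradients(m)
    return(sqrt(g$gx^2 + g$gy^2))
  }
  sqrt(partial_derivative(m, "x", 1L)^2 + partial_derivative(m, "y", 1L)^2)
}

#' Non-directional second-derivative magnitude
#'
#' The combined second-derivative filter
#' `sqrt((d2I/dx2)^2 + (d2I/dy2)^2)`, from the two pure second partials
#' only (no mixed term).
#'
#' @inheritParams first_derivative_magnitude
#' @return Non-negative matrix of the same shape as `img`.
#' @export
second_derivative_magnitude <- function(img, scheme = c("central", "sobel")) {
  scheme <- match.arg(scheme)
  m <- as_pixels(img)
  if (scheme == "sobel") {
    g <- sobel_gradients(m)
    return(sqrt(g$gxx^2 + g$gyy^2))
  }
  sqrt(partial_derivative(m, "x", 2L)^2 + partial_derivative(m, "y", 2L)^2)
}

#' First and second derivative-magnitude fields of an image
#'
#' @inheritParams first_derivative_magnitude
#' @return A `derivative_fields` list with components `d1`, `d2` (both the
#'   shape of `img`) and `scheme`.
#' @export
derivative_fields <- function(img, scheme = c("central", "sobel")) {
  scheme <- match.arg(scheme)
  structure(list(d1 = first_derivative_magnitude(img, scheme),
                 d2 = second_derivative_magnitude(img, scheme),
                 scheme = scheme),
            class = "derivative_fields")
}
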