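#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities with a `provenance`
#' attribute recording the last preparation stage applied (`"raw"`,
#' `"normalized"` or `"filtered"`). Rows index the vertical (y) axis with
#' row 1 at the top; columns index the horizontal (x) axis. Images must be
#' at least 3 x 3 so that second-order central differences are defined
#' everywhere in the interior.
#'
#' @param pixels Numeric matrix of finite intensity values, at least 3 x 3.
#' @param provenance One of `"raw"`, `"normalized"`, `"filtered"`. For
#'   `"normalized"` images the pixel range must be exactly \[0, 1\]
#'   (within 1e-12).
#'
#' @return A `gray_image` object.
#' @examples
#' img <- gray_image(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
gray_image <- function(pixels, provenance = "raw") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    input_error("'pixels' must be a numeric matrix")
  }
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    dimension_error(sprintf(
      "image must be at least 3 x 3 (got %d x %d)", nrow(pixels), ncol(pixels)
    ))
  }
  if (!all(is.finite(pixels))) {
    input_error("image contains non-finite pixel values")
  }
  provenance <- match.arg(provenance, c("raw", "normalized", "filtered"))
  if (provenance == "normalized") {
    rng <- range(pixels)
    if (abs(rng[1L]) > 1e-12 || abs(rng[2L] - 1) > 1e-12) {
      input_error("a 'normalized' image must have min 0 and max 1")
    }
  }
  structure(pixels, class = c("gray_image", class(pixels)),
            provenance = provenance)
}

#' @export
print.gray_image <- function(x, ...) {
  p <- as_pixels(x)
  cat(sprintf("<gray_image> %d x %d, provenance: %s, range [%g, %g]\n",
              nrow(p), ncol(p), attr(x, "provenance") %||% "raw",
              min(p), max(p)))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) as_pixels(x)

# Strip class/attributes down to a plain numeric matrix. Accepts either a
# gray_image or a bare matrix so low-level operators stay permissive.
as_pixels <- function(img) {
  if (inherits(img, "gray_image")) {
    attrs <- attributes(img)
    attributes(img) <- list(dim = attrs$dim)
    return(img)
  }
  if (is.matrix(img) && is.numeric(img)) return(img)
  input_error("expected a gray_image or numeric matrix")
}

provenance <- function(img) attr(img, "provenance") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop a fixed-width border from a field
#'
#' Removes `n` pixels from every side. Used to exclude the frame rows and
#' columns (where one-sided/replicated difference stencils apply) from
#' downstream variance computations.
#'
#' @param field Numeric matrix or `gray_image`.
#' @param n Non-negative integer border width in pixels.
#' @return The cropped matrix (plain matrix; provenance is not preserved).
#' @export
crop_border <- function(field, n) {
  m <- as_pixels(field)
  n <- as.integer(n)
  if (n < 0L) config_error("'n' must be non-negative")
  if (n == 0L) return(m)
  if (nrow(m) <= 2L * n || ncol(m) <= 2L * n) {
    dimension_error("crop_border: nothing left after cropping")
  }
  m[(n + 1L):(nrow(m) - n), (n + 1L):(ncol(m) - n), drop = FALSE]
}
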