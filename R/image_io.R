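#' Read a raster image from disk
#'
#' Reads PNG, JPEG or PGM/PPM (netpbm) rasters and returns intensities on
#' their native integer scale (an 8-bit image yields values in \[0, 255\],
#' a 16-bit PNG values in \[0, 65535\]). Grayscale files return a
#' [gray_image()]; color files return an `rgb_planes` list with components
#' `r`, `g`, `b`, each a `gray_image`-shaped matrix. An alpha channel, if
#' present, is dropped with a warning.
#'
#' TIFF is not supported in this build (no TIFF reader is available);
#' convert to PNG or PGM first.
#'
#' @param path Path to a `.png`, `.jpg`/`.jpeg`, or `.pgm`/`.pnm`/`.ppm`
#'   file.
#' @return A `gray_image`, or an `rgb_planes` list of three matrices.
#' @seealso [to_grayscale()], [write_pgm()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    input_error(sprintf("cannot read image: '%s' does not exist", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = {
        x <- png::readPNG(path, info = TRUE)
        info <- attr(x, "info")
        depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
        unclass(x) * (2^depth - 1)
      },
      jpg = ,
      jpeg = jpeg::readJPEG(path) * 255,
      pgm = ,
      pnm = ,
      ppm = read_pnm_array(path),
      input_error(sprintf(
        "unsupported image format '.%s' for '%s' (PNG, JPEG, PGM supported)",
        ext, path))
    ),
    error = function(e) {
      if (inherits(e, "hjorth2d_error")) stop(e)
      input_error(sprintf("failed to read image '%s': %s",
                          path, conditionMessage(e)))
    }
  )
  planes_from_array(arr, path)
}

planes_from_array <- function(arr, path) {
  if (is.matrix(arr)) {
    check_min_size(arr, path)
    return(gray_image(arr, provenance = "raw"))
  }
  nc <- dim(arr)[3L]
  if (nc == 2L) { # gray + alpha
    warning(sprintf("dropping alpha channel of '%s'", path))
    arr <- arr[, , 1L, drop = TRUE]
    check_min_size(arr, path)
    return(gray_image(arr, provenance = "raw"))
  }
  if (nc == 4L) {
    warning(sprintf("dropping alpha channel of '%s'", path))
    arr <- arr[, , 1:3, drop = FALSE]
    nc <- 3L
  }
  if (nc != 3L) input_error(sprintf("unexpected channel count in '%s'", path))
  check_min_size(arr[, , 1L], path)
  structure(list(r = arr[, , 1L], g = arr[, , 2L], b = arr[, , 3L]),
            class = "rgb_planes")
}

check_min_size <- function(m, path) {
  if (nrow(m) < 3L || ncol(m) < 3L) {
    dimension_error(sprintf(
      "image '%s' is %d x %d; at least 3 x 3 required",
      path, nrow(m), ncol(m)))
  }
}

# pixmap::read.pnm rescales to [0, 1] and discards maxval, so recover the
# native 8-bit scale here; 16-bit netpbm files are not supported.
read_pnm_array <- function(path) {
  pm <- pixmap::read.pnm(path)
  if (methods::is(pm, "pixmapGrey")) {
    return(pm@grey * 255)
  }
  arr <- array(0, c(dim(pm@red), 3L))
  arr[, , 1L] <- pm@red * 255
  arr[, , 2L] <- pm@green * 255
  arr[, , 3L] <- pm@blue * 255
  arr
}

#' Write a grayscale image as plain-text PGM (P2)
#'
#' Quantizes to `max_val` levels after clamping to \[0, max_val\]. The
#' ASCII P2 format keeps fixtures human-readable and diff-friendly.
#'
#' @param img `gray_image` or numeric matrix with values already on the
#'   \[0, max_val\] scale.
#' @param path Output path.
#' @param max_val Maximum gray value (default 255 for 8-bit).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, max_val = 255L) {
  m <- as_pixels(img)
  q <- round(pmin(pmax(m, 0), max_val))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(max_val)), con)
  apply(q, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Write a grayscale image as 8-bit PNG
#'
#' Applies min-max scaling to \[0, 255\] before quantization, mimicking
#' 8-bit acquisition depth. A constant image is written as mid-gray.
#'
#' @param img `gray_image` or numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_png8 <- function(img, path) {
  m <- as_pixels(img)
  rng <- range(m)
  scaled <- if (diff(rng) == 0) {
    matrix(0.5, nrow(m), ncol(m))
  } else {
    round((m - rng[1L]) / diff(rng) * 255) / 255
  }
  png::writePNG(scaled, path)
  invisible(path)
}
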