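#' @name hjorth-descriptors
#' @title The three Hjorth descriptors of a 2D image
#'
#' @description
#' Hjorth's descriptors were introduced for one-dimensional EEG traces and
#' carry over to images once the (directional) signal derivative is
#' replaced by the non-directional derivative magnitudes `I'` and `I''`
#' (see [first_derivative_magnitude()]):
#'
#' * **Activity** = `var(I)` — the population variance of the intensities;
#'   by Parseval's theorem it equals the total spectral power of the
#'   mean-removed image (see [spectral_total_power()]).
#' * **Mobility** = `sd(I') / sd(I)` — a proxy for the dominant spatial
#'   frequency: fine textures move the gradient energy up.
#' * **Complexity** = `(sd(I'') / sd(I')) / (sd(I') / sd(I))` — the change
#'   in mobility between the signal and its derivative, a bandwidth/shape
#'   proxy; it is 1 for a pure 1D sinusoid in the classical definition.
#'
#' All standard deviations are population (divide by N) statistics over
#' every pixel of the supplied fields. Mobility and Complexity are
#' invariant under affine intensity maps `I -> a*I + b` (a != 0);
#' Activity scales by `a^2`.
NULL

pop_var <- function(m) {
  x <- as.numeric(m)
  mean((x - mean(x))^2)
}

pop_sd <- function(m) sqrt(pop_var(m))

#' Activity: population variance of image intensities
#'
#' @param img `gray_image` or numeric matrix.
#' @return Non-negative scalar, in squared intensity units.
#' @family hjorth descriptors
#' @export
activity <- function(img) pop_var(as_pixels(img))

#' Mobility: sd of the gradient magnitude over sd of the image
#'
#' @param img `gray_image` or numeric matrix (must be non-constant).
#' @param d1 First derivative-magnitude field of `img`, same cropping.
#' @return Non-negative scalar (dimensionless).
#' @family hjorth descriptors
#' @export
mobility <- function(img, d1) {
  s0 <- pop_sd(as_pixels(img))
  if (s0 == 0) {
    degenerate_error("Mobility is undefined for a constant image (sd = 0)")
  }
  pop_sd(as_pixels(d1)) / s0
}

#' Complexity: mobility of the derivative over mobility of the image
#'
#' @param d1,d2 First and second derivative-magnitude fields.
#' @param img The image the fields were computed from, same cropping.
#' @return Non-negative scalar (dimensionless).
#' @family hjorth descriptors
#' @export
complexity <- function(d1, d2, img) {
  s0 <- pop_sd(as_pixels(img))
  s1 <- pop_sd(as_pixels(d1))
  if (s0 == 0) {
    degenerate_error("Complexity is undefined for a constant image (sd = 0)")
  }
  if (s1 == 0) {
    degenerate_error(
      "Complexity is undefined when the first derivative field is constant")
  }
  (pop_sd(as_pixels(d2)) / s1) / (s1 / s0)
}

#' Total spectral power of the mean-removed image
#'
#' Computed from the 2D DFT as `sum(|F|^2) / N^2` over all frequency
#' bins, the Parseval normalization under which the total power equals
#' the population variance of the intensities ([activity()]). Provided as
#' an independent frequency-domain route to Activity.
#'
#' @param img `gray_image` or numeric matrix.
#' @return Non-negative scalar equal to `activity(img)` up to rounding.
#' @export
spectral_total_power <- function(img) {
  m <- as_pixels(img)
  n <- length(m)
  sum(Mod(stats::fft(m - mean(m)))^2) / n^2
}

#' Pipeline configuration for descriptor extraction
#'
#' Collects every tunable of the image-preparation and descriptor stages.
#'
#' @param normalize Min-max normalize intensities to \[0, 1\] first
#'   (default `TRUE`). Disable only for scale-sensitivity experiments.
#' @param smoothing A [smoothing_spec()]; default 3 x 3 unit-sum box with
#'   replicate borders. The coefficient rule of the original MATLAB
#'   average filter (mean/sd dependent) is not published; pass a
#'   `kernel_fn(img) -> kernel matrix` to slot in a custom rule.
#' @param scheme Derivative stencil, `"central"` or `"sobel"`.
#' @param crop_border Pixels to strip from each side of the image and both
#'   derivative fields before the variance computations (default 0: the
#'   frame lines, where one-sided stencils apply, are included).
#' @param compute_on `"filtered"` (descriptors from the smoothed image;
#'   default) or `"unfiltered"` (from the normalized, unsmoothed image).
#' @param grayscale_weights RGB-to-gray weights, BT.601 by default.
#' @param kernel_fn Optional function `(matrix) -> unit-sum kernel matrix`
#'   replacing the built-in smoothing kernel, e.g. an image-adaptive rule.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(normalize = TRUE,
                            smoothing = smoothing_spec(),
                            scheme = c("central", "sobel"),
                            crop_border = 0L,
                            compute_on = c("filtered", "unfiltered"),
                            grayscale_weights = c(0.299, 0.587, 0.114),
                            kernel_fn = NULL) {
  scheme <- match.arg(scheme)
  compute_on <- match.arg(compute_on)
  crop_border <- as.integer(crop_border)
  if (crop_border < 0L) config_error("'crop_border' must be >= 0")
  if (!is.null(kernel_fn) && !is.function(kernel_fn)) {
    config_error("'kernel_fn' must be a function or NULL")
  }
  structure(list(normalize = normalize, smoothing = smoothing,
                 scheme = scheme, crop_border = crop_border,
                 compute_on = compute_on,
                 grayscale_weights = grayscale_weights,
                 kernel_fn = kernel_fn),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  sm <- config$smoothing
  paste(
    sprintf("normalize=%s", config$normalize),
    sprintf("smoothing=%s/w%d/s%s/%s", sm$kind, sm$window,
            if (is.null(sm$sigma)) "-" else format(sm$sigma), sm$border),
    sprintf("scheme=%s", config$scheme),
    sprintf("crop=%d", config$crop_border),
    sprintf("on=%s", config$compute_on),
    sprintf("gray=%s", paste(format(config$grayscale_weights),
                             collapse = ",")),
    if (is.null(config$kernel_fn)) "kernel=builtin" else "kernel=custom",
    sep = "; ")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "hjorth2d_error")) {
      stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                          class = class(e)))
    }
    stop(e)
  })
}

apply_smoothing <- function(img, config) {
  if (!is.null(config$kernel_fn)) {
    k <- config$kernel_fn(as_pixels(img))
    if (!is.matrix(k) || abs(sum(k) - 1) > 1e-8) {
      config_error("kernel_fn must return a unit-sum kernel matrix")
    }
    r <- (nrow(k) - 1L) / 2L
    m <- as_pixels(img)
    padded <- pad_matrix(m, r, config$smoothing$border)
    out <- matrix(0, nrow(m), ncol(m))
    for (dy in 0:(nrow(k) - 1L)) for (dx in 0:(ncol(k) - 1L)) {
      out <- out + k[dy + 1L, dx + 1L] *
        padded[(1L + dy):(nrow(m) + dy), (1L + dx):(ncol(m) + dx)]
    }
    return(gray_image(out, provenance = "filtered"))
  }
  smooth_image(img, config$smoothing)
}

#' Compute the Hjorth descriptor triple of one image
#'
#' Runs the full extraction pipeline: grayscale conversion (if given RGB
#' planes or a file path), min-max normalization, smoothing, the two
#' derivative-magnitude fields, then Activity, Mobility and Complexity.
#' Errors raised by a stage are re-thrown with the stage name attached.
#'
#' @param img A file path, `gray_image`, numeric matrix, or `rgb_planes`.
#' @param config A [pipeline_config()].
#' @param image_id,group Optional labels carried into the result.
#' @return A `hjorth_descriptors` list with `activity`, `mobility`,
#'   `complexity`, the labels, and the configuration fingerprint.
#' @examples
#' img <- gray_image(matrix(sin(seq(0, 8 * pi, length.out = 1024)), 32, 32))
#' hjorth_descriptors(img)
#' @export
hjorth_descriptors <- function(img, config = pipeline_config(),
                               image_id = NA_character_,
                               group = NA_character_) {
  if (is.character(img)) img <- run_stage("load", load_image(img))
  if (inherits(img, "rgb_planes")) {
    img <- run_stage("grayscale",
                     to_grayscale(img, weights = config$grayscale_weights))
  }
  gray <- gray_image(as_pixels(img), provenance = "raw")
  prepped <- if (isTRUE(config$normalize)) {
    run_stage("normalize", minmax_normalize(gray))
  } else {
    gray
  }
  base_img <- if (config$compute_on == "filtered") {
    run_stage("smooth", apply_smoothing(prepped, config))
  } else {
    prepped
  }
  fields <- run_stage("derivatives", derivative_fields(base_img,
                                                       config$scheme))
  n <- config$crop_border
  bm <- crop_border(base_img, n)
  d1 <- crop_border(fields$d1, n)
  d2 <- crop_border(fields$d2, n)
  res <- run_stage("descriptors", list(
    activity = activity(bm),
    mobility = mobility(bm, d1),
    complexity = complexity(d1, d2, bm)
  ))
  structure(c(res, list(image_id = image_id, group = group,
                        config = config_fingerprint(config))),
            class = "hjorth_descriptors")
}

#' @export
print.hjorth_descriptors <- function(x, ...) {
  cat(sprintf(
    "<hjorth_descriptors>%s activity=%.6g mobility=%.6g complexity=%.6g\n",
    if (is.na(x$image_id)) "" else paste0(" ", x$image_id),
    x$activity, x$mobility, x$complexity))
  invisible(x)
}
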