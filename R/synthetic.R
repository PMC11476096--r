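# Seeded synthetic textures. These stand in for real micrograph cohorts:
# the groups differ in variance and spatial-frequency content, which is
# exactly the structure the three descriptors respond to. All generators
# are fully determined by (spec, seed).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Texture specification for the synthetic generators
#'
#' @param kind `"plane_wave"` or `"gaussian_random_field"`.
#' @param shape `c(rows, cols)`, each >= 3.
#' @param amplitude Target amplitude: plane waves use it literally; random
#'   fields are rescaled to this population standard deviation.
#' @param frequency Plane-wave spatial frequency in cycles/pixel, in
#'   (0, 0.5\] (Nyquist).
#' @param theta Plane-wave propagation angle in radians (0 = along x).
#' @param spectral_exponent Random-field power-spectrum slope `beta`:
#'   amplitude spectrum shaped by `|omega|^(-beta/2)`, so the power
#'   spectrum falls off as `|omega|^(-beta)`. 0 gives white noise; 2 a
#'   visually smooth field.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @return A `texture_spec` object.
#' @export
texture_spec <- function(kind = c("plane_wave", "gaussian_random_field"),
                         shape = c(64L, 64L), amplitude = 1,
                         frequency = NULL, theta = 0,
                         spectral_exponent = NULL, noise_sd = 0) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 3L)) {
    config_error("'shape' must be c(rows, cols), each >= 3")
  }
  if (kind == "plane_wave") {
    if (is.null(frequency) || frequency <= 0 || frequency > 0.5) {
      config_error("plane-wave 'frequency' must lie in (0, 0.5]")
    }
  } else {
    if (is.null(spectral_exponent) || spectral_exponent < 0) {
      config_error("'spectral_exponent' must be >= 0")
    }
  }
  structure(list(kind = kind, shape = shape, amplitude = amplitude,
                 frequency = frequency, theta = theta,
                 spectral_exponent = spectral_exponent,
                 noise_sd = noise_sd),
            class = "texture_spec")
}

#' Sinusoidal plane-wave test image
#'
#' `I(x, y) = amplitude * sin(2 pi f (x cos(theta) + y sin(theta)))`,
#' shifted by `amplitude` so all values are non-negative, plus optional
#' seeded Gaussian noise. Coordinates are 0-based pixel indices (x along
#' columns).
#'
#' @param spec A `plane_wave` [texture_spec()].
#' @param seed Integer seed (only consumed when `noise_sd > 0`).
#' @return A `gray_image` (provenance `"raw"`).
#' @export
plane_wave <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "texture_spec"))
  if (spec$kind != "plane_wave") config_error("spec kind must be plane_wave")
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  x <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
  y <- matrix(rep(0:(nr - 1L), times = nc), nr, nc)
  phase <- 2 * pi * spec$frequency *
    (x * cos(spec$theta) + y * sin(spec$theta))
  img <- spec$amplitude * sin(phase) + abs(spec$amplitude)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(nr * nc,
                                                     sd = spec$noise_sd),
                                        nr, nc))
  }
  gray_image(img, provenance = "raw")
}

fft_freq <- function(n) (((0:(n - 1L)) + floor(n / 2)) %% n - floor(n / 2)) / n

#' Gaussian random field with power-law spectrum
#'
#' White Gaussian noise is transformed to the frequency domain, its
#' amplitude spectrum multiplied by `|omega|^(-beta/2)` (DC removed), and
#' transformed back. The result is standardized to population standard
#' deviation `amplitude` and shifted so its minimum is 0. `beta = 0`
#' reproduces white noise; larger `beta` concentrates power at low
#' spatial frequencies, giving smoother textures with lower Mobility.
#'
#' @param spec A `gaussian_random_field` [texture_spec()].
#' @param seed Integer seed; the same (spec, seed) pair is bit-identical.
#' @return A `gray_image` (provenance `"raw"`).
#' @export
gaussian_random_field <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "texture_spec"))
  if (spec$kind != "gaussian_random_field") {
    config_error("spec kind must be gaussian_random_field")
  }
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  field <- with_seed(seed, {
    w <- matrix(stats::rnorm(nr * nc), nr, nc)
    fy <- fft_freq(nr); fx <- fft_freq(nc)
    fmag <- sqrt(outer(fy^2, fx^2, `+`))
    shape_f <- fmag^(-spec$spectral_exponent / 2)
    shape_f[1L, 1L] <- 0 # remove DC; also kills the |0|^-b singularity
    f <- Re(stats::fft(stats::fft(w) * shape_f, inverse = TRUE)) / (nr * nc)
    if (spec$noise_sd > 0) {
      f <- f + matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    }
    f
  })
  field <- field - mean(field)
  s <- pop_sd(field)
  if (s > 0) field <- field * (spec$amplitude / s)
  gray_image(field - min(field), provenance = "raw")
}

#' Generate one texture from a spec
#'
#' @param spec A [texture_spec()].
#' @param seed Integer seed.
#' @return A `gray_image`.
#' @export
generate_texture <- function(spec, seed = 1L) {
  switch(spec$kind,
         plane_wave = plane_wave(spec, seed),
         gaussian_random_field = gaussian_random_field(spec, seed))
}

# Stable per-image seed from (master_seed, label, index): a small
# polynomial rolling hash mod 2^31 - 1, exact in double arithmetic.
# Hashing the label (not the group position) means adding a group leaves
# the other groups' images untouched.
derive_seed <- function(master_seed, label, index) {
  p <- 2147483647 # 2^31 - 1
  h <- as.numeric(master_seed) %% p
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% p
  h <- (h * 131 + index) %% p
  as.integer(max(h, 1))
}

#' Generate a labeled synthetic image cohort
#'
#' Produces `n` images per group from per-group texture specs, with
#' per-image seeds derived deterministically from the master seed and the
#' group label. Optionally writes the images (8-bit PNG after min-max
#' scaling, or plain-text PGM) plus a `manifest.csv` of
#' (image_id, group, seed, path).
#'
#' @param groups List of `list(label =, spec =, n =)` entries; labels
#'   must be unique.
#' @param master_seed Integer master seed.
#' @param out_dir Directory to write images into, or `NULL` to keep the
#'   cohort in memory only.
#' @param format `"png"` (default) or `"pgm"` when writing.
#' @return Invisibly, `list(images = named list of gray_image,
#'   manifest = data.frame)`.
#' @export
make_cohort <- function(groups, master_seed = 1L, out_dir = NULL,
                        format = c("png", "pgm")) {
  format <- match.arg(format)
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels)) {
    config_error("duplicate group labels in cohort definition")
  }
  ns <- vapply(groups, function(g) as.integer(g$n), integer(1))
  if (any(ns < 1L)) config_error("every group needs n >= 1")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  images <- list()
  rows <- list()
  for (g in groups) {
    for (i in seq_len(g$n)) {
      seed <- derive_seed(master_seed, g$label, i)
      img <- generate_texture(g$spec, seed)
      id <- sprintf("%s_%03d", g$label, i)
      images[[id]] <- img
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(id, ".", format))
        if (format == "png") write_png8(img, path) else {
          rng <- range(as_pixels(img))
          scaled <- if (diff(rng) == 0) as_pixels(img) * 0 + 127 else
            (as_pixels(img) - rng[1L]) / diff(rng) * 255
          write_pgm(scaled, path)
        }
      }
      rows[[id]] <- data.frame(image_id = id, group = g$label,
                               seed = seed, path = path,
                               stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(list(images = images, manifest = manifest))
}
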