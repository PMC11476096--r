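# Straight-line brute-force reimplementation of the descriptor pipeline.
# Deliberately written with explicit loops and no calls into the package,
# so it can serve as an independent oracle for the vectorized code path.
# Matches the default configuration: BT.601 grayscale, min-max
# normalization, 3x3 unit-sum box smoothing with replicate borders,
# central differences with one-sided (order 1) / replicated (order 2)
# border stencils, population standard deviations.

oracle_pop_sd <- function(m) {
  x <- as.vector(m)
  sqrt(sum((x - sum(x) / length(x))^2) / length(x))
}

oracle_smooth_box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in 1:nr) {
    for (j in 1:nc) {
      acc <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- min(max(i + di, 1), nr)
          jj <- min(max(j + dj, 1), nc)
          acc <- acc + m[ii, jj]
        }
      }
      out[i, j] <- acc / 9
    }
  }
  out
}

oracle_d1_along <- function(v) {
  n <- length(v)
  d <- numeric(n)
  d[1] <- v[2] - v[1]
  d[n] <- v[n] - v[n - 1]
  if (n > 2) for (i in 2:(n - 1)) d[i] <- (v[i + 1] - v[i - 1]) / 2
  d
}

oracle_d2_along <- function(v) {
  n <- length(v)
  d <- numeric(n)
  for (i in 2:(n - 1)) d[i] <- v[i + 1] - 2 * v[i] + v[i - 1]
  d[1] <- d[2]
  d[n] <- d[n - 1]
  d
}

oracle_fields <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  dx1 <- matrix(0, nr, nc); dy1 <- matrix(0, nr, nc)
  dx2 <- matrix(0, nr, nc); dy2 <- matrix(0, nr, nc)
  for (i in 1:nr) {
    dx1[i, ] <- oracle_d1_along(m[i, ])
    dx2[i, ] <- oracle_d2_along(m[i, ])
  }
  for (j in 1:nc) {
    dy1[, j] <- oracle_d1_along(m[, j])
    dy2[, j] <- oracle_d2_along(m[, j])
  }
  list(d1 = sqrt(dx1^2 + dy1^2), d2 = sqrt(dx2^2 + dy2^2))
}

# img: plain matrix (grayscale) or list(r=, g=, b=)
oracle_descriptors <- function(img, crop = 0, normalize = TRUE,
                               smooth = TRUE) {
  m <- if (is.list(img)) {
    0.299 * img$r + 0.587 * img$g + 0.114 * img$b
  } else {
    img
  }
  if (normalize) m <- (m - min(m)) / (max(m) - min(m))
  if (smooth) m <- oracle_smooth_box3(m)
  f <- oracle_fields(m)
  d1 <- f$d1; d2 <- f$d2
  if (crop > 0) {
    sel_r <- (crop + 1):(nrow(m) - crop)
    sel_c <- (crop + 1):(ncol(m) - crop)
    m <- m[sel_r, sel_c]; d1 <- d1[sel_r, sel_c]; d2 <- d2[sel_r, sel_c]
  }
  s0 <- oracle_pop_sd(m); s1 <- oracle_pop_sd(d1); s2 <- oracle_pop_sd(d2)
  list(activity = oracle_pop_sd(m)^2,
       mobility = s1 / s0,
       complexity = (s2 / s1) / (s1 / s0))
}

# all permutations of 1..n (n small), for exhaustive rank-test nulls
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# direct O(n^2 k^2) convolution with border padding, for smoothing checks
oracle_convolve <- function(m, kernel, border = "replicate") {
  nr <- nrow(m); nc <- ncol(m)
  r <- (nrow(kernel) - 1) / 2
  idx <- function(i, n) {
    if (border == "replicate") return(min(max(i, 1), n))
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
    i
  }
  out <- matrix(0, nr, nc)
  for (i in 1:nr) {
    for (j in 1:nc) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + kernel[di + r + 1, dj + r + 1] *
            m[idx(i + di, nr), idx(j + dj, nc)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}
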