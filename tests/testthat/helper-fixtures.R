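# Small in-code fixtures shared across test files.

random_image <- function(seed, nr = 16, nc = 16, max_val = 255) {
  set.seed(seed)
  gray_image(matrix(runif(nr * nc, 0, max_val), nr, nc))
}

ramp_x <- function(nr = 8, nc = 8) {
  gray_image(matrix(rep(0:(nc - 1), each = nr), nr, nc))
}

# the three-group synthetic cohort emulating the pollen study design:
# sizes 18/8/9, groups separated in spectral content (exponents 0/1/2)
pollen_like_cohort <- function(master_seed = 1L, shape = c(256L, 256L)) {
  spec_b <- function(b) {
    texture_spec("gaussian_random_field", shape, spectral_exponent = b)
  }
  make_cohort(list(
    list(label = "groupA", spec = spec_b(0), n = 18L),
    list(label = "groupB", spec = spec_b(1), n = 8L),
    list(label = "groupC", spec = spec_b(2), n = 9L)),
    master_seed = master_seed)
}

# Published worked example: group sizes and rank sums / averages of the
# three-taxon pollen comparison (N = 35).
pollen_sizes <- c(18L, 8L, 9L)
pollen_rank_sums <- list(
  activity = c(348, 229, 53),
  mobility = c(310, 242, 78),
  complexity = c(339, 41, 250))
pollen_rank_averages <- list(
  activity = c(19.333, 28.625, 5.888),
  mobility = c(17.222, 30.250, 8.666),
  complexity = c(18.833, 5.125, 27.777))
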