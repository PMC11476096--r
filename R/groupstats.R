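#' Grouped sample of one descriptor
#'
#' @param values Numeric vector of descriptor values.
#' @param groups Group label for each value (character or factor); group
#'   order follows first appearance unless `groups` is already a factor.
#' @param descriptor_name Label for reporting.
#' @return A `grouped_sample` object.
#' @export
grouped_sample <- function(values, groups, descriptor_name = "value") {
  if (length(values) != length(groups)) {
    input_error("'values' and 'groups' must have the same length")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    input_error("descriptor values must be finite and non-missing")
  }
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) {
    input_error("need at least 2 non-empty groups")
  }
  structure(list(descriptor_name = descriptor_name,
                 values = as.numeric(values), groups = groups,
                 sizes = as.integer(table(groups)),
                 labels = levels(groups),
                 total_n = length(values)),
            class = "grouped_sample")
}

#' Pooled mid-rank summary of a grouped sample
#'
#' Ranks all N values jointly (ties get the average of the tied ranks),
#' then sums and averages per group. Rank sums always satisfy the
#' conservation identity `sum(R_i) = N (N + 1) / 2`.
#'
#' @param sample A [grouped_sample()].
#' @return A `rank_summary` with `sizes`, `rank_sums`, `rank_averages`,
#'   `tie_groups` (multiplicities of tied value clusters) and `N`.
#' @export
rank_all <- function(sample) {
  stopifnot(inherits(sample, "grouped_sample"))
  r <- rank(sample$values, ties.method = "average")
  sums <- as.numeric(tapply(r, sample$groups, sum))
  tab <- table(sample$values)
  rank_summary(labels = sample$labels, sizes = sample$sizes,
               rank_sums = sums,
               tie_groups = as.integer(tab[tab > 1L]))
}

#' Construct a rank summary directly
#'
#' Mostly useful for re-running the rank-based tests from published
#' tables (group sizes plus rank sums or rank averages) without the raw
#' values.
#'
#' @param labels Group labels.
#' @param sizes Group sizes `n_i`.
#' @param rank_sums,rank_averages Supply one of the two.
#' @param tie_groups Multiplicities of tied clusters (default: none).
#' @return A `rank_summary` object.
#' @export
rank_summary <- function(labels = paste0("g", seq_along(sizes)), sizes,
                         rank_sums = NULL, rank_averages = NULL,
                         tie_groups = integer(0)) {
  sizes <- as.integer(sizes)
  if (is.null(rank_sums)) {
    if (is.null(rank_averages)) {
      input_error("supply 'rank_sums' or 'rank_averages'")
    }
    rank_sums <- rank_averages * sizes
  }
  if (length(labels) != length(sizes) ||
      length(rank_sums) != length(sizes)) {
    input_error("'labels', 'sizes' and rank sums must align")
  }
  structure(list(labels = labels, sizes = sizes,
                 rank_sums = as.numeric(rank_sums),
                 rank_averages = rank_sums / sizes,
                 tie_groups = as.integer(tie_groups),
                 N = sum(sizes)),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat(sprintf("<rank_summary> N = %d\n", x$N))
  print(data.frame(group = x$labels, n = x$sizes,
                   rank_sum = x$rank_sums,
                   rank_average = round(x$rank_averages, 3)))
  invisible(x)
}

tie_correction_factor <- function(tie_groups, N) {
  if (length(tie_groups) == 0L || N < 2L) return(1)
  1 - sum(tie_groups^3 - tie_groups) / (N^3 - N)
}

h2d_test_result <- function(statistic, p_value, df, method, extra = list()) {
  structure(c(list(statistic = statistic, p_value = p_value, df = df,
                   method = method), extra),
            class = "h2d_test")
}

#' @export
print.h2d_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.6g\n", x$method,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  invisible(x)
}

#' Kruskal-Wallis H from group sizes and rank sums
#'
#' `H = (12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)) /
#' tie_correction`, referred to a chi-square distribution with k - 1
#' degrees of freedom. Lets published rank-sum tables be re-tested
#' without the raw data.
#'
#' @param sizes Group sizes `n_i`.
#' @param rank_sums Group rank sums `R_i`; must satisfy
#'   `sum(R_i) = N (N + 1) / 2`.
#' @param tie_correction Divisor `1 - sum(t^3 - t) / (N^3 - N)`;
#'   default 1 (no ties).
#' @return An `h2d_test` with `statistic`, `p_value`, `df`.
#' @export
kruskal_wallis_from_ranks <- function(sizes, rank_sums,
                                      tie_correction = 1) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 2L) input_error("need at least 2 groups")
  N <- sum(sizes)
  expected <- N * (N + 1) / 2
  if (abs(sum(rank_sums) - expected) > 1e-6 * expected) {
    input_error(sprintf(
      "rank sums are not conserved: sum = %g, expected N(N+1)/2 = %g",
      sum(rank_sums), expected))
  }
  if (tie_correction <= 0) degenerate_error("all values tied")
  H <- (12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)) /
    tie_correction
  df <- length(sizes) - 1L
  h2d_test_result(H, stats::pchisq(H, df, lower.tail = FALSE), df,
                  "Kruskal-Wallis rank ANOVA")
}

#' Kruskal-Wallis rank ANOVA of a grouped sample
#'
#' Pools the mid-ranks ([rank_all()]) and applies
#' [kruskal_wallis_from_ranks()] with the standard tie correction. The
#' chi-square reference is an approximation; for very small samples an
#' exact permutation p-value over all group assignments is available.
#'
#' @param sample A [grouped_sample()].
#' @param tie_correct Apply the tie correction (default `TRUE`).
#' @param method `"chisq"` (default) or `"permutation"` (exact, total
#'   N limited so the full enumeration stays below ~200k assignments).
#' @return An `h2d_test`; the permutation method reports `df = NA` and
#'   carries `n_permutations`.
#' @export
kruskal_wallis <- function(sample, tie_correct = TRUE,
                           method = c("chisq", "permutation")) {
  stopifnot(inherits(sample, "grouped_sample"))
  method <- match.arg(method)
  if (length(unique(sample$values)) == 1L) {
    degenerate_error("all values identical: H is undefined")
  }
  rs <- rank_all(sample)
  tc <- if (tie_correct) tie_correction_factor(rs$tie_groups, rs$N) else 1
  res <- kruskal_wallis_from_ranks(rs$sizes, rs$rank_sums, tc)
  if (method == "permutation") {
    p <- kw_permutation_p(sample$values, sample$groups, res$statistic,
                          tie_correct)
    res <- h2d_test_result(res$statistic, p$p, NA_integer_,
                           "Kruskal-Wallis (exact permutation)",
                           list(n_permutations = p$n))
  }
  res$rank_summary <- rs
  res
}

kw_statistic_of_ranks <- function(r, groups, tc) {
  sums <- as.numeric(tapply(r, groups, sum))
  sizes <- as.integer(table(groups))
  N <- length(r)
  (12 / (N * (N + 1)) * sum(sums^2 / sizes) - 3 * (N + 1)) / tc
}

# Exact permutation null: enumerate every distinct assignment of the
# observed values to groups of the given sizes and count H >= H_obs.
kw_permutation_p <- function(values, groups, H_obs, tie_correct) {
  sizes <- as.integer(table(groups))
  N <- length(values)
  n_assign <- factorial(N) / prod(factorial(sizes))
  if (n_assign > 2e5) {
    config_error(sprintf(
      "exact permutation infeasible: %.3g distinct assignments", n_assign))
  }
  r <- rank(values, ties.method = "average")
  tc <- if (tie_correct) {
    tab <- table(values)
    tie_correction_factor(as.integer(tab[tab > 1L]), N)
  } else 1
  count <- 0L
  total <- 0L
  # recursive enumeration of index partitions into the k groups
  recurse <- function(remaining, group_idx, assigned_groups) {
    if (group_idx == length(sizes)) {
      g <- assigned_groups
      g[remaining] <- group_idx
      H <- kw_statistic_of_ranks(r, g, tc)
      total <<- total + 1L
      if (H >= H_obs - 1e-12) count <<- count + 1L
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining, sizes[group_idx], simplify = FALSE)
    for (p in picks) {
      g <- assigned_groups
      g[p] <- group_idx
      recurse(setdiff(remaining, p), group_idx + 1L, g)
    }
  }
  recurse(seq_len(N), 1L, integer(N))
  list(p = count / total, n = total)
}

#' Dunn's post hoc test on rank means
#'
#' For each pair of groups, `z_ij = |Rbar_i - Rbar_j| / SE_ij` with
#' `SE_ij = sqrt((N (N + 1) / 12 - T / (12 (N - 1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie clusters (zero without ties). Raw
#' two-sided normal p-values are Bonferroni-adjusted by the number of
#' pairs `k (k - 1) / 2`.
#'
#' @param x A [grouped_sample()] (ranks computed internally, ties
#'   corrected) or a [rank_summary()] (e.g. rebuilt from a published
#'   table; tie information taken from the summary).
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return A `posthoc_matrix` with symmetric matrices `z`, `p_raw`,
#'   `p_adj` (diagonal `NA`).
#' @export
dunn_posthoc <- function(x, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  rs <- if (inherits(x, "grouped_sample")) rank_all(x)
        else if (inherits(x, "rank_summary")) x
        else input_error("'x' must be a grouped_sample or rank_summary")
  k <- length(rs$sizes)
  N <- rs$N
  tie_term <- if (length(rs$tie_groups)) {
    sum(rs$tie_groups^3 - rs$tie_groups) / (12 * (N - 1))
  } else 0
  var_base <- N * (N + 1) / 12 - tie_term
  z <- matrix(NA_real_, k, k, dimnames = list(rs$labels, rs$labels))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      se <- sqrt(var_base * (1 / rs$sizes[i] + 1 / rs$sizes[j]))
      z[i, j] <- z[j, i] <- abs(rs$rank_averages[i] - rs$rank_averages[j]) / se
    }
  }
  p_raw <- 2 * stats::pnorm(-z)
  C <- if (adjust == "bonferroni") k * (k - 1) / 2 else 1
  p_adj <- p_raw
  p_adj[] <- pmin(1, C * p_raw)
  structure(list(labels = rs$labels, z = z, p_raw = p_raw, p_adj = p_adj,
                 adjust = adjust, n_comparisons = k * (k - 1) / 2),
            class = "posthoc_matrix")
}

#' @export
print.posthoc_matrix <- function(x, digits = 6, ...) {
  cat(sprintf("<posthoc_matrix> Dunn z-test, %s-adjusted p-values\n",
              x$adjust))
  print(round(x$p_adj, digits), na.print = "")
  invisible(x)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on the absolute deviations `|x - center(group)|`;
#' `center = "mean"` is classic Levene, `"median"` the Brown-Forsythe
#' variant. The full decomposition (between-group SS/df/MS, residual
#' SS*/df*/MS*, F, p) is reported.
#'
#' @param sample A [grouped_sample()] with every group of size >= 2.
#' @param center `"mean"` (default) or `"median"`.
#' @return An `h2d_test` carrying `SS`, `df`, `MS` (between groups),
#'   `SS_res`, `df_res`, `MS_res` (residual), and `F = MS / MS_res`.
#' @export
levene <- function(sample, center = c("mean", "median")) {
  stopifnot(inherits(sample, "grouped_sample"))
  center <- match.arg(center)
  if (any(sample$sizes < 2L)) {
    input_error("Levene's test needs every group size >= 2")
  }
  cfun <- if (center == "mean") mean else stats::median
  centers <- tapply(sample$values, sample$groups, cfun)
  z <- abs(sample$values - centers[as.integer(sample$groups)])
  k <- nlevels(sample$groups)
  N <- length(z)
  zbar <- mean(z)
  zbar_g <- tapply(z, sample$groups, mean)
  SSB <- sum(sample$sizes * (zbar_g - zbar)^2)
  SSW <- sum((z - zbar_g[as.integer(sample$groups)])^2)
  df1 <- k - 1L
  df2 <- N - k
  MSB <- SSB / df1
  MSW <- SSW / df2
  if (MSW == 0) {
    degenerate_error("Levene F undefined: zero residual mean square")
  }
  Fstat <- MSB / MSW
  h2d_test_result(
    Fstat, stats::pf(Fstat, df1, df2, lower.tail = FALSE), c(df1, df2),
    sprintf("Levene (center = %s)", center),
    list(SS = SSB, df_between = df1, MS = MSB,
         SS_res = SSW, df_res = df2, MS_res = MSW, F = Fstat))
}

#' Shapiro-Wilk normality test
#'
#' Thin contract wrapper around the standard routine, with explicit
#' errors for the degenerate inputs that otherwise fail obscurely.
#'
#' @param values Numeric vector, 3 <= n <= 5000, not all identical.
#' @return An `h2d_test` with the W statistic and p-value.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    input_error(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (n = %d)", n))
  }
  if (length(unique(values)) == 1L) {
    degenerate_error("Shapiro-Wilk W undefined for constant input")
  }
  sw <- stats::shapiro.test(values)
  h2d_test_result(unname(sw$statistic), sw$p.value, NA_integer_,
                  "Shapiro-Wilk")
}
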