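test_that("pooled mid-ranks are conserved and ties get average ranks", {
  s <- grouped_sample(c(1, 4, 2, 3), c("a", "a", "b", "b"))
  rs <- rank_all(s)
  expect_equal(rs$rank_sums, c(5, 5))

  tied <- grouped_sample(c(1, 1, 2), c("a", "a", "b"))
  rt <- rank_all(tied)
  expect_equal(rt$rank_sums, c(3, 3))
  expect_equal(rt$tie_groups, 2L)

  # conservation sum(R_i) = N(N+1)/2 on random grouped data
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:40, 1)
    vals <- sample(1:15, n, replace = TRUE) # plenty of ties
    g <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(g)) < 2) next
    rs <- rank_all(grouped_sample(vals, g))
    expect_equal(sum(rs$rank_sums), n * (n + 1) / 2)
    expect_equal(rs$rank_averages, rs$rank_sums / rs$sizes)
  }
})

test_that("H recomputes the published three-group worked examples", {
  # N = 35 pollen design: rank sums conserve to N(N+1)/2 = 630
  expect_equal(sum(pollen_rank_sums$activity), 630)
  H <- vapply(pollen_rank_sums, function(rs)
    kruskal_wallis_from_ranks(pollen_sizes, rs)$statistic, numeric(1))
  expect_equal(unname(H), c(21.478, 19.004, 20.944), tolerance = 5e-4)

  # equal rank means give H = 0
  expect_equal(kruskal_wallis_from_ranks(c(2L, 2L), c(5, 5))$statistic, 0)
  # violated conservation is rejected
  expect_error(kruskal_wallis_from_ranks(c(3L, 3L), c(10, 20)),
               class = "hjorth2d_input_error")
})

test_that("kruskal_wallis agrees with the reference implementation and is rank-invariant", {
  for (seed in 1:10) {
    set.seed(seed)
    vals <- rnorm(30)
    g <- rep(c("a", "b", "c"), times = c(12, 8, 10))
    s <- grouped_sample(vals, g)
    got <- kruskal_wallis(s)
    ref <- stats::kruskal.test(vals, factor(g))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    # invariance under strictly increasing transforms
    tr <- kruskal_wallis(grouped_sample(exp(vals), g))
    expect_equal(tr$statistic, got$statistic, tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(grouped_sample(rep(1, 6),
                                             rep(c("a", "b"), 3))),
               class = "hjorth2d_degenerate_error")
})

test_that("exact permutation p is reproduced by brute-force enumeration", {
  vals <- c(1.2, 3.4, 0.5, 2.2, 5.1, 4.4)
  g <- rep(c("a", "b", "c"), each = 2)
  s <- grouped_sample(vals, g)
  got <- kruskal_wallis(s, method = "permutation")
  expect_equal(got$n_permutations, 90) # 6! / (2! 2! 2!)

  # independent enumeration over all 6! orderings (each assignment
  # counted 2!2!2! times, leaving the proportion unchanged)
  r <- rank(vals)
  perms <- matrix(unlist(combinat_perms(6)), ncol = 6, byrow = TRUE)
  H_of <- function(rr) {
    sums <- tapply(rr, g, sum)
    12 / (6 * 7) * sum(sums^2 / 2) - 3 * 7
  }
  H_obs <- H_of(r)
  H_all <- apply(perms, 1, function(p) H_of(r[p]))
  expect_equal(got$p, mean(H_all >= H_obs - 1e-12), tolerance = 1e-12)
  expect_equal(got$statistic, H_obs, tolerance = 1e-12)

  # the chi-square p differs from the exact one at this tiny N
  approx <- kruskal_wallis(s)
  expect_false(isTRUE(all.equal(approx$p_value, got$p)))
})

test_that("Dunn-Bonferroni recomputes every published pairwise p-value", {
  labels <- c("Brassica napus", "Helianthus", "Phacelia")
  published <- list(
    activity = c(ab = 0.098529, ac = 0.003929, bc = 0.000015),
    mobility = c(ab = 0.008313, ac = 0.122515, bc = 0.000044),
    complexity = c(ab = 0.004926, ac = 0.097518, bc = 0.000016))
  # exact integer rank sums reproduce all nine printed values to < 1e-6
  for (d in names(published)) {
    rs <- rank_summary(labels, pollen_sizes,
                       rank_sums = pollen_rank_sums[[d]])
    ph <- dunn_posthoc(rs)
    expect_equal(ph$p_adj[1, 2], published[[d]][["ab"]],
                 tolerance = 1e-5 / published[[d]][["ab"]])
    expect_equal(ph$p_adj[1, 3], published[[d]][["ac"]],
                 tolerance = 1e-5 / published[[d]][["ac"]])
    expect_equal(ph$p_adj[2, 3], published[[d]][["bc"]],
                 tolerance = 1e-5 / published[[d]][["bc"]])
  }
})

test_that("posthoc matrix is symmetric with p in (0, 1] and z = 0 for equal rank means", {
  eq <- rank_summary(c("a", "b"), c(4L, 4L), rank_averages = c(4.5, 4.5))
  ph <- dunn_posthoc(eq)
  expect_equal(ph$z[1, 2], 0)
  expect_equal(ph$p_adj[1, 2], 1)

  for (seed in 1:8) {
    set.seed(seed)
    s <- grouped_sample(rnorm(24), sample(letters[1:4], 24,
                                          replace = TRUE,
                                          prob = c(.4, .3, .2, .1)))
    ph <- dunn_posthoc(s)
    expect_equal(ph$p_adj, t(ph$p_adj))
    off <- ph$p_adj[upper.tri(ph$p_adj)]
    expect_true(all(off > 0 & off <= 1))
    expect_equal(ph$n_comparisons, choose(nlevels(s$groups), 2))
  }
})

test_that("Levene decomposition matches a hand-built one-way ANOVA", {
  s <- grouped_sample(c(1, 2, 3, 1, 5, 9), rep(c("a", "b"), each = 3))
  got <- levene(s)
  # oracle: ANOVA on |x - group mean| via lm
  z <- c(abs(c(1, 2, 3) - 2), abs(c(1, 5, 9) - 5))
  fit <- stats::anova(stats::lm(z ~ rep(c("a", "b"), each = 3)))
  expect_equal(got$SS, fit$`Sum Sq`[1], tolerance = 1e-12)
  expect_equal(got$SS_res, fit$`Sum Sq`[2], tolerance = 1e-12)
  expect_equal(got$statistic, fit$`F value`[1], tolerance = 1e-12)
  expect_equal(got$p_value, fit$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(got$df_between, 1L)
  expect_equal(got$df_res, 4L)

  # identical multisets across groups: deviation means equal, F = 0
  s2 <- grouped_sample(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(levene(s2)$statistic, 0)
  expect_equal(levene(s2)$p_value, 1)

  # median centring (Brown-Forsythe) agrees with lm oracle too
  set.seed(3)
  vals <- rexp(21)
  g <- rep(c("a", "b", "c"), each = 7)
  bf <- levene(grouped_sample(vals, g), center = "median")
  zz <- abs(vals - ave(vals, g, FUN = stats::median))
  fit2 <- stats::anova(stats::lm(zz ~ g))
  expect_equal(bf$statistic, fit2$`F value`[1], tolerance = 1e-12)

  expect_error(levene(grouped_sample(c(1, 2, 3), c("a", "a", "b"))),
               class = "hjorth2d_input_error")
})

test_that("Levene reports df = (2, 32) for the 18/8/9 design", {
  set.seed(10)
  vals <- rnorm(35)
  g <- rep(c("a", "b", "c"), times = pollen_sizes)
  got <- levene(grouped_sample(vals, g))
  expect_equal(got$df_between, 2L)
  expect_equal(got$df_res, 32L)
})

test_that("Shapiro-Wilk contract: sensitivity, specificity and degenerate inputs", {
  normal_pass <- exp_reject <- logical(200)
  for (i in 1:200) {
    set.seed(i)
    normal_pass[i] <- shapiro_wilk(rnorm(50))$p_value > 0.05
    exp_reject[i] <- shapiro_wilk(rexp(50))$p_value < 0.05
  }
  expect_gte(mean(normal_pass), 0.90)
  expect_gte(mean(exp_reject), 0.90)
  expect_error(shapiro_wilk(c(1, 2)), class = "hjorth2d_input_error")
  expect_error(shapiro_wilk(rep(3, 10)),
               class = "hjorth2d_degenerate_error")
})
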