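# brute-force two-sample KS statistic: sweep the ECDF difference over
# every observed value
ks_bruteforce <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

test_that("ks_compare matches closed cases and the ECDF sweep oracle", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(ks_compare(a, a)$D, 0)
  expect_equal(ks_compare(a, a)$p, 1)
  expect_equal(ks_compare(a, a + 100)$D, 1)
  # interleaved quartets: D = 0.25 (n >= 5 enforced, so embed in 8s)
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  y <- x + 0.5
  expect_equal(ks_compare(x, y)$D, 0.25)
  expect_equal(ks_compare(x, y)$D, ks_bruteforce(x, y))
  set.seed(31)
  for (i in 1:100) {
    x <- round(runif(sample(5:20, 1), 0, 10), 1)
    y <- round(runif(sample(5:20, 1), 0, 10), 1)
    expect_equal(ks_compare(x, y)$D, ks_bruteforce(x, y), tolerance = 1e-12)
  }
  expect_error(ks_compare(1:3, 1:10), "n >= 5")
})

test_that("pairwise KS matrix distinguishes distinct populations", {
  set.seed(32)
  same <- rlnorm(100, 0, 0.3)
  res0 <- pairwise_ks_matrix(list(a = same, b = same, c = same))
  expect_equal(res0$significant_fraction, 0)
  expect_true(isSymmetric(res0$p_matrix))
  expect_true(all(diag(res0$p_matrix) == 1))
  # 12 lines with distinct (mean, spread) profiles at n = 200:
  # nearly every pair distinguishable, mirroring high pairwise accuracy
  profiles <- expand.grid(mu = log(c(0.25, 0.45, 0.7, 1.05)),
                          sd = c(0.15, 0.35, 0.6))
  dists <- lapply(seq_len(nrow(profiles)), function(i)
    rlnorm(200, profiles$mu[i], profiles$sd[i]))
  names(dists) <- sprintf("line%02d", seq_along(dists))
  res <- pairwise_ks_matrix(dists)
  expect_gte(res$significant_fraction, 0.9)
})

test_that("kw_dunn flags exactly the shifted group", {
  set.seed(33)
  same <- rnorm(50)
  r0 <- kw_dunn(list(same, same, same))
  expect_equal(nrow(r0$significant_pairs), 0L)
  g <- list(rnorm(50), rnorm(50), rnorm(50, 2))
  r <- kw_dunn(g)
  expect_lt(r$omnibus_p, 1e-6)
  expect_equal(nrow(r$significant_pairs), 2L)
  expect_true(all(3 %in% r$significant_pairs[1, ]))
  expect_true(all(3 %in% r$significant_pairs[2, ]))
  expect_warning(rt <- kw_dunn(list(rep(1, 10), rep(1, 10))), "tied")
  expect_equal(rt$omnibus_p, 1)
  expect_error(kw_dunn(list(rnorm(3), rnorm(10))), "n >= 5")
})

test_that("Dunn z-statistics match independent arithmetic", {
  # no ties: z_ij = (Rbar_i - Rbar_j) / sqrt(N(N+1)/12 * (1/n_i + 1/n_j))
  g <- list(c(1.1, 2.2, 3.3, 4.4, 9.9), c(5.5, 6.6, 7.7, 8.8, 10.1),
            c(0.5, 2.9, 6.1, 11.3, 12.4))
  N <- 15
  r <- rank(unlist(g))
  rb <- c(mean(r[1:5]), mean(r[6:10]), mean(r[11:15]))
  z12 <- (rb[1] - rb[2]) / sqrt(N * (N + 1) / 12 * (2 / 5))
  z13 <- (rb[1] - rb[3]) / sqrt(N * (N + 1) / 12 * (2 / 5))
  res <- kw_dunn(g)
  expect_equal(res$z_matrix[1, 2], z12, tolerance = 1e-12)
  expect_equal(res$z_matrix[1, 3], z13, tolerance = 1e-12)
  # Bonferroni over the 3 pairs
  expect_equal(res$p_matrix[1, 2], min(1, 3 * 2 * pnorm(-abs(z12))),
               tolerance = 1e-12)
})

test_that("colony divergence fraction tracks clonal memory", {
  base <- make_baseline()
  founders <- unname(stats::quantile(base, c(0.05, 0.5, 0.95)))
  widely <- generate_colony_series(
    colony_synth_params(base, n_colonies = 3, founders = founders,
                        intra_colony_sd_day10 = 0.02,
                        convergence_weight_day20 = 1,
                        cells_per_colony_per_day = 30L), seed = 34)
  expect_gte(colony_divergence_fraction(widely, day = 10), 0.9)
  # null: every colony sampled from the same law
  null_ser <- generate_colony_series(
    colony_synth_params(base, n_colonies = 6,
                        founders = rep(mean(base), 6),
                        intra_colony_sd_day10 = 0.2,
                        convergence_weight_day20 = 0,
                        cells_per_colony_per_day = 30L), seed = 35)
  expect_lte(colony_divergence_fraction(null_ser, day = 10), 0.1)
  # invariant to colony ordering
  perm <- widely
  perm$colonies <- rev(perm$colonies)
  expect_equal(colony_divergence_fraction(perm, day = 10),
               colony_divergence_fraction(widely, day = 10))
})

test_that("bootstrap subset test behaves at its extremes and reproduces", {
  base <- make_baseline()
  top <- sort(base, decreasing = TRUE)[1:30]
  p_top <- bootstrap_subset_test(top, base, n_iter = 2000, seed = 1)
  expect_lte(p_top, 1 / 2001 + 1e-12)
  expect_equal(bootstrap_subset_test(base, base, n_iter = 1000, seed = 1), 1)
  expect_equal(bootstrap_subset_test(top, base, n_iter = 2000, seed = 7),
               bootstrap_subset_test(top, base, n_iter = 2000, seed = 7))
  expect_error(bootstrap_subset_test(c(base, 1), base, n_iter = 1000), "larger")
  expect_error(bootstrap_subset_test(top, base, n_iter = 10), "1000")
  # KS-distance variant available behind the flag
  p_ks <- bootstrap_subset_test(top, base, n_iter = 1000, seed = 1,
                                statistic = "ks")
  expect_lte(p_ks, 0.01)
})

test_that("convergence summary quantifies drift toward the baseline", {
  base <- make_baseline()
  founders <- unname(stats::quantile(base, seq(0.1, 0.9, by = 0.1)))
  ser <- generate_colony_series(
    colony_synth_params(base, n_colonies = 9, founders = founders,
                        intra_colony_sd_day10 = 0.05,
                        convergence_weight_day20 = 1,
                        cells_per_colony_per_day = 50L), seed = 36)
  cs <- convergence_summary(ser)
  expect_equal(nrow(cs), 9L)
  bm <- attr(cs, "baseline_mean")
  closer <- abs(cs$mean20 - bm) < abs(cs$mean10 - bm)
  expect_gte(sum(closer), 8L)
  # w = 0: day-20 spreads match day-10 spreads
  ser0 <- generate_colony_series(
    colony_synth_params(base, n_colonies = 5, intra_colony_sd_day10 = 0.1,
                        convergence_weight_day20 = 0,
                        cells_per_colony_per_day = 400L), seed = 37)
  cs0 <- convergence_summary(ser0)
  expect_true(all(abs(cs0$cv20 / cs0$cv10 - 1) < 0.2))
})

test_that("threshold split uncovers piecewise correlation structure", {
  r1 <- pearson_with_split(x = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           y = 2 * c(0.1, 0.3, 0.5, 0.7, 0.9) + 1)
  expect_equal(r1$overall_r, 1, tolerance = 1e-12)
  expect_error(pearson_with_split(rep(0.5, 5), 1:5), "zero-variance")
  # independent x, y: mean r near 0 over simulations
  set.seed(38)
  rs <- replicate(500, pearson_with_split(runif(11), rnorm(11))$overall_r)
  expect_lt(abs(mean(rs)), 0.05)
  # piecewise-linear phenotype with a break at 0.4: group r beats overall
  set.seed(39)
  x <- c(runif(6, 0.05, 0.35), runif(6, 0.45, 1.1))
  y <- ifelse(x < 0.4, 5 * x, 2 - 1.5 * x) + rnorm(12, 0, 0.05)
  names(x) <- names(y) <- sprintf("line%d", 1:12)
  rep <- pearson_with_split(x, y, threshold = 0.4)
  expect_setequal(rep$members_low, sprintf("line%d", 1:6))
  expect_gt(abs(rep$group_low_r), abs(rep$overall_r))
  expect_gt(abs(rep$group_high_r), abs(rep$overall_r))
})
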