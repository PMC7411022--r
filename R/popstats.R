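#' Score distribution summary container
#'
#' @param population_id identifier.
#' @param scores numeric vector of (normalized) scores, n >= 2.
#' @return a `score_distribution` with `n`, `mean`, `sd` and `cv`
#'   (sd/mean, defined for positive mean).
#' @export
score_distribution <- function(population_id, scores) {
  scores <- as.numeric(scores)
  stopifnot(length(scores) >= 2, all(is.finite(scores)))
  m <- mean(scores); s <- stats::sd(scores)
  structure(list(population_id = population_id, scores = scores,
                 n = length(scores), mean = m, sd = s,
                 cv = if (m > 0) s / m else NA_real_),
            class = "score_distribution")
}

as_scores <- function(x) {
  if (inherits(x, "score_distribution")) x$scores else as.numeric(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares the full shapes of two score distributions (not just their
#' means). Exact p-values are used when `n * m <= 1e4`, the asymptotic
#' approximation otherwise.
#'
#' @param a,b `score_distribution`s or numeric vectors, each n >= 5.
#' @return list with `D` (KS statistic) and `p`.
#' @export
ks_compare <- function(a, b) {
  x <- as_scores(a); y <- as_scores(b)
  if (length(x) < 5 || length(y) < 5)
    stop("ks_compare(): both samples need n >= 5")
  exact <- length(x) * length(y) <= 1e4
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Pairwise KS matrix over populations
#'
#' Tests every unordered pair of distributions and reports the fraction
#' of pairs significant after multiple-testing correction — the package's
#' operationalization of "how distinguishable are these populations by
#' their score distributions".
#'
#' @param distributions named list of `score_distribution`s / vectors.
#' @param alpha significance level after correction.
#' @param correction a `p.adjust` method (default `"bonferroni"`).
#' @return list with `p_matrix` (raw p, symmetric, unit diagonal),
#'   `p_adjusted`, `significant_fraction` and `significant_pairs`.
#' @export
pairwise_ks_matrix <- function(distributions, alpha = 0.05,
                               correction = "bonferroni") {
  k <- length(distributions)
  stopifnot(k >= 2)
  ids <- names(distributions)
  if (is.null(ids)) ids <- sprintf("pop%d", seq_len(k))
  p <- matrix(1, k, k, dimnames = list(ids, ids))
  pairs <- utils::combn(k, 2)
  praw <- apply(pairs, 2, function(ij)
    ks_compare(distributions[[ij[1]]], distributions[[ij[2]]])$p)
  padj <- stats::p.adjust(praw, method = correction)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    p[i1, i2] <- p[i2, i1] <- praw[j]
  }
  sig <- padj < alpha
  list(p_matrix = p, p_adjusted = padj,
       significant_fraction = mean(sig),
       significant_pairs = cbind(ids[pairs[1, sig]], ids[pairs[2, sig]]))
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Nonparametric k-group comparison suited to the skewed, non-Gaussian
#' score distributions: Kruskal-Wallis omnibus (via [stats::kruskal.test])
#' followed by Dunn's pairwise z-tests on the pooled rank means with the
#' standard tie correction, Bonferroni-adjusted over the pairs.
#'
#' @param groups list of numeric score vectors (>= 2 groups, each n >= 5).
#' @param alpha significance level for the adjusted pairwise p-values.
#' @param p_adjust adjustment method over pairs (default `"bonferroni"`).
#' @return list with `omnibus_p`, `p_matrix` (Dunn adjusted p, symmetric),
#'   `z_matrix`, `significant_pairs` (2-column matrix of group indices)
#'   and `n_pairs`.
#' @export
kw_dunn <- function(groups, alpha = 0.05, p_adjust = "bonferroni") {
  k <- length(groups)
  stopifnot(k >= 2)
  n <- vapply(groups, length, integer(1))
  if (any(n < 5)) stop("kw_dunn(): every group needs n >= 5")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), n))
  if (length(unique(x)) == 1L) {
    warning("kw_dunn(): all observations tied; omnibus p = 1")
    pm <- matrix(1, k, k)
    return(list(omnibus_p = 1, p_matrix = pm, z_matrix = matrix(0, k, k),
                significant_pairs = matrix(integer(0), 0, 2), n_pairs = choose(k, 2)))
  }
  omnibus <- stats::kruskal.test(x, g)$p.value

  # Dunn pairwise z on pooled ranks with tie correction
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- p <- matrix(NA_real_, k, k)
  diag(p) <- 1; diag(z) <- 0
  praw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i1] + 1 / n[i2]))
    zj <- (rbar[i1] - rbar[i2]) / se
    z[i1, i2] <- z[i2, i1] <- zj
    praw[j] <- 2 * stats::pnorm(-abs(zj))
  }
  padj <- stats::p.adjust(praw, method = p_adjust)
  for (j in seq_len(ncol(pairs))) {
    p[pairs[1, j], pairs[2, j]] <- p[pairs[2, j], pairs[1, j]] <- padj[j]
  }
  sig <- which(padj < alpha)
  list(omnibus_p = omnibus, p_matrix = p, z_matrix = z,
       significant_pairs = t(pairs[, sig, drop = FALSE]),
       n_pairs = ncol(pairs))
}

#' Fraction of colony pairs with significantly different scores
#'
#' Quantifies clonal memory: right after expansion most colony pairs
#' differ (founders carried different phenotypes); as colonies drift back
#' to the population distribution the fraction drops. Pairs are compared
#' with Dunn's post hoc test after a Kruskal-Wallis omnibus over all
#' colonies at the chosen day.
#'
#' @param series a `colony_series` from [generate_colony_series()] (or a
#'   compatible list).
#' @param day 10 or 20.
#' @param alpha significance level for adjusted pairwise p-values.
#' @return fraction in \[0, 1\] of unordered colony pairs significantly
#'   different.
#' @export
colony_divergence_fraction <- function(series, day = 10, alpha = 0.05) {
  stopifnot(day %in% c(10, 20), length(series$colonies) >= 2)
  field <- if (day == 10) "day10" else "day20"
  groups <- lapply(series$colonies, `[[`, field)
  kd <- kw_dunn(groups, alpha = alpha)
  nrow(kd$significant_pairs) / kd$n_pairs
}

#' Bootstrap subset-confidence test for a colony
#'
#' Can the colony's scores be read as a random subset of the unsorted
#' population? The null resamples subsets of the colony's size without
#' replacement from the baseline; the statistic is the absolute
#' difference between subset mean and baseline mean. The p-value uses the
#' add-one convention `(k + 1) / (n_iter + 1)` so it is never exactly
#' zero. The colony is declared "not a random subset" at confidence `c`
#' when `p < 1 - c` (the study used c = 0.995).
#'
#' @param colony numeric score vector of the colony.
#' @param baseline numeric score vector of the unsorted population
#'   (`length(colony) <= length(baseline)`).
#' @param n_iter number of null draws (>= 1000; default 10000).
#' @param seed integer seed for the resampling.
#' @param statistic `"mean"` (absolute mean difference, default) or
#'   `"ks"` (KS distance to the baseline).
#' @return the bootstrap p-value.
#' @export
bootstrap_subset_test <- function(colony, baseline, n_iter = 10000L,
                                  seed = 1L, statistic = c("mean", "ks")) {
  statistic <- match.arg(statistic)
  colony <- as_scores(colony); baseline <- as_scores(baseline)
  if (length(colony) > length(baseline))
    stop("bootstrap_subset_test(): colony larger than baseline")
  if (n_iter < 1000) stop("bootstrap_subset_test(): n_iter must be >= 1000")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  m <- length(colony)
  stat_fun <- if (statistic == "mean") {
    bm <- mean(baseline)
    function(v) abs(mean(v) - bm)
  } else {
    function(v) suppressWarnings(
      stats::ks.test(v, baseline, exact = FALSE)$statistic)
  }
  obs <- stat_fun(colony)
  null <- vapply(seq_len(n_iter), function(i)
    stat_fun(baseline[sample.int(length(baseline), m)]), numeric(1))
  (sum(null >= obs) + 1) / (n_iter + 1)
}

#' Per-colony convergence summary between day 10 and day 20
#'
#' Tabulates each colony's mean and coefficient of variation at both time
#' points, to quantify the convergence of colony means toward the
#' baseline mean and the simultaneous broadening of their spreads.
#'
#' @param series a `colony_series`.
#' @return data.frame (one row per colony) with columns `colony_id`,
#'   `founder`, `mean10`, `mean20`, `cv10`, `cv20`; attributes
#'   `baseline_mean`, `max_abs_dev20` (max |mean20 - baseline mean|) and
#'   `cv_ratio_range` (range of cv20/cv10).
#' @export
convergence_summary <- function(series) {
  rows <- lapply(series$colonies, function(col) {
    data.frame(colony_id = col$colony_id, founder = col$founder,
               mean10 = mean(col$day10), mean20 = mean(col$day20),
               cv10 = stats::sd(col$day10) / mean(col$day10),
               cv20 = stats::sd(col$day20) / mean(col$day20),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bm <- mean(series$baseline)
  attr(out, "baseline_mean") <- bm
  attr(out, "max_abs_dev20") <- max(abs(out$mean20 - bm))
  attr(out, "cv_ratio_range") <- range(out$cv20 / out$cv10)
  out
}

#' Population-level Pearson correlation with a threshold split
#'
#' Correlates per-population mean normalized scores with a phenotype
#' (e.g. EMT score or migration speed), overall and within the two groups
#' obtained by splitting the populations at a score threshold (default
#' 0.4, the split separating slow from fast migrating lines). A group
#' contributes a correlation only when it has at least 3 members.
#'
#' @param x per-population mean normalized scores (named).
#' @param y per-population phenotype values, same order/names.
#' @param threshold score threshold for the split (default 0.4).
#' @return a `correlation_report`: `overall_r`, `overall_p`,
#'   `group_low_r`, `group_high_r` (`NA` when undersized), `threshold`
#'   and the group memberships.
#' @export
pearson_with_split <- function(x, y, threshold = 0.4) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_with_split(): zero-variance input, correlation undefined")
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("pop%d", seq_along(x))
  ct <- stats::cor.test(x, y)
  low <- x < threshold
  grp_r <- function(sel) {
    if (sum(sel) < 3) return(NA_real_)
    if (stats::sd(x[sel]) == 0 || stats::sd(y[sel]) == 0) return(NA_real_)
    stats::cor(x[sel], y[sel])
  }
  structure(list(overall_r = unname(ct$estimate), overall_p = ct$p.value,
                 group_low_r = grp_r(low), group_high_r = grp_r(!low),
                 threshold = threshold,
                 members_low = ids[low], members_high = ids[!low]),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("overall Pearson r = %.3f (p = %.3g); split at %.2f:\n",
              x$overall_r, x$overall_p, x$threshold))
  cat(sprintf("  low group (n=%d): r = %.3f\n", length(x$members_low),
              x$group_low_r))
  cat(sprintf("  high group (n=%d): r = %.3f\n", length(x$members_high),
              x$group_high_r))
  invisible(x)
}
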