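#' Rank descriptors by their power to separate populations
#'
#' Trains a Random-Forest classifier on the standardized descriptor
#' matrix against population labels and reports normalized impurity
#' importances (summing to 1), the out-of-bag accuracy, and a 2D t-SNE
#' embedding of the standardized matrix for visualization. Constant
#' descriptors are excluded from the fit with a message. Deterministic
#' under a fixed seed.
#'
#' @param descriptors data.frame or matrix, one row per cell, descriptor
#'   columns (identical names across cells).
#' @param labels population labels, one per row (>= 2 populations,
#'   >= 20 cells each).
#' @param seed integer seed.
#' @param n_trees random-forest size.
#' @param perplexity t-SNE perplexity.
#' @return a `feature_ranking`: `importances` (named, sums to 1),
#'   `classifier_oob_accuracy`, `embedding` (cells x 2), `labels`,
#'   `excluded_constant` (descriptor names dropped).
#' @export
rank_descriptors <- function(descriptors, labels, seed = 1L,
                             n_trees = 500L, perplexity = 10) {
  X <- as.matrix(descriptors)
  labels <- factor(labels)
  stopifnot(nrow(X) == length(labels))
  if (nlevels(labels) < 2) stop("rank_descriptors(): need >= 2 populations")
  if (any(table(labels) < 20))
    stop("rank_descriptors(): need >= 20 cells per population")
  if (anyNA(X) || any(!is.finite(X)))
    stop("rank_descriptors(): descriptors must be finite")
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const))
    message("rank_descriptors(): excluding constant descriptor(s): ",
            paste(colnames(X)[const], collapse = ", "))
  X <- X[, !const, drop = FALSE]
  Xs <- scale(X)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(Xs, labels, ntree = n_trees)
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  oob <- 1 - rf$err.rate[nrow(rf$err.rate), "OOB"]
  emb <- tsne_embed(Xs, perplexity = perplexity,
                    seed = as.integer(seed) + 1L)
  structure(list(importances = imp,
                 classifier_oob_accuracy = unname(oob),
                 embedding = emb, labels = labels,
                 excluded_constant = colnames(as.matrix(descriptors))[const]),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking: OOB accuracy %.3f; top descriptors:\n",
              x$classifier_oob_accuracy))
  top <- sort(x$importances, decreasing = TRUE)[seq_len(min(5, length(x$importances)))]
  for (nm in names(top)) cat(sprintf("  %-24s %.3f\n", nm, top[nm]))
  invisible(x)
}

#' Exact t-SNE embedding
#'
#' Compact exact (non-Barnes-Hut) t-distributed stochastic neighbor
#' embedding, adequate for the few hundred cells of a typical run:
#' per-point bandwidths matched to the target perplexity by bisection,
#' early exaggeration, and momentum gradient descent. Deterministic
#' under a fixed seed.
#'
#' @param X numeric matrix (rows = points), already standardized.
#' @param perplexity effective number of neighbors.
#' @param n_iter gradient-descent iterations.
#' @param seed integer seed for the initialization.
#' @return points x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(X, perplexity = 10, n_iter = 300L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("tsne_embed(): need >= 4 points")
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2

  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) }
      else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else { betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5; eta <- 100
  Pex <- P * 4   # early exaggeration
  for (it in seq_len(n_iter)) {
    Puse <- if (it <= 100) Pex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    if (it == 20) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
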