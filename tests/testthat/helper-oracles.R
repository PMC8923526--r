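# Independent oracles and small fixtures shared across tests.

# A small, fast synthetic study for smoke-level tests.
small_spec <- function(seed = 1, ...) {
  args <- list(n_weeks = 2, timepoints_per_day = 4, replicates = 1,
               cultivars = c("A", "B"), m_metabolites = 24, n_undetected = 6,
               n_blocks = 4, n_signal_blocks = 2, support_indices = 1:6,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_spec, args)
}

# Cophenetic distance matrix by explicit traversal of the merge tree:
# the height at which each pair of leaves first joins a common cluster.
# Independent of stats::cophenetic.
coph_oracle <- function(dend) {
  hc <- dend$hclust
  n <- nrow(hc$merge) + 1L
  D <- matrix(0, n, n)
  members <- vector("list", nrow(hc$merge))
  leaves <- function(x, k) if (x < 0) -x else members[[x]]
  for (k in seq_len(nrow(hc$merge))) {
    a <- leaves(hc$merge[k, 1], k)
    b <- leaves(hc$merge[k, 2], k)
    for (i in a) for (j in b) D[i, j] <- D[j, i] <- hc$height[k]
    members[[k]] <- c(a, b)
  }
  dimnames(D) <- list(hc$labels, hc$labels)
  D
}

# Brute-force chi-square distances between the row profiles of a
# nonnegative table (the distances CA row coordinates must reproduce).
chisq_row_distances <- function(x) {
  P <- x / sum(x)
  r <- rowSums(P)
  cmass <- colSums(P)
  prof <- P / r
  n <- nrow(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((prof[i, ] - prof[j, ])^2 / cmass))
  D
}

# Closed-form LASSO by enumeration of sign patterns (m small): for every
# support/sign assignment solve the stationarity system with an unpenalized
# intercept and keep solutions whose signs are self-consistent; the best
# consistent objective is the global optimum.
lasso_enumeration_oracle <- function(X, y, alpha) {
  n <- nrow(X); m <- ncol(X)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), m)))
  best <- Inf
  for (p in seq_len(nrow(patterns))) {
    s <- patterns[p, ]
    A <- which(s != 0)
    if (length(A) == 0) {
      w <- numeric(m); w0 <- mean(y)
    } else {
      Xa <- scale(X[, A, drop = FALSE], scale = FALSE)
      yc <- y - mean(y)
      wa <- tryCatch(solve(crossprod(Xa) / n,
                           crossprod(Xa, yc) / n - alpha * s[A]),
                     error = function(e) NULL)
      if (is.null(wa)) next
      if (!all(sign(wa) == s[A])) next
      w <- numeric(m); w[A] <- wa
      w0 <- mean(y) - sum(colMeans(X[, A, drop = FALSE]) * wa)
    }
    r <- y - w0 - drop(X %*% w)
    obj <- sum(r^2) / (2 * n) + alpha * sum(abs(w))
    # check the zero coordinates satisfy the subgradient bound
    g <- drop(crossprod(X, r)) / n
    if (any(abs(g[s == 0]) > alpha + 1e-9)) next
    if (obj < best) best <- obj
  }
  best
}

lasso_objective_of <- function(X, y, w, w0, alpha) {
  sum((y - w0 - drop(X %*% w))^2) / (2 * length(y)) + alpha * sum(abs(w))
}

# A reduced three-greenhouse pipeline configuration for fast end-to-end runs.
tiny_config <- function(seed = 1) {
  default_config(
    synthetic = list(
      seed = seed, n_weeks = 2, timepoints_per_day = 6, replicates = 1,
      cultivars = c("A", "B"), m_metabolites = 30, n_undetected = 5,
      n_blocks = 4, n_signal_blocks = 2, support_indices = 1:8,
      experiments = data.frame(label = c("TK", "IA1", "IA2"),
                               shift = c(0, 0.5, 0.9),
                               design = c("timeseries", "snapshot",
                                          "snapshot"))),
    model = list(grid_length = 12, k = 5, seed = 7))
}

random_nonneg_table <- function(n, m) {
  matrix(stats::rexp(n * m) + 0.05, n, m,
         dimnames = list(paste0("r", seq_len(n)), paste0("c", seq_len(m))))
}
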