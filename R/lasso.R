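#' Soft-thresholding operator
#'
#' Proximal operator of the L1 norm: `sign(z) * max(|z| - gamma, 0)`. This is
#' the elementary update inside coordinate-descent LASSO.
#'
#' @param z Numeric vector.
#' @param gamma Nonnegative threshold.
#' @return Numeric vector of the same length as `z`.
#' @export
#' @examples
#' soft_threshold(c(-2, 0.5, 2), 0.5)
soft_threshold <- function(z, gamma) {
  stopifnot(is.numeric(z), is.numeric(gamma), all(gamma >= 0))
  sign(z) * pmax(abs(z) - gamma, 0)
}

check_design <- function(X, y) {
  X <- as.matrix(X)
  if (!is.numeric(X) || !is.numeric(y)) stop("X and y must be numeric")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 2L) stop("need at least two samples")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite entries in the design matrix or response")
  X
}

lasso_objective <- function(X, y, w, w0, alpha) {
  r <- y - w0 - drop(X %*% w)
  sum(r^2) / (2 * length(y)) + alpha * sum(abs(w))
}

#' Fit a LASSO linear model by cyclic coordinate descent
#'
#' Minimizes `(1/2n) * ||y - w0 - X w||^2 + alpha * ||w||_1` with an
#' unpenalized intercept `w0`. Columns of `X` are used as supplied; build `X`
#' from standardized metabolite profiles (see [standardize_profiles()]) to
#' match the intended use, where coefficients are in rate units per z-score.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Numeric response (anthesis rate, flowers per week).
#' @param alpha Nonnegative penalty constant.
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   sweep.
#' @param max_sweeps Maximum number of coordinate-descent sweeps.
#' @return An object of class `lasso_fit`: list with `w` (named
#'   coefficients), `w0` (intercept), `alpha`, `n_sweeps`, `converged`,
#'   `objective_value`.
#' @seealso [lasso_prox_reference()] for an independent minimizer of the same
#'   objective, [kkt_residual()] for an optimality check.
#' @export
fit_lasso <- function(X, y, alpha, tol = 1e-7, max_sweeps = 1e5) {
  X <- check_design(X, y)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a single nonnegative number")
  res <- .lasso_cd_path(X, y, alpha, tol, as.integer(max_sweeps))
  if (!res$converged[1])
    warning("coordinate descent did not converge in ", max_sweeps, " sweeps")
  structure(list(
    w = setNames(res$w[, 1], colnames(X)),
    w0 = res$w0[1],
    alpha = alpha,
    n_sweeps = res$n_sweeps[1],
    converged = res$converged[1],
    objective_value = res$objective[1]
  ), class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("LASSO fit: alpha =", format(x$alpha),
      "| nonzero coefficients:", sum(x$w != 0), "of", length(x$w),
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Predict from a LASSO fit
#'
#' @param object A `lasso_fit`.
#' @param newx Feature matrix with the same columns as the training matrix.
#' @param ... Unused.
#' @return Numeric vector `w0 + newx %*% w`.
#' @export
predict.lasso_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$w))
    stop("newx has ", ncol(newx), " columns but the model has ",
         length(object$w), " coefficients")
  drop(object$w0 + newx %*% object$w)
}

#' Coefficient-of-determination and mean squared error
#'
#' `r2_score()` computes `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`;
#' `mse()` computes `mean((y - yhat)^2)`.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return A single number.
#' @export
r2_score <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("y has zero variance; R^2 is undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' @rdname r2_score
#' @export
mse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  mean((y - yhat)^2)
}

#' Maximum KKT residual of a LASSO solution
#'
#' At the minimizer of the objective, the feature-residual correlations
#' `g_j = (1/n) x_j' (y - w0 - X w)` satisfy `|g_j| <= alpha` for `w_j = 0`
#' and `g_j = alpha * sign(w_j)` otherwise. Returns the largest violation.
#'
#' @param fit A `lasso_fit`.
#' @inheritParams fit_lasso
#' @return The maximum KKT violation (0 at an exact optimum).
#' @export
kkt_residual <- function(fit, X, y) {
  X <- check_design(X, y)
  n <- length(y)
  g <- drop(crossprod(X, y - fit$w0 - drop(X %*% fit$w))) / n
  active <- fit$w != 0
  viol_zero <- if (any(!active)) max(pmax(abs(g[!active]) - fit$alpha, 0)) else 0
  viol_act <- if (any(active)) max(abs(g[active] - fit$alpha * sign(fit$w[active]))) else 0
  max(viol_zero, viol_act, abs(mean(y - fit$w0 - drop(X %*% fit$w))))
}

#' Reference LASSO minimizer by accelerated proximal gradient
#'
#' An independent long-run FISTA minimizer of the same objective as
#' [fit_lasso()], used to validate the coordinate-descent implementation.
#' The intercept is carried as an extra unpenalized coordinate; the step size
#' is `1/L` with `L` the largest eigenvalue of the augmented Gram matrix.
#' Slower but algorithmically unrelated to coordinate descent.
#'
#' @inheritParams fit_lasso
#' @param max_iter Maximum number of proximal-gradient iterations.
#' @param tol Stop when the maximum parameter change falls below this value.
#' @return A list with `w`, `w0`, `alpha`, `objective_value`, `n_iter`.
#' @export
lasso_prox_reference <- function(X, y, alpha, max_iter = 2e5, tol = 1e-13) {
  X <- check_design(X, y)
  n <- nrow(X)
  Z <- cbind(1, X)
  G <- crossprod(Z) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  zty <- drop(crossprod(Z, y)) / n
  theta <- c(mean(y), numeric(ncol(X)))
  v <- theta
  tk <- 1
  it <- 0L
  for (it in seq_len(max_iter)) {
    grad <- drop(G %*% v) - zty
    theta_new <- v - grad / L
    theta_new[-1] <- soft_threshold(theta_new[-1], alpha / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    v <- theta_new + ((tk - 1) / t_new) * (theta_new - theta)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    tk <- t_new
    if (delta < tol) break
  }
  w <- setNames(theta[-1], colnames(X))
  list(w = w, w0 = theta[1], alpha = alpha,
       objective_value = lasso_objective(X, y, w, theta[1], alpha),
       n_iter = it)
}

#' Deterministic shuffled k-fold assignments
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffle; the caller's RNG state
#'   is left untouched.
#' @return Integer vector of fold labels in `1:k`.
#' @export
fold_assignments <- function(n, k, seed) {
  if (k > n) stop("k must not exceed the number of samples")
  if (k < 2) stop("k must be at least 2")
  local_seed(seed, rep_len(seq_len(k), n)[sample.int(n)])
}

#' k-fold cross-validation of a LASSO fit
#'
#' Fits on k-1 folds and predicts the held-out fold; the reported `cv_r2` and
#' `cv_mse` are computed on the pooled out-of-fold predictions. Per-fold
#' metrics are also returned. By default the features are used as supplied
#' (standardization done once on the full data); `fold_safe = TRUE`
#' re-standardizes within each training fold and applies those parameters to
#' the held-out fold.
#'
#' @inheritParams fit_lasso
#' @param k Number of folds.
#' @param seed Seed for the fold shuffle.
#' @param fold_safe Re-standardize inside each training fold.
#' @return List with `cv_r2`, `cv_mse`, `predictions`, `folds`, `per_fold`.
#' @export
kfold_cv <- function(X, y, alpha, k = 10, seed = 1, tol = 1e-7,
                     max_sweeps = 1e5, fold_safe = FALSE) {
  X <- check_design(X, y)
  folds <- fold_assignments(nrow(X), k, seed)
  pred <- numeric(length(y))
  per_fold <- data.frame(fold = seq_len(k), r2 = NA_real_, mse = NA_real_)
  for (f in seq_len(k)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (fold_safe) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, sd_pop)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    fit <- fit_lasso(Xtr, y[!test], alpha, tol, max_sweeps)
    pred[test] <- predict(fit, Xte)
    per_fold$mse[f] <- mse(y[test], pred[test])
    per_fold$r2[f] <- if (sd_pop(y[test]) > 0) r2_score(y[test], pred[test]) else NA_real_
  }
  list(cv_r2 = r2_score(y, pred), cv_mse = mse(y, pred),
       predictions = pred, folds = folds, per_fold = per_fold)
}

#' Logarithmically spaced penalty grid
#'
#' @param alpha_min,alpha_max Grid endpoints.
#' @param length Number of grid points.
#' @return Numeric vector, increasing.
#' @export
lasso_alpha_grid <- function(alpha_min = 5e-5, alpha_max = 0.5, length = 50) {
  stopifnot(alpha_min > 0, alpha_max > alpha_min, length >= 2)
  exp(seq(log(alpha_min), log(alpha_max), length.out = length))
}

#' Penalty sweep with cross-validation
#'
#' Fits the full regularization path by warm-started coordinate descent along
#' descending penalties and records, for every `alpha`, the training R^2 and
#' 10-fold cross-validated R^2 and MSE, plus the size and identity of the
#' nonzero-coefficient support.
#'
#' @inheritParams kfold_cv
#' @param alpha_grid Vector of positive penalties (any order).
#' @return A data frame of class `lasso_sweep` with columns `alpha`,
#'   `train_r2`, `cv_r2`, `cv_mse`, `support_size`, and a `support_ids`
#'   list-column. The full coefficient path is attached as attributes
#'   `coefficients` (features x alphas) and `intercepts`.
#' @export
alpha_sweep <- function(X, y, alpha_grid = lasso_alpha_grid(), k = 10,
                        seed = 1, tol = 1e-7, max_sweeps = 1e5,
                        fold_safe = FALSE) {
  X <- check_design(X, y)
  if (length(alpha_grid) == 0) stop("alpha_grid is empty")
  if (any(alpha_grid <= 0)) stop("alpha_grid must be positive")
  alphas <- sort(unique(alpha_grid), decreasing = TRUE)
  ids <- colnames(X) %||% paste0("f", seq_len(ncol(X)))

  path <- .lasso_cd_path(X, y, alphas, tol, as.integer(max_sweeps))
  train_r2 <- vapply(seq_along(alphas), function(a) {
    r2_score(y, path$w0[a] + drop(X %*% path$w[, a]))
  }, numeric(1))

  folds <- fold_assignments(nrow(X), k, seed)
  pred <- matrix(NA_real_, length(y), length(alphas))
  for (f in seq_len(k)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (fold_safe) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, sd_pop)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    # fold solutions sit close to the full-data path at the same penalty,
    # so start each fold fit there rather than at the previous penalty
    fp <- .lasso_cd_path(Xtr, y[!test], alphas, tol, as.integer(max_sweeps),
                         if (!fold_safe) path$w, if (!fold_safe) path$w0)
    pred[test, ] <- sweep(Xte %*% fp$w, 2, fp$w0, "+")
  }
  cv_r2 <- apply(pred, 2, function(p) r2_score(y, p))
  cv_mse <- apply(pred, 2, function(p) mse(y, p))

  support <- lapply(seq_along(alphas), function(a) ids[path$w[, a] != 0])
  out <- data.frame(alpha = alphas, train_r2 = train_r2, cv_r2 = cv_r2,
                    cv_mse = cv_mse,
                    support_size = vapply(support, length, integer(1)))
  out$support_ids <- I(support)
  rownames(path$w) <- ids
  attr(out, "coefficients") <- path$w
  attr(out, "intercepts") <- path$w0
  attr(out, "converged") <- path$converged
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  class(out) <- c("lasso_sweep", "data.frame")
  out
}

sweep_pick <- function(sweep, idx) {
  structure(list(
    alpha = sweep$alpha[idx],
    support_ids = sweep$support_ids[[idx]],
    support_size = sweep$support_size[idx],
    train_r2 = sweep$train_r2[idx],
    cv_r2 = sweep$cv_r2[idx],
    cv_mse = sweep$cv_mse[idx],
    w = attr(sweep, "coefficients")[, idx],
    w0 = attr(sweep, "intercepts")[idx]
  ), class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat("Selected model: alpha =", format(x$alpha),
      "| support =", x$support_size,
      "| train R2 =", round(x$train_r2, 3),
      "| CV R2 =", round(x$cv_r2, 3),
      "| CV MSE =", signif(x$cv_mse, 3), "\n")
  invisible(x)
}

#' Elbow selection of the predictor panel
#'
#' Operationalizes the graphical elbow rule: among all sweep records whose
#' cross-validated R^2 is within `tol` of the best cross-validated R^2,
#' return the one with the smallest support (ties broken toward the larger
#' penalty). The returned record's `support_ids` are the predictor
#' metabolites.
#'
#' @param sweep A `lasso_sweep`.
#' @param tol Tolerance below the maximum cross-validated R^2.
#' @return A `lasso_selection` (alpha, support, metrics, coefficients).
#' @export
select_elbow <- function(sweep, tol = 0.02) {
  ok <- is.finite(sweep$cv_r2)
  if (!any(ok)) stop("no finite cross-validated R^2 in the sweep")
  cv_best <- max(sweep$cv_r2[ok])
  cand <- which(ok & sweep$cv_r2 >= cv_best - tol)
  cand <- cand[order(sweep$support_size[cand], -sweep$alpha[cand])]
  sweep_pick(sweep, cand[1])
}

#' Minimum cross-validated-MSE selection
#'
#' @param sweep A `lasso_sweep`.
#' @return A `lasso_selection` at the penalty with the smallest
#'   cross-validated MSE (ties toward larger penalty).
#' @export
select_min_cv_mse <- function(sweep) {
  ok <- is.finite(sweep$cv_mse)
  if (!any(ok)) stop("no finite cross-validated MSE in the sweep")
  cand <- which(ok)
  cand <- cand[order(sweep$cv_mse[cand], -sweep$alpha[cand])]
  sweep_pick(sweep, cand[1])
}

#' Re-fit a predictor panel on combined multi-experiment data
#'
#' Restricts each dataset to the panel columns, standardizes each dataset
#' separately (population SD), row-concatenates them, and re-runs the penalty
#' sweep; the final model is the sweep record with the minimum
#' cross-validated MSE.
#'
#' @param panel_ids Character vector of panel feature names; must be present
#'   in every dataset.
#' @param matrices List of numeric matrices (samples x features) with column
#'   names.
#' @param rates List of response vectors matching `matrices` row counts.
#' @param standardize_per_dataset Standardize within each dataset before
#'   concatenation (default) or globally afterwards.
#' @inheritParams alpha_sweep
#' @return List with `selection` (a `lasso_selection`), `sweep`, and the
#'   combined design `X`, `y`.
#' @export
refit_panel <- function(panel_ids, matrices, rates,
                        standardize_per_dataset = TRUE,
                        alpha_grid = lasso_alpha_grid(), k = 10, seed = 1,
                        tol = 1e-7, max_sweeps = 1e5) {
  stopifnot(is.list(matrices), is.list(rates),
            length(matrices) == length(rates))
  parts <- lapply(seq_along(matrices), function(i) {
    m <- as.matrix(matrices[[i]])
    missing <- setdiff(panel_ids, colnames(m))
    if (length(missing))
      stop("panel feature(s) missing in dataset ", i, ": ",
           paste(missing, collapse = ", "))
    m <- m[, panel_ids, drop = FALSE]
    if (standardize_per_dataset) m <- standardize_profiles(m)
    m
  })
  X <- do.call(rbind, parts)
  if (!standardize_per_dataset) X <- standardize_profiles(X)
  y <- unlist(rates, use.names = FALSE)
  sweep <- alpha_sweep(X, y, alpha_grid = alpha_grid, k = k, seed = seed,
                       tol = tol, max_sweeps = max_sweeps)
  list(selection = select_min_cv_mse(sweep), sweep = sweep, X = X, y = y)
}
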