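test_that("soft thresholding matches its closed form", {
  expect_equal(soft_threshold(0.5, 1.0), 0)
  expect_equal(soft_threshold(2.0, 0.5), 1.5)
  expect_equal(soft_threshold(-2.0, 0.5), -1.5)
  z <- seq(-3, 3, by = 0.25)
  expect_equal(soft_threshold(z, 0.7), sign(z) * pmax(abs(z) - 0.7, 0))
})

test_that("penalties at or above the null threshold give the empty model", {
  set.seed(11)
  X <- scale(matrix(rnorm(200), 40, 5))[, ]
  y <- rnorm(40, 5)
  alpha_max <- max(abs(crossprod(X, y - mean(y)) / nrow(X)))
  fit <- fit_lasso(X, y, alpha_max * 1.000001)
  expect_true(all(fit$w == 0))
  expect_equal(fit$w0, mean(y))
  # just below the threshold at least one coefficient activates
  fit2 <- fit_lasso(X, y, alpha_max * 0.99)
  expect_gt(sum(fit2$w != 0), 0)
})

test_that("the unpenalized limit recovers ordinary least squares", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(40 * 4), 40, 4)
    y <- drop(X %*% c(1, -2, 0.5, 3)) + rnorm(40)
    fit <- fit_lasso(X, y, 0)
    ols <- lm(y ~ X)
    expect_equal(unname(fit$w), unname(coef(ols)[-1]), tolerance = 1e-6)
    expect_equal(fit$w0, unname(coef(ols)[1]), tolerance = 1e-6)
  }
  # single standardized column, exact linear response
  set.seed(1)
  x <- scale(rnorm(30))[, ]
  y <- 2 * x + 7
  fit <- fit_lasso(matrix(x), y, 0)
  expect_equal(unname(fit$w), 2, tolerance = 1e-7)
  expect_equal(fit$w0, 7, tolerance = 1e-7)
})

test_that("coordinate descent agrees with the proximal-gradient reference", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(20 * 5), 20, 5)
    y <- drop(X %*% rnorm(5)) + rnorm(20)
    for (alpha in c(0.05, 0.3)) {
      cd <- fit_lasso(X, y, alpha)
      ref <- lasso_prox_reference(X, y, alpha)
      expect_lt(abs(cd$objective_value - ref$objective_value), 1e-8)
      expect_lt(kkt_residual(cd, X, y), 1e-6)
    }
  }
})

test_that("the solution objective matches sign-pattern enumeration (m = 3)", {
  for (s in 1:6) {
    set.seed(100 + s)
    X <- matrix(rnorm(15 * 3), 15, 3)
    y <- drop(X %*% c(1.5, 0, -1)) + rnorm(15, sd = 0.5)
    alpha <- c(0.05, 0.15, 0.4)[(s %% 3) + 1]
    cd <- fit_lasso(X, y, alpha)
    best <- lasso_enumeration_oracle(X, y, alpha)
    expect_lt(abs(cd$objective_value - best), 1e-8)
  }
})

test_that("coordinate descent matches glmnet on a standardized problem", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  X <- scale(matrix(rnorm(60 * 8), 60, 8))[, ]
  y <- drop(X %*% c(2, -1, rep(0, 6))) + rnorm(60)
  alpha <- 0.2
  cd <- fit_lasso(X, y, alpha)
  gn <- glmnet::glmnet(X, y, lambda = alpha, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(unname(cd$w), as.vector(gn$beta), tolerance = 1e-5)
  expect_equal(cd$w0, unname(gn$a0), tolerance = 1e-5)
})

test_that("prediction is the affine map w0 + Xw", {
  fit <- structure(list(w = c(a = 0, b = 0), w0 = 3.5), class = "lasso_fit")
  expect_equal(predict(fit, matrix(rnorm(10), 5, 2)), rep(3.5, 5))
  fit$w <- c(a = 1, b = -2)
  Xn <- matrix(1:6, 3, 2)
  expect_equal(predict(fit, Xn), 3.5 + Xn[, 1] - 2 * Xn[, 2])
  X2 <- Xn; X2[, 1] <- 2 * X2[, 1]
  expect_equal(predict(fit, X2) - predict(fit, Xn), Xn[, 1])
  expect_error(predict(fit, matrix(1, 2, 3)), "columns")
})

test_that("accuracy metrics follow their definitions", {
  y <- c(0, 0, 1, 1); yhat <- c(0, 1, 0, 1)
  expect_equal(mse(y, yhat), 0.5)
  expect_equal(r2_score(y, yhat), -1.0)
  expect_equal(r2_score(y, y), 1)
  expect_equal(mse(y, y), 0)
  expect_equal(r2_score(y, rep(mean(y), 4)), 0)
  expect_error(r2_score(rep(1, 4), yhat), "variance")
})

test_that("cross-validation is deterministic given the seed and honest on noise", {
  set.seed(42)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rnorm(60)
  a <- kfold_cv(X, y, 0.05, k = 5, seed = 9)
  b <- kfold_cv(X, y, 0.05, k = 5, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a$folds, kfold_cv(X, y, 0.05, k = 5, seed = 10)$folds))
  # noise-only responses should not look predictable out of fold
  cvr <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(50 * 3), 50, 3)
    kfold_cv(X, rnorm(50), 0.02, k = 5, seed = s)$cv_r2
  }, numeric(1))
  expect_lt(mean(cvr), 0.05)
  # noiseless linear signal is recovered perfectly as alpha -> 0
  set.seed(5)
  Xs <- matrix(rnorm(80 * 4), 80, 4)
  ys <- drop(Xs %*% c(1, 2, -1, 0.5)) + 3
  expect_gt(kfold_cv(Xs, ys, 1e-8, k = 10, seed = 1)$cv_r2, 1 - 1e-6)
})

test_that("fold assignment covers all samples in balanced shuffled folds", {
  f <- fold_assignments(23, 5, seed = 4)
  expect_setequal(unique(f), 1:5)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  expect_error(fold_assignments(4, 10, 1), "exceed")
})

test_that("the penalty grid spans the stated endpoints", {
  g <- lasso_alpha_grid()
  expect_equal(length(g), 50)
  expect_equal(min(g), 5e-5)
  expect_equal(max(g), 0.5)
})

test_that("the sweep reports monotone training fit and the full path", {
  set.seed(8)
  X <- scale(matrix(rnorm(50 * 6), 50, 6))[, ]
  y <- drop(X %*% c(2, -1.5, 1, 0, 0, 0)) + rnorm(50, sd = 0.5)
  sw <- alpha_sweep(X, y, alpha_grid = lasso_alpha_grid(length = 20),
                    k = 5, seed = 2)
  expect_s3_class(sw, "lasso_sweep")
  # alphas descend; training R^2 must not increase with the penalty
  expect_true(all(diff(sw$alpha) < 0))
  expect_true(all(diff(sw$train_r2) > -1e-6))
  expect_equal(sw$support_size,
               vapply(sw$support_ids, length, integer(1)))
  # a grid point above the null threshold yields the empty model
  amax <- max(abs(crossprod(X, y - mean(y)) / nrow(X)))
  sw2 <- alpha_sweep(X, y, alpha_grid = c(amax * 1.01, 0.01), k = 5, seed = 2)
  expect_equal(sw2$support_size[1], 0)
  # near-zero penalty approaches the OLS training fit
  r2_ols <- summary(lm(y ~ X))$r.squared
  expect_equal(sw$train_r2[nrow(sw)], r2_ols, tolerance = 1e-3)
})

fake_sweep <- function(cv_r2, support_size, alpha = rev(seq_along(cv_r2)),
                       cv_mse = 1 - cv_r2) {
  out <- data.frame(alpha = alpha, train_r2 = cv_r2 + 0.1, cv_r2 = cv_r2,
                    cv_mse = cv_mse, support_size = support_size)
  out$support_ids <- I(lapply(support_size, function(k) paste0("m", seq_len(k))))
  attr(out, "coefficients") <- matrix(0, max(support_size), nrow(out))
  attr(out, "intercepts") <- numeric(nrow(out))
  class(out) <- c("lasso_sweep", "data.frame")
  out
}

test_that("elbow selection picks the smallest support within tolerance", {
  # one record strictly dominates
  sw <- fake_sweep(c(0.5, 0.8, 0.6), c(10, 5, 20))
  expect_equal(select_elbow(sw)$support_size, 5)
  # two records within tol: the smaller support wins
  sw <- fake_sweep(c(0.750, 0.748), c(29, 60))
  expect_equal(select_elbow(sw, tol = 0.02)$support_size, 29)
  # outside tol the maximum wins
  sw <- fake_sweep(c(0.750, 0.700), c(29, 10))
  expect_equal(select_elbow(sw, tol = 0.02)$support_size, 29)
  # support ties break toward the larger penalty
  sw <- fake_sweep(c(0.75, 0.75), c(8, 8), alpha = c(0.3, 0.1))
  expect_equal(select_elbow(sw)$alpha, 0.3)
  expect_error(select_elbow(fake_sweep(c(NaN, NaN), c(1, 2))), "finite")
})

test_that("minimum-MSE selection returns the smallest cross-validated MSE", {
  sw <- fake_sweep(c(0.5, 0.7, 0.65), c(10, 13, 20),
                   cv_mse = c(0.4, 0.26, 0.3))
  sel <- select_min_cv_mse(sw)
  expect_equal(sel$cv_mse, 0.26)
  expect_equal(sel$support_size, 13)
})

test_that("panel refits restrict to the panel and handle degenerate input", {
  set.seed(21)
  X <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(NULL, paste0("met", 1:8)))
  y <- drop(scale(X[, 1:3]) %*% c(1, -1, 0.8)) + rnorm(60, sd = 0.3)
  panel <- paste0("met", 1:4)
  rf <- refit_panel(panel, list(X), list(y), k = 5, seed = 3,
                    alpha_grid = lasso_alpha_grid(length = 15))
  expect_true(all(rf$selection$support_ids %in% panel))
  expect_equal(ncol(rf$X), 4)
  # single-feature panel can select at most that feature
  rf1 <- refit_panel("met1", list(X), list(y), k = 5, seed = 3,
                     alpha_grid = lasso_alpha_grid(length = 10))
  expect_lte(rf1$selection$support_size, 1)
  expect_error(refit_panel(c("met1", "nope"), list(X), list(y)), "nope")
})

test_that("multi-batch refits recover panel members shared across batches", {
  specs <- lapply(1:3, function(i)
    small_spec(seed = 30 + i, m_metabolites = 30, support_indices = 1:6,
               n_weeks = 3, timepoints_per_day = 6, replicates = 2))
  sets <- lapply(specs, generate_dataset)
  mats <- lapply(sets, function(d) preprocess_peaks(d$peaks)$values)
  ys <- lapply(sets, function(d) unname(d$truth$y))
  common <- Reduce(intersect, lapply(mats, colnames))
  panel <- intersect(sets[[1]]$truth$support_ids, common)
  mats <- lapply(mats, function(m) m[, common, drop = FALSE])
  rf <- refit_panel(panel, mats, ys, k = 5, seed = 1,
                    alpha_grid = lasso_alpha_grid(length = 20))
  expect_true(all(rf$selection$support_ids %in% panel))
  expect_gt(rf$selection$support_size, 0)
  expect_equal(nrow(rf$X), sum(vapply(ys, length, numeric(1))))
})
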