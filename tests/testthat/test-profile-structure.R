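test_that("PCA matches an eigendecomposition oracle and reconstructs", {
  set.seed(4)
  x <- matrix(rnorm(12 * 5), 12, 5)
  p <- pca_profiles(x)
  xc <- sweep(x, 2, colMeans(x))
  # oracle: eigen of the scatter matrix
  eig <- eigen(crossprod(xc), symmetric = TRUE)
  V <- eig$vectors
  for (c in seq_len(ncol(V))) { # same sign convention
    i <- which.max(abs(V[, c]))
    if (V[i, c] < 0) V[, c] <- -V[, c]
  }
  expect_equal(unname(p$loadings), V[, seq_len(ncol(p$loadings))],
               tolerance = 1e-8)
  expect_equal(unname(p$scores), unname(xc %*% V), tolerance = 1e-8)
  # full-rank reconstruction and unit ratio sum
  expect_equal(p$scores %*% t(p$loadings), xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(p$contribution_ratios), 1, tolerance = 1e-10)
  expect_true(all(diff(p$contribution_ratios) <= 1e-12))
  # orthogonal score columns
  g <- crossprod(p$scores)
  expect_equal(g - diag(diag(g)), matrix(0, 5, 5), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-one data loads a single component; duplicates duplicate scores", {
  set.seed(9)
  x <- outer(rnorm(10), c(1, 2, -1))
  p <- suppressWarnings(pca_profiles(x, n_components = 1))
  expect_equal(p$contribution_ratios[1], 1, tolerance = 1e-10)
  x2 <- rbind(x, x[1, ])
  p2 <- pca_profiles(x2)
  expect_equal(p2$scores[11, ], p2$scores[1, ], tolerance = 1e-10)
  expect_warning(pca_profiles(x, n_components = 3), "rank")
})

test_that("correlation distance is 1 - r with the documented range", {
  set.seed(6)
  a <- rnorm(50)
  x <- cbind(p = a, q = 2 * a + 5, r = -a, s = rnorm(50))
  d <- correlation_distance_matrix(x)
  expect_equal(d["p", "q"], 0, tolerance = 1e-12)
  expect_equal(d["p", "r"], 2, tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  set.seed(1)
  big <- matrix(rnorm(2e4), 1e4, 2)
  expect_equal(correlation_distance_matrix(big)[1, 2], 1, tolerance = 0.1)
  expect_error(correlation_distance_matrix(cbind(a, rep(1, 50))), "constant")
})

test_that("agglomeration merges closest points first under any linkage", {
  d <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  for (m in c("single", "complete", "average", "ward")) {
    dd <- agglomerate(d, m)
    expect_equal(sort(dd$merge[1, ]), c(-2, -1)) # x and y first
    expect_equal(dd$height[1], 1)
  }
  # chain spaced 1 apart: single linkage merges at heights (1, 1)
  chain <- matrix(c(0, 1, 2,
                    1, 0, 1,
                    2, 1, 0), 3, 3)
  expect_equal(agglomerate(chain, "single")$height, c(1, 1))
  # two leaves merge once at their distance
  two <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(agglomerate(two, "average")$height, 3)
  expect_error(agglomerate(matrix(c(0, 1, 2, 0), 2, 2), "average"),
               "symmetric")
  expect_error(agglomerate(two, "upgma"), "unknown")
})

test_that("cophenetic correlation matches the merge-tree traversal oracle", {
  set.seed(12)
  n <- 7
  x <- matrix(rnorm(n * 3), n)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("l", 1:n), paste0("l", 1:n))
  for (m in c("average", "single", "complete")) {
    dend <- agglomerate(d, m)
    oracle <- coph_oracle(dend)
    r_oracle <- cor(d[upper.tri(d)], oracle[upper.tri(oracle)])
    expect_equal(cophenetic_correlation(dend, d), r_oracle,
                 tolerance = 1e-10)
  }
  # invariance to leaf relabeling
  perm <- sample(n)
  dp <- d[perm, perm]
  expect_equal(cophenetic_correlation(agglomerate(dp, "average"), dp),
               cophenetic_correlation(agglomerate(d, "average"), d),
               tolerance = 1e-10)
  expect_error(cophenetic_correlation(agglomerate(d[1:2, 1:2], "single"),
                                      d[1:2, 1:2]), "3 leaves")
})

test_that("ultrametric distances are reproduced exactly (r = 1)", {
  set.seed(3)
  base <- agglomerate(as.matrix(dist(matrix(rnorm(18), 6))), "average")
  ultra <- coph_oracle(base) # an exactly ultrametric matrix
  dend <- agglomerate(ultra, "average")
  expect_equal(cophenetic_correlation(dend, ultra), 1, tolerance = 1e-10)
  sel <- select_linkage(ultra)
  expect_equal(sel$best_method, "average") # ties resolve to average first
})

test_that("linkage selection maximizes the cophenetic coefficient", {
  set.seed(8)
  d <- as.matrix(dist(matrix(rnorm(30), 10)))
  dimnames(d) <- list(paste0("m", 1:10), paste0("m", 1:10))
  sel <- suppressWarnings(select_linkage(d))
  expect_equal(nrow(sel$table), 7)
  # every table entry matches an independent recomputation via the oracle
  for (i in seq_len(nrow(sel$table))) {
    dend <- suppressWarnings(agglomerate(d, sel$table$method[i]))
    oracle <- coph_oracle(dend)[rownames(d), colnames(d)]
    expect_equal(sel$table$cophenetic_r[i],
                 cor(d[upper.tri(d)], oracle[upper.tri(oracle)]),
                 tolerance = 1e-10)
  }
  expect_equal(max(sel$table$cophenetic_r),
               sel$table$cophenetic_r[sel$table$method == sel$best_method])
  expect_equal(select_linkage(d, "average")$best_method, "average")
})

test_that("single-linkage cophenetic distances never exceed the input", {
  for (s in 1:5) {
    set.seed(s)
    d <- as.matrix(dist(matrix(rnorm(24), 8)))
    co <- coph_oracle(agglomerate(d, "single"))
    expect_true(all(co <= d + 1e-12))
  }
})

test_that("cutting the dendrogram yields height-threshold components", {
  chain <- matrix(c(0, 1, 2,
                    1, 0, 1,
                    2, 1, 0), 3, 3,
                  dimnames = list(letters[1:3], letters[1:3]))
  dend <- agglomerate(chain, "single")
  expect_equal(length(unique(cut_clusters(dend, 10))), 1)
  expect_equal(length(unique(cut_clusters(dend, 0))), 3)
  expect_equal(length(unique(cut_clusters(dend, 0.5))), 3)
  one <- cut_clusters(dend, 1.0)
  expect_equal(length(unique(one)), 1) # cutree includes merges at the height
})
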