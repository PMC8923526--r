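#' Principal component analysis of metabolite profiles
#'
#' Singular value decomposition of the column-centered matrix. Scores are
#' `U %*% diag(d)`, loadings are `V`, and the contribution ratio of each
#' component is its share of the total variance. Component signs are pinned
#' deterministically: the largest-magnitude loading of each component is
#' made positive.
#'
#' @param x A standardized `metabolite_matrix` or plain numeric matrix.
#' @param n_components Number of components to return (default: full rank).
#' @return An object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (metabolites x components), `contribution_ratios` (over the
#'   full spectrum), `sdev`.
#' @export
pca_profiles <- function(x, n_components = NULL) {
  v <- mm_values(x)
  if (inherits(x, "metabolite_matrix") && x$state != "standardized")
    warning("PCA input is in state '", x$state, "', not 'standardized'")
  v <- sweep(v, 2, colMeans(v))
  s <- svd(v)
  rank <- sum(s$d > max(s$d) * 1e-12)
  k <- n_components %||% rank
  if (k > rank) {
    warning("n_components (", k, ") exceeds rank (", rank, "); truncated")
    k <- rank
  }
  # deterministic sign convention
  for (c in seq_len(k)) {
    i <- which.max(abs(s$v[, c]))
    if (s$v[i, c] < 0) {
      s$v[, c] <- -s$v[, c]
      s$u[, c] <- -s$u[, c]
    }
  }
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(v)
  rownames(loadings) <- colnames(v)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 contribution_ratios = (s$d^2 / sum(s$d^2))[seq_len(k)],
                 sdev = s$d[seq_len(k)] / sqrt(nrow(v))),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$scores), "components;",
      "contribution ratios:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$contribution_ratios, 3)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Correlation distance matrix
#'
#' Pairwise distances `1 - r` between metabolite profiles, where `r` is the
#' Pearson correlation. Range `[0, 2]`, zero diagonal.
#'
#' @param x A `metabolite_matrix` or numeric matrix (samples x metabolites).
#' @param subset Optional metabolite ids to restrict to.
#' @return Symmetric numeric matrix.
#' @export
correlation_distance_matrix <- function(x, subset = NULL) {
  v <- mm_values(x)
  if (!is.null(subset)) v <- v[, subset, drop = FALSE]
  sds <- apply(v, 2, sd_pop)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(v)[sds == 0] %||% which(sds == 0), collapse = ", "))
  d <- 1 - cor(v)
  diag(d) <- 0
  d
}

LINKAGE_METHODS <- c(single = "single", complete = "complete",
                     average = "average", weighted = "mcquitty",
                     centroid = "centroid", median = "median",
                     ward = "ward.D2")

#' Agglomerative hierarchical clustering
#'
#' Standard agglomerative merging of a distance matrix under one of the
#' seven classical linkage methods (`weighted` is WPGMA/mcquitty; `ward` is
#' the squared-distance Ward criterion). Centroid and median linkage may
#' produce non-monotone merge heights (inversions); a warning is emitted
#' when they do.
#'
#' @param distances Symmetric distance matrix or `dist` object.
#' @param linkage_method One of `"single"`, `"complete"`, `"average"`,
#'   `"weighted"`, `"centroid"`, `"median"`, `"ward"`.
#' @return Object of class `hcl_dendrogram` wrapping the merge tree:
#'   `merge`, `height`, `labels`, `linkage_method`, and the underlying
#'   [stats::hclust] object.
#' @export
agglomerate <- function(distances, linkage_method = "average") {
  if (!linkage_method %in% names(LINKAGE_METHODS))
    stop("unknown linkage method: ", linkage_method)
  if (is.matrix(distances)) {
    if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-12)))
      stop("distance matrix must be symmetric")
    distances <- stats::as.dist(distances)
  }
  hc <- hclust(distances, method = LINKAGE_METHODS[[linkage_method]])
  if (is.unsorted(hc$height))
    warning("non-monotone merge heights (inversions) under '",
            linkage_method, "' linkage")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 linkage_method = linkage_method, hclust = hc),
            class = "hcl_dendrogram")
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (the merge height at which each pair first joins a
#' common cluster).
#'
#' @param dendrogram An `hcl_dendrogram`.
#' @param distances The distance matrix (or `dist`) the dendrogram was built
#'   from, over the same leaves.
#' @return A number in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(dendrogram, distances) {
  stopifnot(inherits(dendrogram, "hcl_dendrogram"))
  if (is.matrix(distances)) distances <- stats::as.dist(distances)
  if (attr(distances, "Size") < 3)
    stop("cophenetic correlation needs at least 3 leaves")
  cor(as.vector(distances), as.vector(cophenetic(dendrogram$hclust)))
}

#' Data-driven linkage selection
#'
#' Builds one dendrogram per candidate linkage method and returns the one
#' with the maximum cophenetic correlation coefficient. Ties are broken by a
#' fixed preference order with `"average"` first, then the order of
#' `methods`.
#'
#' @param distances Symmetric distance matrix or `dist`.
#' @param methods Candidate linkage methods.
#' @return List with `best_method`, `dendrogram`, and `table` (data frame of
#'   method and cophenetic correlation).
#' @export
select_linkage <- function(distances,
                           methods = c("average", "single", "complete",
                                       "weighted", "centroid", "median",
                                       "ward")) {
  stopifnot(length(methods) >= 1)
  methods <- unique(c(intersect("average", methods), methods))
  dendros <- lapply(methods, function(m)
    suppressWarnings(agglomerate(distances, m)))
  coefs <- vapply(dendros, cophenetic_correlation, numeric(1),
                  distances = distances)
  best <- which.max(coefs) # first max wins; "average" is evaluated first
  list(best_method = methods[best], dendrogram = dendros[[best]],
       table = data.frame(method = methods, cophenetic_r = coefs))
}

#' Cut a dendrogram at a height threshold
#'
#' Clusters are the connected components left after removing all merges
#' above the threshold.
#'
#' @param dendrogram An `hcl_dendrogram`.
#' @param height_threshold Cut height (default 0.5, the correlation-distance
#'   cut used for predictor-metabolite modules).
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(dendrogram, height_threshold = 0.5) {
  stopifnot(inherits(dendrogram, "hcl_dendrogram"), height_threshold >= 0)
  cutree(dendrogram$hclust, h = height_threshold)
}
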