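#' Shift a standardized matrix to be nonnegative
#'
#' Subtracts the single global minimum from every entry so that the smallest
#' entry becomes exactly zero, the preparation step before correspondence
#' analysis of z-scored profiles. Idempotent.
#'
#' @param x Numeric matrix (or `metabolite_matrix`).
#' @return Matrix of the same shape with minimum 0.
#' @export
nonneg_shift <- function(x) {
  v <- mm_values(x)
  v - min(v)
}

#' Correspondence analysis
#'
#' Classical CA of a nonnegative table: with `P` the table divided by its
#' grand total, row masses `r` and column masses `c`, the standardized
#' residuals `S_ij = (P_ij - r_i c_j) / sqrt(r_i c_j)` are decomposed by
#' SVD. Both rows and columns are returned in principal coordinates (the
#' symmetric map): `diag(r)^(-1/2) U D` and `diag(c)^(-1/2) V D`. All
#' `min(n, m) - 1` dimensions are kept; the principal inertias are the
#' squared singular values and sum to the total inertia
#' `sum(S^2)` (= Pearson chi-square / grand total).
#'
#' @param x Nonnegative numeric matrix with positive row and column sums.
#' @return Object of class `ca_result`: `row_coords`, `col_coords`,
#'   `singular_values`, `principal_inertias`, `total_inertia`, `d`.
#' @export
correspondence_analysis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("correspondence analysis needs a nonnegative table")
  rs <- rowSums(x); cs <- colSums(x)
  if (any(rs == 0))
    stop("zero row sum(s): ",
         paste(rownames(x)[rs == 0] %||% which(rs == 0), collapse = ", "))
  if (any(cs == 0))
    stop("zero column sum(s): ",
         paste(colnames(x)[cs == 0] %||% which(cs == 0), collapse = ", "))
  total <- sum(x)
  P <- x / total
  r <- rs / total
  c <- cs / total
  S <- (P - tcrossprod(r, c)) / sqrt(tcrossprod(r, c))
  total_inertia <- sum(S^2)
  d <- min(nrow(x), ncol(x)) - 1L
  if (d < 1L) stop("table must have at least 2 rows and 2 columns")
  sv <- svd(S)
  if (total_inertia < 1e-12)
    warning("table rows are proportional; total inertia is 0 and all ",
            "coordinates are 0")
  # deterministic sign convention per dimension
  for (k in seq_len(d)) {
    i <- which.max(abs(sv$v[, k]))
    if (sv$v[i, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  dk <- sv$d[seq_len(d)]
  row_coords <- (sv$u[, seq_len(d), drop = FALSE] / sqrt(r)) %*% diag(dk, d)
  col_coords <- (sv$v[, seq_len(d), drop = FALSE] / sqrt(c)) %*% diag(dk, d)
  dimnames(row_coords) <- list(rownames(x), paste0("Dim", seq_len(d)))
  dimnames(col_coords) <- list(colnames(x), paste0("Dim", seq_len(d)))
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 singular_values = dk, principal_inertias = dk^2,
                 total_inertia = total_inertia, d = d,
                 row_masses = r, col_masses = c),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "rows x",
      nrow(x$col_coords), "columns,", x$d, "dimensions; total inertia",
      signif(x$total_inertia, 4), "\n")
  invisible(x)
}

#' Euclidean distances between CA coordinates
#'
#' `cross_distances()` returns the metabolite x sample matrix of Euclidean
#' distances between column (metabolite) and row (sample) principal
#' coordinates over all dimensions; `pairwise_distances()` the symmetric
#' distance matrix among one coordinate set.
#'
#' @param ca A `ca_result`.
#' @return For `cross_distances`, a metabolites x samples matrix.
#' @export
cross_distances <- function(ca) {
  stopifnot(inherits(ca, "ca_result"))
  a <- ca$col_coords; b <- ca$row_coords
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' @rdname cross_distances
#' @param coords Coordinate matrix (points x dimensions).
#' @export
pairwise_distances <- function(coords) {
  as.matrix(dist(coords))
}

#' Edge table from a cross (bipartite) distance matrix
#'
#' @param dmat Metabolite x sample (or any bipartite) distance matrix with
#'   dimnames.
#' @return Data frame `node_a`, `node_b`, `distance`, one row per pair.
#' @export
cross_edge_table <- function(dmat) {
  data.frame(node_a = rep(rownames(dmat), times = ncol(dmat)),
             node_b = rep(colnames(dmat), each = nrow(dmat)),
             distance = as.vector(dmat))
}

#' Edge table from a symmetric distance matrix
#'
#' @param dmat Symmetric distance matrix with dimnames; only the upper
#'   triangle (each unordered pair once) is emitted.
#' @return Data frame `node_a`, `node_b`, `distance`.
#' @export
pairwise_edge_table <- function(dmat) {
  idx <- which(upper.tri(dmat), arr.ind = TRUE)
  data.frame(node_a = rownames(dmat)[idx[, 1]],
             node_b = colnames(dmat)[idx[, 2]],
             distance = dmat[idx])
}

#' Percentile-threshold edge selection
#'
#' The threshold is the empirical percentile (linear interpolation, the
#' standard type-7 quantile) of all distances; an edge passes iff its
#' distance is strictly less than the threshold.
#'
#' @param edges Data frame with a `distance` column (see
#'   [cross_edge_table()] / [pairwise_edge_table()]) or a bare numeric
#'   vector of distances.
#' @param percentile Proportion in (0, 1]; default 0.15 (the 15th
#'   percentile).
#' @return Object of class `edge_list`: the `edges` data frame gains a
#'   `passed` flag; `threshold_value` and `percentile` are attached.
#' @export
percentile_threshold <- function(edges, percentile = 0.15) {
  if (is.numeric(edges))
    edges <- data.frame(node_a = as.character(seq_along(edges)),
                        node_b = NA_character_, distance = edges)
  if (nrow(edges) == 0) stop("empty distance collection")
  stopifnot(percentile > 0, percentile <= 1)
  thr <- unname(quantile(edges$distance, percentile, type = 7))
  edges$passed <- edges$distance < thr
  structure(list(edges = edges, threshold_value = thr,
                 percentile = percentile),
            class = "edge_list")
}

#' @export
print.edge_list <- function(x, ...) {
  cat("Edge list:", nrow(x$edges), "pairs;",
      sum(x$edges$passed), "passed the",
      sprintf("%g%%", 100 * x$percentile), "threshold (",
      signif(x$threshold_value, 4), ")\n")
  invisible(x)
}

#' Aggregate metabolite-sample edges to sample characteristics
#'
#' For each metabolite and each level of the chosen characteristic
#' (experiment, cultivar, sampling time, day/night), emits an edge weighted
#' by the mean distance of that metabolite's passed pairs to samples of that
#' level. Metabolites with no passed pair to a level get no edge.
#'
#' @param edge_list An `edge_list` over metabolite-sample pairs (`node_b` =
#'   sample id).
#' @param sample_meta Data frame with a `sample_id` column and the
#'   characteristic column.
#' @param characteristic Column of `sample_meta` to aggregate by.
#' @return Data frame `metabolite`, `level`, `weight` (mean passed
#'   distance), `n_pairs`.
#' @export
aggregate_by_characteristic <- function(edge_list, sample_meta,
                                        characteristic = "experiment") {
  stopifnot(inherits(edge_list, "edge_list"),
            characteristic %in% names(sample_meta))
  all_lev <- sample_meta[[characteristic]][
    match(edge_list$edges$node_b, sample_meta$sample_id)]
  if (anyNA(all_lev))
    stop("unlabeled sample(s): ",
         paste(unique(edge_list$edges$node_b[is.na(all_lev)]), collapse = ", "))
  keep <- edge_list$edges$passed
  e <- edge_list$edges[keep, , drop = FALSE]
  lev <- all_lev[keep]
  if (nrow(e) == 0)
    return(data.frame(metabolite = character(), level = character(),
                      weight = numeric(), n_pairs = integer()))
  key <- interaction(e$node_a, lev, drop = TRUE, sep = "\r")
  agg <- data.frame(
    metabolite = vapply(strsplit(levels(key), "\r"), `[`, "", 1),
    level = vapply(strsplit(levels(key), "\r"), `[`, "", 2),
    weight = as.vector(tapply(e$distance, key, mean)),
    n_pairs = as.vector(tapply(e$distance, key, length))
  )
  agg <- agg[order(agg$metabolite, agg$level), ]
  rownames(agg) <- NULL
  agg
}

#' Day/night labels for sampling times
#'
#' Clock times in `[06:00, 18:00]` are day; times in `[20:00, 24:00)` or
#' `[00:00, 04:00]` are night. Off-grid times (e.g. 05:00, 19:00) are an
#' error: samples are expected on the 2-hour sampling grid.
#'
#' @param times POSIXct datetimes, `"HH:MM"` strings, or numeric hours.
#' @return Character vector of `"day"` / `"night"`.
#' @export
day_night_labels <- function(times) {
  h <- if (inherits(times, "POSIXt")) {
    as.numeric(format(times, "%H", tz = "UTC")) +
      as.numeric(format(times, "%M", tz = "UTC")) / 60
  } else if (is.character(times)) {
    parts <- strsplit(times, ":", fixed = TRUE)
    vapply(parts, function(p) as.numeric(p[1]) +
             (if (length(p) > 1) as.numeric(p[2]) / 60 else 0), numeric(1))
  } else {
    as.numeric(times)
  }
  out <- ifelse(h >= 6 & h <= 18, "day",
                ifelse(h >= 20 | h <= 4, "night", NA_character_))
  if (anyNA(out))
    stop("time(s) outside the day (06:00-18:00) and night (20:00-04:00) ",
         "windows: ", paste(unique(h[is.na(out)]), collapse = ", "))
  out
}

#' Diurnal-stability screen of a metabolite panel
#'
#' Scales each panel metabolite to `[0, 1]` over the time-series samples and
#' records the population standard deviation of the scaled series; small SD
#' means the metabolite is stable across the day and hence robust to
#' sampling time. Records are sorted ascending by SD. If a
#' characteristic-level network aggregated over day/night is supplied, each
#' record is flagged with the day and night associations.
#'
#' @param x `metabolite_matrix` or matrix restricted to the time-series
#'   samples.
#' @param panel_ids Metabolite ids to screen.
#' @param day_night_edges Optional data frame from
#'   [aggregate_by_characteristic()] at the day/night level.
#' @return Data frame `metabolite_id`, `sd_scaled`, `day_association`,
#'   `night_association`, ascending in `sd_scaled`.
#' @export
diurnal_stability <- function(x, panel_ids = NULL, day_night_edges = NULL) {
  v <- mm_values(x)
  if (!is.null(panel_ids)) v <- v[, panel_ids, drop = FALSE]
  if (nrow(v) < 2) stop("need at least 2 timepoints")
  scaled <- scale01_profiles(v)
  rec <- data.frame(metabolite_id = colnames(scaled),
                    sd_scaled = apply(scaled, 2, sd_pop))
  if (!is.null(day_night_edges)) {
    rec$day_association <- rec$metabolite_id %in%
      day_night_edges$metabolite[day_night_edges$level == "day"]
    rec$night_association <- rec$metabolite_id %in%
      day_night_edges$metabolite[day_night_edges$level == "night"]
  } else {
    rec$day_association <- rec$night_association <- NA
  }
  rec <- rec[order(rec$sd_scaled), ]
  rownames(rec) <- NULL
  rec
}
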