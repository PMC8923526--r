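#' Peak table container
#'
#' Holds raw peak areas from a widely targeted metabolomics run together with
#' the extraction-blank areas, the designated internal-standard columns, and
#' per-sample metadata.
#'
#' @param areas Nonnegative numeric matrix, samples x compounds, with column
#'   names (compound ids) and row names (sample ids).
#' @param blank_areas Nonnegative numeric matrix, compounds x blank
#'   replicates, with row names matching `colnames(areas)`.
#' @param internal_standard_ids Character vector of compound ids that are
#'   internal standards.
#' @param sample_meta Data frame with one row per sample; expected columns
#'   include `sample_id`, `experiment`, `cultivar`, `plant`, `datetime`,
#'   `replicate`.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(areas, blank_areas, internal_standard_ids, sample_meta) {
  areas <- as.matrix(areas)
  blank_areas <- as.matrix(blank_areas)
  if (any(areas < 0)) stop("peak areas must be nonnegative")
  if (any(blank_areas < 0)) stop("blank areas must be nonnegative")
  if (is.null(colnames(areas))) stop("areas must have compound column names")
  if (!all(internal_standard_ids %in% colnames(areas)))
    stop("every internal_standard_id must be a compound column")
  if (!setequal(rownames(blank_areas), colnames(areas)))
    stop("blank_areas rows must match the compound columns of areas")
  blank_areas <- blank_areas[colnames(areas), , drop = FALSE]
  if (ncol(blank_areas) < 1) stop("need at least one blank replicate")
  if (nrow(sample_meta) != nrow(areas))
    stop("sample_meta must have one row per sample")
  structure(list(areas = areas, blank_areas = blank_areas,
                 internal_standard_ids = internal_standard_ids,
                 sample_meta = sample_meta),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("Peak table:", nrow(x$areas), "samples x", ncol(x$areas), "compounds (",
      length(x$internal_standard_ids), "internal standards,",
      ncol(x$blank_areas), "blank replicates )\n")
  invisible(x)
}

#' Metabolite content matrix
#'
#' Samples x metabolites matrix of relative metabolite contents with sample
#' metadata and a state flag recording which transformation has been applied
#' (`"raw_relative"`, `"standardized"`, or `"scaled01"`).
#'
#' @param values Numeric matrix, samples x metabolites, no missing values.
#' @param sample_meta Data frame, one row per sample.
#' @param state One of `"raw_relative"`, `"standardized"`, `"scaled01"`.
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, sample_meta,
                              state = c("raw_relative", "standardized", "scaled01")) {
  values <- as.matrix(values)
  state <- match.arg(state)
  if (anyNA(values)) stop("metabolite matrix must not contain missing values")
  if (nrow(sample_meta) != nrow(values))
    stop("sample_meta must have one row per sample")
  structure(list(values = values,
                 metabolite_ids = colnames(values),
                 sample_meta = sample_meta,
                 state = state),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat("Metabolite matrix:", nrow(x$values), "samples x", ncol(x$values),
      "metabolites [", x$state, "]\n")
  invisible(x)
}

mm_values <- function(x) if (inherits(x, "metabolite_matrix")) x$values else as.matrix(x)

#' Signal-to-noise ratios against extraction blanks
#'
#' Divides each peak area by the mean blank area of the same compound.
#' Areas below the detection limit are expected to have been set to zero
#' upstream; those zeros propagate to zero S/N.
#'
#' @param areas Samples x compounds area matrix.
#' @param blank_areas Compounds x replicates blank area matrix (rows aligned
#'   with `colnames(areas)` or in the same order).
#' @param zero_blank What to do when a compound's mean blank area is zero:
#'   `"error"` (default) or `"substitute"` the smallest positive mean blank
#'   (reported via a message).
#' @return Samples x compounds matrix of S/N ratios.
#' @export
compute_snr <- function(areas, blank_areas, zero_blank = c("error", "substitute")) {
  zero_blank <- match.arg(zero_blank)
  areas <- as.matrix(areas)
  blank_areas <- as.matrix(blank_areas)
  if (nrow(blank_areas) != ncol(areas))
    stop("blank_areas must have one row per compound column of areas")
  mb <- rowMeans(blank_areas)
  if (any(mb <= 0)) {
    bad <- which(mb <= 0)
    if (zero_blank == "error")
      stop("zero mean blank area for compound(s): ",
           paste(colnames(areas)[bad] %||% bad, collapse = ", "))
    sub <- min(mb[mb > 0])
    message("substituting smallest positive mean blank (", format(sub),
            ") for ", length(bad), " compound(s)")
    mb[bad] <- sub
  }
  sweep(areas, 2, mb, "/")
}

#' Detection filter on signal-to-noise ratios
#'
#' Keeps metabolite `j` iff its S/N exceeds `threshold` (strictly) in
#' strictly more than `min_fraction` of the samples. Internal standards are
#' excluded from the candidate list.
#'
#' @param snr Samples x compounds S/N matrix.
#' @param threshold S/N cutoff (default 2).
#' @param min_fraction Required fraction of samples (default 0.5).
#' @param exclude Compound ids to drop from the candidates (internal
#'   standards).
#' @return Character vector of kept metabolite ids.
#' @export
detection_filter <- function(snr, threshold = 2, min_fraction = 0.5,
                             exclude = character()) {
  stopifnot(min_fraction > 0, min_fraction < 1)
  snr <- as.matrix(snr)
  if (is.null(colnames(snr))) colnames(snr) <- as.character(seq_len(ncol(snr)))
  ids <- colnames(snr)
  cand <- setdiff(ids, exclude)
  n <- nrow(snr)
  passes <- colSums(snr[, cand, drop = FALSE] > threshold)
  kept <- cand[passes > min_fraction * n]
  if (length(kept) == 0)
    stop("all metabolites removed by the detection filter; ",
         "review the S/N threshold (", threshold, ") and blanks")
  kept
}

#' Internal-standard normalization
#'
#' Divides each metabolite's peak area by the internal-standard area of the
#' same sample to obtain the relative metabolite content.
#'
#' @param areas Samples x compounds area matrix.
#' @param is_assignment Either a single internal-standard compound id used
#'   for every metabolite, or a named character vector mapping metabolite id
#'   to its internal standard.
#' @param sample_meta Optional sample metadata carried into the result.
#' @return A `metabolite_matrix` in state `"raw_relative"` (internal-standard
#'   columns removed).
#' @export
normalize_by_internal_standard <- function(areas, is_assignment,
                                           sample_meta = NULL) {
  areas <- as.matrix(areas)
  ids <- colnames(areas)
  is_ids <- unique(unname(is_assignment))
  if (!all(is_ids %in% ids))
    stop("internal standard(s) not found: ",
         paste(setdiff(is_ids, ids), collapse = ", "))
  mets <- setdiff(ids, is_ids)
  map <- if (is.null(names(is_assignment)) && length(is_assignment) == 1) {
    setNames(rep(is_assignment, length(mets)), mets)
  } else {
    if (!all(mets %in% names(is_assignment)))
      stop("is_assignment must name every metabolite")
    is_assignment[mets]
  }
  is_areas <- areas[, is_ids, drop = FALSE]
  zero_rows <- rownames(areas)[apply(is_areas == 0, 1, any)]
  if (length(zero_rows))
    stop("zero internal-standard area in sample(s): ",
         paste(zero_rows, collapse = ", "))
  values <- areas[, mets, drop = FALSE] / areas[, map, drop = FALSE]
  colnames(values) <- mets
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample_id = rownames(areas) %||%
                                as.character(seq_len(nrow(areas))))
  metabolite_matrix(values, sample_meta, "raw_relative")
}

#' Full peak-table preprocessing
#'
#' Runs the standard chain on a [peak_table()]: S/N computation against the
#' extraction blanks, the detection filter, and internal-standard
#' normalization of the kept metabolites.
#'
#' @param pt A `peak_table`.
#' @param snr_threshold,min_fraction Detection-filter parameters.
#' @param is_assignment Internal-standard mapping; default: the first
#'   designated internal standard for all metabolites.
#' @param zero_blank Passed to [compute_snr()].
#' @return A `metabolite_matrix` in state `"raw_relative"` containing only
#'   the detected metabolites.
#' @export
preprocess_peaks <- function(pt, snr_threshold = 2, min_fraction = 0.5,
                             is_assignment = NULL,
                             zero_blank = c("error", "substitute")) {
  stopifnot(inherits(pt, "peak_table"))
  snr <- compute_snr(pt$areas, pt$blank_areas, zero_blank)
  kept <- detection_filter(snr, snr_threshold, min_fraction,
                           exclude = pt$internal_standard_ids)
  is_assignment <- is_assignment %||% pt$internal_standard_ids[1]
  keep_cols <- c(kept, unique(unname(is_assignment)))
  normalize_by_internal_standard(pt$areas[, keep_cols, drop = FALSE],
                                 is_assignment, pt$sample_meta)
}

apply_columnwise <- function(x, fun, state) {
  v <- mm_values(x)
  out <- apply(v, 2, fun)
  if (!is.matrix(out)) out <- matrix(out, nrow(v), ncol(v), dimnames = dimnames(v))
  dimnames(out) <- dimnames(v)
  if (inherits(x, "metabolite_matrix"))
    metabolite_matrix(out, x$sample_meta, state)
  else out
}

#' Column-wise standardization (z-scores)
#'
#' Centers each metabolite to mean zero and scales to standard deviation one
#' using the population SD (divisor n). Constant columns are an error.
#'
#' @param x A `metabolite_matrix` or plain numeric matrix.
#' @return Same type as the input; for a `metabolite_matrix`, state becomes
#'   `"standardized"`.
#' @export
standardize_profiles <- function(x) {
  v <- mm_values(x)
  sds <- apply(v, 2, sd_pop)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(v)[sds == 0] %||% which(sds == 0), collapse = ", "))
  apply_columnwise(x, function(col) (col - mean(col)) / sd_pop(col),
                   "standardized")
}

#' Column-wise 0-1 scaling
#'
#' Maps each metabolite linearly onto `[0, 1]`: `(x - min) / (max - min)`.
#' Constant columns are an error.
#'
#' @inheritParams standardize_profiles
#' @return Same type as the input; state becomes `"scaled01"`.
#' @export
scale01_profiles <- function(x) {
  v <- mm_values(x)
  rng <- apply(v, 2, function(col) diff(range(col)))
  if (any(rng == 0))
    stop("constant column(s): ",
         paste(colnames(v)[rng == 0] %||% which(rng == 0), collapse = ", "))
  apply_columnwise(x, function(col) (col - min(col)) / (max(col) - min(col)),
                   "scaled01")
}

#' Read a peak table from CSV files
#'
#' Reads the sample peak-area CSV (metadata columns `sample_id`,
#' `experiment`, `cultivar`, `plant`, `datetime`, `replicate` followed by
#' compound columns) and the companion blank CSV (`compound` column followed
#' by one column per blank replicate), as written by [write_dataset()].
#'
#' @param peaks_csv,blanks_csv File paths.
#' @param internal_standard_ids Compound ids of the internal standards.
#' @return A `peak_table`.
#' @export
read_peak_table <- function(peaks_csv, blanks_csv,
                            internal_standard_ids = c("IS1", "IS2")) {
  peaks <- read.csv(peaks_csv, check.names = FALSE)
  meta_cols <- c("sample_id", "experiment", "cultivar", "plant", "datetime",
                 "replicate")
  meta_cols <- intersect(meta_cols, names(peaks))
  meta <- peaks[meta_cols]
  areas <- as.matrix(peaks[setdiff(names(peaks), meta_cols)])
  rownames(areas) <- meta$sample_id
  blanks <- read.csv(blanks_csv, check.names = FALSE)
  blank_areas <- as.matrix(blanks[setdiff(names(blanks), "compound")])
  rownames(blank_areas) <- blanks$compound
  peak_table(areas, blank_areas, internal_standard_ids, meta)
}
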