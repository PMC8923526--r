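#' Default pipeline configuration
#'
#' All study constants live here rather than in the code: the S/N threshold
#' of 2 with the more-than-half sample fraction, the penalty grid from
#' 5e-5 to 0.5 with 50 points, 10 cross-validation folds, the elbow
#' tolerance, the 15th-percentile network threshold, and the 0.5 dendrogram
#' cut. The default synthetic design is one time-series experiment plus two
#' snapshot experiments with batch shifts.
#'
#' @param ... Named overrides merged over the defaults (top-level blocks:
#'   `synthetic`, `preprocessing`, `model`, `cluster`, `network`).
#' @return Nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    synthetic = list(
      seed = 1,
      experiments = data.frame(
        label = c("TK01", "IA04", "IA06"),
        shift = c(0, 0.6, 1.0),
        design = c("timeseries", "snapshot", "snapshot"))),
    preprocessing = list(snr_threshold = 2, min_fraction = 0.5),
    model = list(alpha_min = 5e-5, alpha_max = 0.5, grid_length = 50,
                 k = 10, seed = 7, elbow_tol = 0.02,
                 variants = c("metabolome", "environment", "combined")),
    cluster = list(cut_height = 0.5,
                   methods = c("average", "single", "complete", "weighted",
                               "centroid", "median", "ward")),
    network = list(percentile = 0.15,
                   characteristics = c("experiment", "cultivar",
                                       "sampling_time", "day_night"))
  )
  over <- list(...)
  for (blk in names(over)) {
    if (is.list(over[[blk]]) && !is.data.frame(over[[blk]]) &&
        blk %in% names(cfg)) {
      for (nm in names(over[[blk]])) cfg[[blk]][[nm]] <- over[[blk]][[nm]]
    } else {
      cfg[[blk]] <- over[[blk]]
    }
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level blocks as in [default_config()], merged
#'   over the defaults. An `experiments` entry under `synthetic` may be a
#'   list of records with `label`, `shift`, `design`.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic$experiments) && !is.data.frame(y$synthetic$experiments))
    y$synthetic$experiments <- do.call(rbind, lapply(y$synthetic$experiments,
                                                     as.data.frame))
  do.call(default_config, y)
}

add_sample_characteristics <- function(meta) {
  dt <- as.POSIXct(meta$datetime, tz = "UTC",
                   format = "%Y-%m-%dT%H:%M:%SZ")
  meta$sampling_time <- format(dt, "%H:%M", tz = "UTC")
  meta$day_night <- day_night_labels(dt)
  meta
}

fit_variant <- function(X, y, mcfg) {
  grid <- lasso_alpha_grid(mcfg$alpha_min, mcfg$alpha_max, mcfg$grid_length)
  sweep <- alpha_sweep(X, y, alpha_grid = grid, k = mcfg$k, seed = mcfg$seed)
  list(sweep = sweep, selection = select_elbow(sweep, tol = mcfg$elbow_tol))
}

#' Run the full analysis pipeline
#'
#' Executes the whole study flow on synthetic data: simulate, preprocess
#' (S/N detection filter on the primary time-series experiment, internal
#' standard normalization), derive anthesis rates and pair them with
#' samples, fit the penalty sweep for the metabolome / environment /
#' combined variants with elbow selection, re-fit the selected panel on the
#' combined multi-experiment data (minimum cross-validated MSE), PCA,
#' hierarchical clustering with cophenetic linkage selection,
#' correspondence-analysis association networks, and the diurnal-stability
#' screen. Every stage writes its output under `out_dir` and is re-loadable
#' from those files; a manifest with configuration, seeds, metrics, and
#' per-file checksums is written at the end. Reruns with the same
#' configuration produce byte-identical manifests.
#'
#' @param config Configuration from [default_config()] or [read_config()].
#' @param out_dir Output directory.
#' @param seed Optional override of the synthetic-data seed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) config$synthetic$seed <- seed
  stages <- character()

  # -- simulate ---------------------------------------------------------
  spec <- do.call(synthetic_spec, config$synthetic)
  ds <- generate_dataset(spec)
  data_dir <- file.path(out_dir, "data")
  files <- write_dataset(ds, data_dir)
  stages <- c(stages, "simulate")

  # -- preprocess -------------------------------------------------------
  pt <- read_peak_table(files["peaks"], files["blanks"])
  meta <- add_sample_characteristics(pt$sample_meta)
  primary <- config$synthetic$experiments$label[
    config$synthetic$experiments$design == "timeseries"][1]
  if (is.na(primary)) primary <- config$synthetic$experiments$label[1]
  prim_rows <- meta$experiment == primary
  snr <- compute_snr(pt$areas, pt$blank_areas)
  kept <- detection_filter(snr[prim_rows, , drop = FALSE],
                           threshold = config$preprocessing$snr_threshold,
                           min_fraction = config$preprocessing$min_fraction,
                           exclude = pt$internal_standard_ids)
  mm <- normalize_by_internal_standard(
    pt$areas[, c(kept, pt$internal_standard_ids[1]), drop = FALSE],
    pt$internal_standard_ids[1], meta)
  matrix_path <- file.path(out_dir, "relative_contents.csv")
  write.csv(cbind(meta, as.data.frame(mm$values)), matrix_path,
            row.names = FALSE)
  stages <- c(stages, "preprocess")

  # -- rates ------------------------------------------------------------
  rates <- anthesis_rates(read.csv(files["anthesis"]))
  y_all <- assign_rates_to_samples(rates, meta)
  rates_path <- file.path(out_dir, "rates.csv")
  write.csv(rates, rates_path, row.names = FALSE)
  stages <- c(stages, "rates")

  # -- fit variants on the primary experiment ---------------------------
  env <- read.csv(files["env"])
  env_m <- as.matrix(env[match(meta$sample_id, env$sample_id), -1])
  rownames(env_m) <- meta$sample_id
  X_met <- standardize_profiles(mm$values[prim_rows, , drop = FALSE])
  X_env <- standardize_profiles(env_m[prim_rows, , drop = FALSE])
  y <- y_all[prim_rows]
  variant_X <- list(metabolome = X_met, environment = X_env,
                    combined = cbind(X_met, X_env))
  fits <- lapply(config$model$variants,
                 function(v) fit_variant(variant_X[[v]], y, config$model))
  names(fits) <- config$model$variants
  for (v in names(fits)) {
    sw <- fits[[v]]$sweep
    write.csv(sw[setdiff(names(sw), "support_ids")],
              file.path(out_dir, paste0("sweep_", v, ".csv")),
              row.names = FALSE)
    sel <- fits[[v]]$selection
    jsonlite::write_json(
      list(alpha = sel$alpha, support_ids = sel$support_ids,
           train_r2 = sel$train_r2, cv_r2 = sel$cv_r2, cv_mse = sel$cv_mse,
           w0 = sel$w0, w = as.list(sel$w[sel$w != 0])),
      file.path(out_dir, paste0("model_", v, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stages <- c(stages, "fit")

  # -- refit the panel on all experiments -------------------------------
  panel <- fits$metabolome$selection$support_ids
  refit <- NULL
  if (length(unique(meta$experiment)) > 1 && length(panel) > 0) {
    by_exp <- split(seq_len(nrow(meta)), meta$experiment)
    refit <- refit_panel(panel,
                         lapply(by_exp, function(i) mm$values[i, , drop = FALSE]),
                         lapply(by_exp, function(i) y_all[i]),
                         k = config$model$k, seed = config$model$seed)
    jsonlite::write_json(
      list(panel = panel, alpha = refit$selection$alpha,
           support_ids = refit$selection$support_ids,
           train_r2 = refit$selection$train_r2,
           cv_r2 = refit$selection$cv_r2,
           cv_mse = refit$selection$cv_mse),
      file.path(out_dir, "refit.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stages <- c(stages, "refit")
  }

  # -- profile structure ------------------------------------------------
  pca <- pca_profiles(X_met, n_components = 2)
  write.csv(data.frame(sample_id = meta$sample_id[prim_rows], pca$scores),
            file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  cluster <- NULL
  if (length(panel) >= 3) {
    # panel profiles across all experiments, standardized per experiment
    parts <- lapply(split(seq_len(nrow(meta)), meta$experiment), function(i)
      standardize_profiles(mm$values[i, panel, drop = FALSE]))
    panel_mat <- do.call(rbind, parts)[order(unlist(split(seq_len(nrow(meta)), meta$experiment))), , drop = FALSE]
    cd <- correlation_distance_matrix(panel_mat)
    linksel <- select_linkage(cd, config$cluster$methods)
    clusters <- cut_clusters(linksel$dendrogram, config$cluster$cut_height)
    write.csv(linksel$table, file.path(out_dir, "cophenetic_table.csv"),
              row.names = FALSE)
    write.csv(data.frame(metabolite = names(clusters), cluster = clusters),
              file.path(out_dir, "clusters.csv"), row.names = FALSE)
    cluster <- list(best_method = linksel$best_method,
                    n_clusters = length(unique(clusters)))
    stages <- c(stages, "cluster")
  } else {
    panel_mat <- NULL
  }
  stages <- c(stages, "pca")

  # -- correspondence-analysis networks + diurnal screen ----------------
  network <- NULL
  stability <- NULL
  if (!is.null(panel_mat)) {
    ca <- correspondence_analysis(nonneg_shift(panel_mat))
    el <- percentile_threshold(cross_edge_table(cross_distances(ca)),
                               config$network$percentile)
    for (ch in config$network$characteristics) {
      agg <- aggregate_by_characteristic(el, meta, ch)
      utils::write.table(agg, file.path(out_dir, paste0("network_", ch, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    mm_el <- percentile_threshold(
      pairwise_edge_table(pairwise_distances(ca$col_coords)),
      config$network$percentile)
    utils::write.table(mm_el$edges[mm_el$edges$passed, ],
                       file.path(out_dir, "network_metabolites.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    dn_edges <- aggregate_by_characteristic(el, meta, "day_night")
    stability <- diurnal_stability(mm$values[prim_rows, , drop = FALSE],
                                   panel, dn_edges)
    write.csv(stability, file.path(out_dir, "diurnal_stability.csv"),
              row.names = FALSE)
    network <- list(threshold = el$threshold_value,
                    n_passed = sum(el$edges$passed),
                    n_metabolite_edges = sum(mm_el$edges$passed))
    stages <- c(stages, "canet", "diurnal")
  }

  # -- manifest ---------------------------------------------------------
  out_files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  out_files <- out_files[!grepl("manifest\\.json$", out_files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("anthemet")),
    config = config,
    stages = stages,
    metrics = list(
      n_samples = nrow(meta),
      n_detected_metabolites = length(kept),
      variants = compare_variants(fits),
      panel_size = length(panel),
      refit = if (!is.null(refit)) list(
        n_selected = refit$selection$support_size,
        train_r2 = refit$selection$train_r2,
        cv_r2 = refit$selection$cv_r2,
        cv_mse = refit$selection$cv_mse) else NULL,
      pca_contribution_ratios = pca$contribution_ratios[1:2],
      cluster = cluster,
      network = network,
      stability_sd_range = if (!is.null(stability))
        range(stability$sd_scaled) else NULL),
    checksums = as.list(setNames(unname(tools::md5sum(out_files)),
                                 sub(paste0("^", out_dir, "/?"), "", out_files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Tabulate prediction accuracies across model variants
#'
#' @param fits Named list of variant fits as produced inside
#'   [run_pipeline()] (each with a `selection`), or a manifest list with
#'   `metrics$variants` already tabulated.
#' @return Data frame with one row per variant: `variant`, `train_r2`,
#'   `cv_r2`, `cv_mse`, `support_size`.
#' @export
compare_variants <- function(fits) {
  if (!is.null(fits$metrics$variants)) return(as.data.frame(fits$metrics$variants))
  stopifnot(length(fits) >= 1)
  do.call(rbind, lapply(names(fits), function(v) {
    s <- fits[[v]]$selection
    data.frame(variant = v, train_r2 = s$train_r2, cv_r2 = s$cv_r2,
               cv_mse = s$cv_mse, support_size = s$support_size)
  }))
}
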