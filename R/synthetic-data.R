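#' Specification of a synthetic anthesis-metabolome study
#'
#' Describes a ground-truth-known dataset emulating the study design this
#' package targets: 2-hourly leaf sampling over 24 h, repeated weekly across
#' cultivars and experiments, a targeted-metabolomics peak table with
#' internal standards and extraction blanks, and an anthesis rate linearly
#' dependent on a sparse subset of metabolites.
#'
#' Metabolite contents are generated on a latent z-scale as
#' `z = loading * block_factor + A * sin(2*pi*(hour - phase)/24) + noise`,
#' where a cell is an experiment-cultivar-week combination; the experiment
#' batch shift is a measurement artifact added on the way to peak areas
#' only. The phenotype-linked metabolites (the support) are grouped
#' into a few coherent latent blocks of their own, mirroring the observation
#' that predictor metabolites form tightly correlated modules; their block
#' factors vary per cell (the slowly changing physiological state that
#' drives flowering), while the factors of the remaining blocks vary per
#' sampling occasion (cell x hour), giving correlated short-horizon
#' fluctuations without week-level signal. The true weekly rate of a cell is
#' `intercept_rate - rate_trend*(week-1) + sum(beta * zbar) + noise`, with
#' `zbar` the realized weekly mean content, and is broadcast to every leaf
#' sample of that cell. One designated marker metabolite has zero diurnal
#' amplitude but a large coefficient (a stable, strongly predictive marker).
#'
#' @param n_weeks Number of weekly sampling campaigns.
#' @param timepoints_per_day Samples per 24-h day (12 = every 2 h).
#' @param replicates Leaf replicates per cultivar and timepoint.
#' @param cultivars Cultivar labels.
#' @param experiments Data frame with columns `label`, `shift` (batch shift
#'   in z-units added to every metabolite), and `design` (`"timeseries"` or
#'   `"snapshot"`; snapshots sample only around midday in two of the weeks).
#' @param m_metabolites Number of genuinely detectable metabolites.
#' @param n_undetected Extra blank-dominated compounds (true negatives for
#'   the detection filter).
#' @param n_blocks Total number of correlated latent blocks.
#' @param n_signal_blocks Blocks reserved for the support metabolites.
#' @param support_indices Indices (in `1:m_metabolites`) of the
#'   phenotype-linked metabolites.
#' @param beta Optional named effect sizes (rate units per z-unit) for the
#'   support; default: magnitudes drawn from `beta_range` with one sign per
#'   signal block.
#' @param beta_range Range of effect-size magnitudes.
#' @param marker_beta Effect size of the designated stable marker (the first
#'   support index).
#' @param signal_sd Target standard deviation (flowers per week) of the
#'   metabolite-driven rate component across cells; the drawn effect sizes
#'   are rescaled once so the realized signal matches it, which pins the
#'   generator's predictability at a stable level across seeds. `NULL`
#'   disables the calibration.
#' @param support_block_cor Correlation between the cell-level factors of
#'   support metabolites within a signal block; the remainder of each
#'   factor is metabolite-specific. 1 means the block factor is fully
#'   shared.
#' @param week_alignment Fraction of the signal-block factor variance
#'   aligned with the (standardized) week axis, emulating seasonal drift of
#'   the developmental modules; the sign of the alignment is drawn per
#'   block.
#' @param intercept_rate Baseline rate, flowers per week.
#' @param rate_trend Weekly decline of the baseline, flowers per week.
#' @param diurnal_amplitudes Optional per-metabolite amplitudes (z-units);
#'   default: drawn from `amplitude_range` with a fraction `prop_stable`
#'   set to 0 ("stable" metabolites), and 0 for the marker.
#' @param amplitude_range Range of diurnal amplitudes.
#' @param prop_stable Fraction of metabolites with zero diurnal amplitude.
#' @param noise_sd_metabolite SD of the per-sample metabolite noise
#'   (z-units).
#' @param noise_sd_rate SD of the weekly rate noise (flowers per week). The
#'   realized noise draws are rescaled to this SD exactly, so the
#'   generator's signal-to-noise ratio does not wander across seeds.
#' @param content_scale Log-area units per latent z-unit: peak areas are
#'   `exp(content_scale * z)` times the abundance and internal-standard
#'   factors, giving right-skewed positive areas with a realistic
#'   coefficient of variation (about 40 percent at the default).
#' @param block_loading_range Range of block-factor loadings.
#' @param is_response_factor Mean internal-standard peak area (area units).
#' @param blank_level Mean extraction-blank peak area.
#' @param blank_replicates Number of blank replicate measurements.
#' @param start_date First anthesis observation date.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   output files.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_weeks = 4,
                           timepoints_per_day = 12,
                           replicates = 2,
                           cultivars = c("RGK", "CFM"),
                           experiments = data.frame(label = "TK01",
                                                    shift = 0,
                                                    design = "timeseries"),
                           m_metabolites = 161,
                           n_undetected = 40,
                           n_blocks = 8,
                           n_signal_blocks = 3,
                           support_indices = seq_len(29),
                           beta = NULL,
                           beta_range = c(0.12, 0.25),
                           marker_beta = 0.35,
                           signal_sd = 2.0,
                           support_block_cor = 1.0,
                           week_alignment = 0.4,
                           intercept_rate = 12,
                           rate_trend = 0,
                           diurnal_amplitudes = NULL,
                           amplitude_range = c(0.2, 1.0),
                           prop_stable = 0.2,
                           noise_sd_metabolite = 0.75,
                           noise_sd_rate = 0.9,
                           content_scale = 0.4,
                           block_loading_range = c(0.55, 0.8),
                           is_response_factor = 5e4,
                           blank_level = 1000,
                           blank_replicates = 3,
                           start_date = as.Date("2016-08-09"),
                           seed = 1) {
  spec <- as.list(environment())
  fail <- function(field, why) stop("invalid '", field, "': ", why)
  if (n_weeks < 1) fail("n_weeks", "must be >= 1")
  if (timepoints_per_day < 1) fail("timepoints_per_day", "must be >= 1")
  if (replicates < 1) fail("replicates", "must be >= 1")
  if (m_metabolites < 2) fail("m_metabolites", "must be >= 2")
  if (!all(support_indices %in% seq_len(m_metabolites)))
    fail("support_indices", "must be a subset of 1:m_metabolites")
  if (anyDuplicated(support_indices)) fail("support_indices", "duplicates")
  if (!is.null(diurnal_amplitudes)) {
    if (length(diurnal_amplitudes) != m_metabolites)
      fail("diurnal_amplitudes", "needs one amplitude per metabolite")
    if (any(diurnal_amplitudes < 0)) fail("diurnal_amplitudes", "must be >= 0")
  }
  if (!is.null(beta) && length(beta) != length(support_indices))
    fail("beta", "needs one effect per support index")
  if (noise_sd_metabolite < 0) fail("noise_sd_metabolite", "must be >= 0")
  if (noise_sd_rate < 0) fail("noise_sd_rate", "must be >= 0")
  if (n_blocks <= n_signal_blocks)
    fail("n_blocks", "must exceed n_signal_blocks")
  if (n_signal_blocks < 1) fail("n_signal_blocks", "must be >= 1")
  if (support_block_cor < 0 || support_block_cor > 1)
    fail("support_block_cor", "must be in [0, 1]")
  if (week_alignment < 0 || week_alignment > 1)
    fail("week_alignment", "must be in [0, 1]")
  if (!all(c("label", "shift", "design") %in% names(experiments)))
    fail("experiments", "needs columns label, shift, design")
  if (!all(experiments$design %in% c("timeseries", "snapshot")))
    fail("experiments", "design must be 'timeseries' or 'snapshot'")
  if (is_response_factor <= 0) fail("is_response_factor", "must be > 0")
  if (blank_level <= 0) fail("blank_level", "must be > 0")
  structure(spec, class = "synthetic_spec")
}

sample_grid <- function(spec) {
  grids <- lapply(seq_len(nrow(spec$experiments)), function(e) {
    exp <- spec$experiments[e, ]
    if (exp$design == "timeseries") {
      weeks <- seq_len(spec$n_weeks)
      hours <- seq(0, 24 - 24 / spec$timepoints_per_day,
                   by = 24 / spec$timepoints_per_day)
    } else {
      weeks <- unique(c(max(1L, spec$n_weeks %/% 2L), spec$n_weeks))
      hours <- c(10, 12, 14)
    }
    g <- expand.grid(replicate = seq_len(spec$replicates), hour = hours,
                     week = weeks, cultivar = spec$cultivars,
                     stringsAsFactors = FALSE)
    g$experiment <- exp$label
    g$shift <- exp$shift
    g
  })
  g <- do.call(rbind, grids)
  g$date <- spec$start_date + 7 * (g$week - 1) + 4
  g$datetime <- format(as.POSIXct(paste(g$date, sprintf("%02d:00:00", g$hour)),
                                  tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  g$plant <- paste0(g$cultivar, "-p", g$replicate)
  g$cell <- paste(g$experiment, g$cultivar, g$week, sep = ":")
  g$sample_id <- sprintf("%s_%s_w%d_h%02d_r%d", g$experiment, g$cultivar,
                         g$week, g$hour, g$replicate)
  g
}

#' Generate a synthetic dataset with known ground truth
#'
#' Realizes a [synthetic_spec()]: latent metabolite contents, weekly anthesis
#' rates driven by the support metabolites, peak areas obtained by mapping
#' contents through `exp()` (peak areas are nonnegative and right-skewed)
#' and multiplying by the sample's internal-standard area with mild
#' multiplicative noise, extraction blanks, blank-dominated undetectable
#' compounds, and white-noise environmental covariates.
#'
#' @param spec A `synthetic_spec`.
#' @return Object of class `synthetic_dataset`: `peaks` (a [peak_table()]),
#'   `anthesis` (group, date, cumulative_count), `env` (white-noise
#'   environmental factors per sample), `truth` (support, effect sizes,
#'   amplitudes, per-cell true rates, per-sample broadcast rates, realized
#'   R^2), and the `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed, {
    m <- spec$m_metabolites
    met_ids <- sprintf("met%03d", seq_len(m))
    support <- sort(spec$support_indices)
    marker <- support[1]
    s <- length(support)

    # block structure: support metabolites fill the signal blocks
    blocks <- integer(m)
    sig_split <- split(support, rep(seq_len(spec$n_signal_blocks),
                                    length.out = s))
    for (b in seq_along(sig_split)) blocks[sig_split[[b]]] <- b
    rest <- setdiff(seq_len(m), support)
    n_rest_blocks <- spec$n_blocks - spec$n_signal_blocks
    blocks[rest] <- spec$n_signal_blocks +
      rep(seq_len(n_rest_blocks), length.out = length(rest))

    loadings <- runif(m, spec$block_loading_range[1], spec$block_loading_range[2])
    amplitudes <- spec$diurnal_amplitudes %||% {
      a <- runif(m, spec$amplitude_range[1], spec$amplitude_range[2])
      a[runif(m) < spec$prop_stable] <- 0
      a
    }
    amplitudes[marker] <- 0
    phases <- runif(m, 0, 24)

    beta <- spec$beta %||% {
      sign_block <- sample(c(-1, 1), spec$n_signal_blocks, replace = TRUE)
      runif(s, spec$beta_range[1], spec$beta_range[2]) *
        sign_block[rep(seq_len(spec$n_signal_blocks), length.out = s)]
    }
    names(beta) <- met_ids[support]
    beta[met_ids[marker]] <- spec$marker_beta

    grid <- sample_grid(spec)
    n <- nrow(grid)
    cells <- unique(grid[c("experiment", "cultivar", "week", "cell", "shift")])
    cell_idx <- match(grid$cell, cells$cell)

    # Latent block factors. Signal blocks (the support's modules) track the
    # slowly varying physiological state: one draw per experiment-cultivar-
    # week cell, partially aligned with the seasonal week axis (development
    # drives both the metabolite modules and flowering). The remaining
    # blocks co-fluctuate on the hour scale: one draw per sampling occasion
    # (cell x hour), centered within each cell so they carry block-level
    # correlation but no week-level signal.
    week_std <- (cells$week - mean(cells$week)) /
      max(sd_pop(cells$week), .Machine$double.eps)
    phi <- spec$week_alignment
    u_cell <- sqrt(phi) * outer(sample(c(-1, 1), spec$n_signal_blocks,
                                       replace = TRUE), week_std) +
      sqrt(1 - phi) * matrix(rnorm(spec$n_signal_blocks * nrow(cells)),
                             spec$n_signal_blocks, nrow(cells))
    occ <- paste(grid$cell, grid$hour, sep = "@")
    occ_levels <- unique(occ)
    occ_idx <- match(occ, occ_levels)
    occ_cell <- sub("@.*$", "", occ_levels)
    n_rest <- spec$n_blocks - spec$n_signal_blocks
    u_occ <- matrix(rnorm(n_rest * length(occ_levels)), n_rest,
                    length(occ_levels))
    for (b in seq_len(n_rest)) # remove any week-level leakage
      u_occ[b, ] <- u_occ[b, ] - ave(u_occ[b, ], occ_cell)

    # support metabolites share their block factor at correlation
    # support_block_cor and keep an idiosyncratic cell-level component of
    # their own, so each one carries distinct week-level information
    rho <- spec$support_block_cor
    nu <- matrix(rnorm(sum(blocks <= spec$n_signal_blocks) * nrow(cells)),
                 ncol = nrow(cells))
    factor_mat <- matrix(0, n, m)
    is_sig <- blocks <= spec$n_signal_blocks
    factor_mat[, is_sig] <-
      sqrt(rho) * t(u_cell[blocks[is_sig], cell_idx, drop = FALSE]) +
      sqrt(1 - rho) * t(nu[, cell_idx, drop = FALSE])
    factor_mat[, !is_sig] <- t(u_occ[blocks[!is_sig] - spec$n_signal_blocks,
                                     occ_idx, drop = FALSE])

    # true latent contents; the experiment batch shift is a measurement
    # artifact and is added only on the way to peak areas, never to the
    # contents that drive the phenotype
    z <- rep(loadings, each = n) * factor_mat +
      outer(grid$hour, seq_len(m),
            function(h, j) amplitudes[j] * sin(2 * pi * (h - phases[j]) / 24)) +
      matrix(rnorm(n * m, 0, spec$noise_sd_metabolite), n, m)
    colnames(z) <- met_ids

    # realized weekly mean contents per cell -> true rates
    zbar <- apply(z[, support, drop = FALSE], 2,
                  function(col) tapply(col, grid$cell, mean))
    zbar <- zbar[cells$cell, , drop = FALSE]
    rate_noise <- rnorm(nrow(cells), 0, spec$noise_sd_rate)
    if (spec$noise_sd_rate > 0 && nrow(cells) > 1 && sd_pop(rate_noise) > 0)
      rate_noise <- rate_noise * spec$noise_sd_rate / sd_pop(rate_noise)
    signal <- drop(zbar %*% beta[met_ids[support]])
    # calibrate the drawn effect sizes so the realized metabolite-driven
    # component has the specified spread (stable predictability over
    # seeds); the spread is measured within the primary time-series
    # experiment so that batch shifts and the noisier snapshot weekly
    # means do not dominate it
    prim_lab <- spec$experiments$label[spec$experiments$design == "timeseries"][1]
    if (is.na(prim_lab)) prim_lab <- spec$experiments$label[1]
    signal_within <- (signal - ave(signal, cells$experiment))[
      cells$experiment == prim_lab]
    if (!is.null(spec$signal_sd) && sd_pop(signal_within) > 0) {
      scale_c <- spec$signal_sd / sd_pop(signal_within)
      beta <- beta * scale_c
      signal <- signal * scale_c
    }
    rate_raw <- spec$intercept_rate - spec$rate_trend * (cells$week - 1) +
      signal + rate_noise
    truncated <- rate_raw < 0
    cells$true_rate <- pmax(rate_raw, 0)

    y <- cells$true_rate[cell_idx]
    # effective noise includes any truncation adjustment
    noise_eff <- (rate_noise + (cells$true_rate - rate_raw))[cell_idx]
    r2_true <- if (sd_pop(y) > 0) {
      1 - sum((noise_eff - mean(noise_eff))^2) / sum((y - mean(y))^2)
    } else NA_real_

    # cumulative anthesis per experiment:cultivar over week boundaries
    anthesis <- do.call(rbind, lapply(
      split(cells, paste(cells$experiment, cells$cultivar, sep = ":")),
      function(cc) {
        cc <- cc[order(cc$week), ]
        full <- data.frame(week = seq_len(spec$n_weeks))
        full$rate <- cc$true_rate[match(full$week, cc$week)]
        # weeks not sampled in snapshot designs still accrue flowers;
        # interpolate their rate from the nearest sampled week
        if (anyNA(full$rate)) {
          near <- vapply(full$week, function(w) cc$week[which.min(abs(cc$week - w))], numeric(1))
          full$rate[is.na(full$rate)] <- cc$true_rate[match(near[is.na(full$rate)], cc$week)]
        }
        data.frame(group = paste(cc$experiment[1], cc$cultivar[1], sep = ":"),
                   date = spec$start_date + 7 * (0:spec$n_weeks),
                   cumulative_count = cumsum(c(0, full$rate)))
      }))
    rownames(anthesis) <- NULL

    # peak areas: exp() of latent content x internal standard x mult. noise
    g <- rlnorm(m, 0, 0.6) # per-metabolite abundance/response factor
    is1 <- rlnorm(n, log(spec$is_response_factor), 0.08)
    is2 <- rlnorm(n, log(spec$is_response_factor / 4), 0.08)
    areas <- exp(spec$content_scale * (z + grid$shift)) * rep(g, each = n) * is1 *
      matrix(exp(rnorm(n * m, 0, 0.05)), n, m)
    areas[matrix(runif(n * m) < 0.01, n, m)] <- 0 # below detection limit

    und_ids <- if (spec$n_undetected > 0)
      sprintf("und%03d", seq_len(spec$n_undetected)) else character()
    und <- matrix(spec$blank_level *
                    exp(rnorm(n * spec$n_undetected, 0, 0.5)),
                  n, spec$n_undetected, dimnames = list(NULL, und_ids))

    all_areas <- cbind(areas, und, IS1 = is1, IS2 = is2)
    rownames(all_areas) <- grid$sample_id

    compound_ids <- colnames(all_areas)
    blank <- matrix(abs(rnorm(length(compound_ids) * spec$blank_replicates,
                              spec$blank_level, 0.1 * spec$blank_level)),
                    length(compound_ids), spec$blank_replicates,
                    dimnames = list(compound_ids,
                                    paste0("blank_", seq_len(spec$blank_replicates))))
    blank["IS1", ] <- rlnorm(spec$blank_replicates,
                             log(spec$is_response_factor), 0.05)
    blank["IS2", ] <- rlnorm(spec$blank_replicates,
                             log(spec$is_response_factor / 4), 0.05)

    meta <- grid[c("sample_id", "experiment", "cultivar", "plant",
                   "datetime", "replicate")]
    rownames(meta) <- NULL
    pt <- peak_table(all_areas, blank, c("IS1", "IS2"), meta)

    env <- data.frame(sample_id = grid$sample_id,
                      solar_irradiance = 300 + 120 * rnorm(n),
                      air_temperature = 25 + 3 * rnorm(n),
                      relative_humidity = 70 + 8 * rnorm(n),
                      co2 = 500 + 100 * rnorm(n))

    truth <- list(support_ids = met_ids[support],
                  marker_id = met_ids[marker],
                  beta = beta,
                  amplitudes = setNames(amplitudes, met_ids),
                  phases = setNames(phases, met_ids),
                  blocks = setNames(blocks, met_ids),
                  loadings = setNames(loadings, met_ids),
                  cells = cells[c("experiment", "cultivar", "week", "true_rate")],
                  zbar_support = zbar,
                  y = setNames(y, grid$sample_id),
                  r2_true = r2_true,
                  n_truncated_rates = sum(truncated))

    structure(list(peaks = pt, anthesis = anthesis, env = env,
                   truth = truth, spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$peaks$areas), "samples x",
      ncol(x$peaks$areas), "compounds;", length(x$truth$support_ids),
      "support metabolites; realized R^2 =",
      round(x$truth$r2_true, 3), "\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `peaks.csv` (sample metadata followed by one column per compound),
#' `blanks.csv` (compound, one column per blank replicate), `anthesis.csv`
#' (group, date, cumulative_count), `env.csv`, and `ground_truth.json`.
#' Output is byte-identical for identical spec + seed.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(peaks = file.path(dir, "peaks.csv"),
             blanks = file.path(dir, "blanks.csv"),
             anthesis = file.path(dir, "anthesis.csv"),
             env = file.path(dir, "env.csv"),
             truth = file.path(dir, "ground_truth.json"))
  pt <- dataset$peaks
  peaks_df <- cbind(pt$sample_meta, as.data.frame(pt$areas))
  write.csv(peaks_df, paths["peaks"], row.names = FALSE)
  blanks_df <- cbind(data.frame(compound = rownames(pt$blank_areas)),
                     as.data.frame(pt$blank_areas))
  write.csv(blanks_df, paths["blanks"], row.names = FALSE)
  write.csv(dataset$anthesis, paths["anthesis"], row.names = FALSE)
  write.csv(dataset$env, paths["env"], row.names = FALSE)
  truth <- dataset$truth
  truth$cells <- as.data.frame(truth$cells)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
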