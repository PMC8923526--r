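test_that("the nonnegative shift subtracts the single global minimum", {
  x <- matrix(c(-2.3, 0, 1, 4), 2, 2)
  s <- nonneg_shift(x)
  expect_equal(min(s), 0)
  expect_equal(s, x + 2.3)
  y <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(nonneg_shift(y), y)          # already nonnegative with min 0
  expect_equal(nonneg_shift(nonneg_shift(x)), nonneg_shift(x)) # idempotent
})

test_that("correspondence analysis satisfies the chi-square identities", {
  for (s in 1:5) {
    set.seed(s)
    x <- random_nonneg_table(7, 5)
    ca <- correspondence_analysis(x)
    # inertia x grand total = Pearson chi-square statistic
    chi2 <- suppressWarnings(chisq.test(x)$statistic)
    expect_equal(ca$total_inertia * sum(x), unname(chi2), tolerance = 1e-10)
    expect_equal(sum(ca$principal_inertias), ca$total_inertia,
                 tolerance = 1e-10)
    expect_equal(ca$principal_inertias, ca$singular_values^2)
    expect_equal(ca$d, 4)
    # mass-weighted centroids of both coordinate sets sit at the origin
    expect_equal(drop(ca$row_masses %*% ca$row_coords), rep(0, ca$d),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(drop(ca$col_masses %*% ca$col_coords), rep(0, ca$d),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # row-coordinate distances reproduce brute-force chi-square distances
    expect_equal(unname(pairwise_distances(ca$row_coords)),
                 chisq_row_distances(x), tolerance = 1e-10)
  }
})

test_that("degenerate and invalid tables are handled explicitly", {
  prop <- matrix(rep(c(1, 2, 3), each = 3), 3, 3, byrow = TRUE)
  expect_warning(ca <- correspondence_analysis(t(prop)), "proportional")
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)
  expect_equal(max(abs(ca$row_coords)), 0, tolerance = 1e-7)
  bad <- matrix(c(1, 2, 0, 0), 2, 2,
                dimnames = list(c("r1", "r2"), c("c1", "c2")))
  expect_error(correspondence_analysis(bad), "c2")
  expect_error(correspondence_analysis(t(bad)), "row sum")
  expect_error(correspondence_analysis(matrix(c(-1, 1, 1, 1), 2, 2)),
               "nonnegative")
})

test_that("cross distances are plain Euclidean over all dimensions", {
  ca <- list(row_coords = rbind(s1 = c(0, 0), s2 = c(1, 1)),
             col_coords = rbind(m1 = c(3, 4), m2 = c(0, 0)))
  class(ca) <- "ca_result"
  d <- cross_distances(ca)
  expect_equal(d["m1", "s1"], 5)      # 3-4-5 triangle by hand
  expect_equal(d["m2", "s1"], 0)      # coincident points
  expect_equal(d["m1", "s2"], sqrt(2^2 + 3^2))
  # invariance under a joint rotation of both coordinate sets
  th <- 0.7; Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ca2 <- ca
  ca2$row_coords <- ca$row_coords %*% Q
  ca2$col_coords <- ca$col_coords %*% Q
  expect_equal(cross_distances(ca2), d, tolerance = 1e-12)
})

test_that("percentile thresholding interpolates and admits strictly below", {
  el <- percentile_threshold(as.numeric(1:20), 0.15)
  expect_equal(el$threshold_value, 3.85)
  expect_equal(sum(el$edges$passed), 3)
  expect_equal(el$edges$distance[el$edges$passed], c(1, 2, 3))
  # all-equal distances admit nothing under the strict inequality
  expect_equal(sum(percentile_threshold(rep(2, 10))$edges$passed), 0)
  # at the 100th percentile everything but the maximum passes
  el2 <- percentile_threshold(as.numeric(1:7), 1.0)
  expect_equal(sum(el2$edges$passed), 6)
  expect_error(percentile_threshold(data.frame(distance = numeric(0))),
               "empty")
  # passed count is bounded by the percentile definition
  set.seed(2)
  d <- runif(403)
  el3 <- percentile_threshold(d, 0.15)
  expect_lte(sum(el3$edges$passed), 0.15 * length(d) + 1)
})

test_that("characteristic aggregation averages passed distances per level", {
  edges <- data.frame(node_a = c("m1", "m1", "m1", "m2"),
                      node_b = c("s1", "s2", "s3", "s1"),
                      distance = c(1, 3, 50, 2))
  el <- structure(list(edges = transform(edges, passed = distance < 10),
                       threshold_value = 10, percentile = 0.15),
                  class = "edge_list")
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     experiment = c("A", "A", "B"))
  agg <- aggregate_by_characteristic(el, meta, "experiment")
  expect_equal(agg$weight[agg$metabolite == "m1" & agg$level == "A"], 2)
  expect_equal(agg$weight[agg$metabolite == "m2" & agg$level == "A"], 2)
  # m1's only pair to level B failed the threshold: no edge
  expect_false(any(agg$metabolite == "m1" & agg$level == "B"))
  # sample order must not matter
  el_rev <- el; el_rev$edges <- el$edges[rev(seq_len(nrow(el$edges))), ]
  expect_equal(aggregate_by_characteristic(el_rev, meta, "experiment"), agg)
  # empty networks are valid
  el0 <- el; el0$edges$passed <- FALSE
  expect_equal(nrow(aggregate_by_characteristic(el0, meta, "experiment")), 0)
  meta_bad <- meta[1:2, ]
  expect_error(aggregate_by_characteristic(el, meta_bad, "experiment"),
               "unlabeled")
})

test_that("day/night labels follow the stated clock windows", {
  expect_equal(day_night_labels("18:00"), "day")
  expect_equal(day_night_labels("06:00"), "day")
  expect_equal(day_night_labels("02:00"), "night")
  expect_equal(day_night_labels(c(20, 22, 0, 4)), rep("night", 4))
  expect_equal(day_night_labels(as.POSIXct("2016-08-16 12:00", tz = "UTC")),
               "day")
  expect_error(day_night_labels("05:00"), "windows")
  expect_error(day_night_labels(19), "windows")
})

test_that("diurnal stability ranks flat series below fluctuating ones", {
  # constant-plus-one-outlier: SD of a 0/1 indicator with p = 1/11
  x <- cbind(spike = c(rep(0, 10), 1),
             square = rep(c(0, 1), length.out = 11))
  rec <- diurnal_stability(x)
  expect_equal(rec$sd_scaled[rec$metabolite_id == "spike"],
               sqrt(10) / 11, tolerance = 1e-12)
  sq <- rec$sd_scaled[rec$metabolite_id == "square"]
  expect_lt(abs(sq - 0.5), 0.01) # near the Bernoulli(1/2) maximum at n = 11
  expect_true(all(rec$sd_scaled <= 0.5 + 1e-12))
  expect_equal(rec$metabolite_id, c("spike", "square")) # ascending order
  expect_error(diurnal_stability(x[1, , drop = FALSE]), "2 timepoints")
  # day/night flags come from the aggregated network
  dn <- data.frame(metabolite = c("spike", "square", "square"),
                   level = c("day", "day", "night"))
  rec2 <- diurnal_stability(x, day_night_edges = dn)
  expect_true(rec2$day_association[rec2$metabolite_id == "spike"])
  expect_false(rec2$night_association[rec2$metabolite_id == "spike"])
  expect_true(all(unlist(rec2[rec2$metabolite_id == "square",
                              c("day_association", "night_association")])))
})

test_that("metabolites sharing a latent block sit closer in CA space", {
  ds <- generate_dataset(small_spec(seed = 4, m_metabolites = 30,
                                    support_indices = 1:10,
                                    n_blocks = 5, n_signal_blocks = 2,
                                    timepoints_per_day = 8, replicates = 2))
  mm <- preprocess_peaks(ds$peaks)
  z <- standardize_profiles(mm$values)
  ca <- correspondence_analysis(nonneg_shift(z))
  d <- pairwise_distances(ca$col_coords)
  blocks <- ds$truth$blocks[colnames(mm$values)]
  same <- outer(blocks, blocks, "==") & upper.tri(d)
  diff_b <- outer(blocks, blocks, "!=") & upper.tri(d)
  expect_lt(median(d[same]), median(d[diff_b]))
})

test_that("a high-amplitude sinusoid outranks a flat marker metabolite", {
  amps <- c(0, rep(0.1, 11), rep(1.2, 12))
  ds <- generate_dataset(small_spec(seed = 9, timepoints_per_day = 12,
                                    diurnal_amplitudes = amps,
                                    noise_sd_metabolite = 0.25))
  mm <- preprocess_peaks(ds$peaks)
  stab <- diurnal_stability(mm$values, panel_ids = c("met001", "met020"))
  expect_lt(stab$sd_scaled[stab$metabolite_id == "met001"],
            stab$sd_scaled[stab$metabolite_id == "met020"])
})
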