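# anthemet

Predicting the anthesis (flowering) rate of greenhouse tomato from leaf
metabolome profiles.

The number of newly opened flowers per week — the anthesis rate — is an
early index of tomato fruit production. Leaf metabolite profiles are a
direct readout of the plant's internal state and can be collected without
removing fruit. `anthemet` implements the full analysis chain for building
and vetting a metabolite-based rate predictor, for plant scientists and
greenhouse phenotyping groups working with widely targeted LC-MS/MS data:

* **Preprocessing** of a raw peak table: signal-to-noise ratios against
  extraction blanks, a detection filter (S/N > 2 in more than half of the
  samples), internal-standard normalization, standardization, 0–1 scaling.
* **Phenotype rates**: anthesis rates as gradients of the cumulative
  flower-count curve (flowers·week⁻¹), pairing of rates with 2-hourly leaf
  samples, Mann-Whitney and Kruskal–Wallis/Conover group comparisons.
* **Sparse linear modeling** — the core. LASSO regression

  $$\min_{w_0,\,w}\; \tfrac{1}{2n}\lVert y - w_0 - Xw\rVert_2^2 + \alpha\lVert w\rVert_1$$

  by cyclic coordinate descent (compiled, covariance updates, warm-started
  penalty paths), a 50-point sweep of α over [5×10⁻⁵, 0.5] with 10-fold
  cross-validation, elbow-based selection of the predictor-metabolite
  panel, and re-validation of the panel on combined multi-greenhouse data
  (minimum cross-validated MSE).
* **Marker characterization**: PCA with contribution ratios, hierarchical
  clustering of correlation distances with the linkage chosen by maximum
  cophenetic correlation, correspondence-analysis association networks
  (15th-percentile Euclidean distance threshold in full CA space), and a
  diurnal-stability screen (SD of the 0–1-scaled 24-h series; day
  06:00–18:00 vs night 20:00–04:00).
* **A synthetic-data generator** with known ground truth that emulates the
  study design (192 time-series samples, 161 detected metabolites in
  correlated blocks, diurnal rhythms, batch-shifted snapshot experiments,
  a sparse metabolite-driven rate), so the whole pipeline is testable
  end to end.

## Worked example

```r
library(anthemet)

ds <- generate_dataset(synthetic_spec(seed = 1))  # ground truth known
ds
#> Synthetic dataset: 192 samples x 203 compounds; 29 support metabolites; realized R^2 = 0.893

mm <- preprocess_peaks(ds$peaks)                  # S/N filter + IS normalization
mm
#> Metabolite matrix: 192 samples x 161 metabolites [ raw_relative ]

rates <- anthesis_rates(ds$anthesis)              # flowers per week
head(rates, 3)
#>      group      start        end      rate
#> 1 TK01:CFM 2016-08-09 2016-08-16  7.948004
#> 2 TK01:CFM 2016-08-16 2016-08-23 12.396360
#> 3 TK01:CFM 2016-08-23 2016-08-30 11.522915

y <- assign_rates_to_samples(rates, ds$peaks$sample_meta)
X <- standardize_profiles(mm$values)

sweep <- alpha_sweep(X, y, seed = 1)              # 50 penalties x 10-fold CV
panel <- select_elbow(sweep)
panel
#> Selected model: alpha = 0.195347 | support = 19 | train R2 = 0.745 | CV R2 = 0.667 | CV MSE = 2.51

stab <- diurnal_stability(mm$values, panel$support_ids)
head(stab, 3)
#>   metabolite_id sd_scaled night_association day_association
#> 1        met014 0.1302359                NA              NA
#> 2        met010 0.1303688                NA              NA
#> 3        met005 0.1327563                NA              NA
```

Reading the output: the elbow rule picked the 19-metabolite panel whose
cross-validated R² (0.667) is within tolerance of the best attainable on
this dataset (the generator's own noise floor puts true predictability at
R² 0.89 for cell means; the weekly rate is constant within a cultivar-week,
which caps out-of-sample R² below that — see the methods vignette). Against
the generator's truth this panel has precision 0.95 and recall 0.62, the
expected behavior when the response varies only between cultivar-weeks.
The stability screen then ranks panel members by how flat their 0–1-scaled
24-h profile is (SD ≤ 0.5 by construction); the flattest members are the
candidates for sampling-time-robust deployment.

The full orchestrated flow — three simulated greenhouses, all three model
variants (metabolome / environment / combined), panel refit, clustering,
CA networks, diurnal screen, and a checksummed manifest — is one call:

```r
manifest <- run_pipeline(default_config(), "out", seed = 1)
manifest$metrics$variants   # Table-style accuracy comparison per variant
```

or from a shell: `Rscript inst/cli/anthemet.R run-all --out out --seed 1`.

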