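test_that("a noiseless single peak reproduces its configured height at the apex", {
  cfg <- spectrum_sim_config(n_scans = 3, mz_range = c(100, 110),
                             peak_centers = 105.003, peak_heights = 5e5,
                             peak_width_sigma = 0.02, noise_sd = 0,
                             grid_step = 0.01, seed = 1)
  sp <- simulate_spectrum(cfg)
  apex <- which.min(abs(sp$mz - 105.003))
  expect_equal(max(sp$intensity[1, ]), sp$intensity[1, apex])
  # the grid point nearest the center is within half a step of it
  expect_equal(sp$intensity[1, apex],
               5e5 * exp(-(sp$mz[apex] - 105.003)^2 / (2 * 0.02^2)))
})

test_that("a peak-free spectrum is exactly baseline plus drift", {
  cfg <- spectrum_sim_config(n_scans = 2, mz_range = c(100, 120),
                             baseline_level = 100, baseline_drift_slope = 3,
                             noise_sd = 0, seed = 1)
  sp <- simulate_spectrum(cfg)
  for (k in 1:2)
    expect_equal(sp$intensity[k, ], 100 + 3 * (sp$mz - 100))
})

test_that("spectrum simulation is reproducible and validates its config", {
  cfg <- spectrum_sim_config(n_scans = 4, mz_range = c(100, 105),
                             peak_centers = 102, peak_heights = 1e5,
                             noise_sd = 300, seed = 11)
  expect_identical(simulate_spectrum(cfg), simulate_spectrum(cfg))
  expect_error(spectrum_sim_config(peak_centers = 99, peak_heights = 1,
                                   mz_range = c(100, 105)),
               "peak_centers")
  expect_error(spectrum_sim_config(peak_centers = 102, peak_heights = -1,
                                   mz_range = c(100, 105)),
               "peak_heights")
  expect_error(spectrum_sim_config(noise_sd = -2), "noise_sd")
  expect_error(cohort_sim_config(n_peaks = 4, n_discriminant_ratio_pairs = 3),
               "n_discriminant_ratio_pairs")
})

test_that("pairwise ratios are bit-identical under per-sample scaling", {
  sim <- simulate_cohort(cohort_sim_config(n_samples_per_class = 4,
                                           n_peaks = 8, seed = 7))
  X <- sim$matrix$intensities
  set.seed(42)
  for (i in sample(nrow(X), 5)) {
    row1 <- X[i, ]
    # power-of-two factors rescale the significand exactly: bit identity
    for (c_scale in c(0.25, 2, 1024)) {
      r1 <- outer(row1, row1, "/")
      r2 <- outer(row1 * c_scale, row1 * c_scale, "/")
      expect_identical(r1, r2)
    }
    # arbitrary positive factors cancel to within one ulp
    c_any <- runif(1, 0.1, 50)
    r2 <- outer(row1 * c_any, row1 * c_any, "/")
    expect_equal(outer(row1, row1, "/"), r2, tolerance = 1e-14)
  }
})

test_that("effect size 1 plants no between-class ratio signal despite large intensity variance", {
  sim <- simulate_cohort(cohort_sim_config(
    n_samples_per_class = 200, n_replicates = 1, n_peaks = 10,
    n_discriminant_ratio_pairs = 2, ratio_effect_size = 1,
    injection_scale_sd = 1.0, intensity_noise_cv = 0.05, seed = 3))
  m <- sim$matrix; gt <- sim$ground_truth
  for (q in seq_len(nrow(gt$pairs))) {
    r <- m$intensities[, gt$pairs$numerator[q]] /
         m$intensities[, gt$pairs$denominator[q]]
    cls_means <- tapply(r, m$class_labels, mean)
    expect_lt(max(cls_means) / min(cls_means), 1.05)
  }
  # raw intensities still fluctuate strongly (injection factor sdlog = 1)
  cv_raw <- apply(m$intensities, 2, sd) / colMeans(m$intensities)
  expect_gt(min(cv_raw), 0.5)
})

test_that("empirical planted-ratio class means match the configured means at n = 200/class", {
  sim <- simulate_cohort(cohort_sim_config(
    n_samples_per_class = 200, n_replicates = 1, n_peaks = 10,
    n_discriminant_ratio_pairs = 2, ratio_effect_size = 3,
    intensity_noise_cv = 0.1, seed = 5))
  m <- sim$matrix; gt <- sim$ground_truth
  for (q in seq_len(nrow(gt$pairs))) {
    r <- m$intensities[, gt$pairs$numerator[q]] /
         m$intensities[, gt$pairs$denominator[q]]
    emp <- tapply(r, m$class_labels, mean)[gt$class_levels]
    expect_equal(as.numeric(emp), gt$class_ratio_means[, q], tolerance = 0.05)
    expect_true(all(diff(as.numeric(emp)) > 0))  # ordered as planted
  }
})

test_that("cohort simulation is reproducible for a fixed seed", {
  cfg <- cohort_sim_config(n_samples_per_class = 5, n_peaks = 12, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("planted ratios out-score non-planted ratios in a two-sample t statistic", {
  # two classes so a plain two-sample t statistic applies
  sim <- simulate_cohort(cohort_sim_config(
    n_classes = 2, n_samples_per_class = 50, n_replicates = 1, n_peaks = 12,
    n_discriminant_ratio_pairs = 2, ratio_effect_size = 2,
    intensity_noise_cv = 0.2, seed = 21))
  m <- sim$matrix; gt <- sim$ground_truth
  rs <- build_ratios(m)
  tstat <- apply(rs$ratios, 2, function(r) {
    abs(t.test(r[m$class_labels == "C1"], r[m$class_labels == "C2"])$statistic)
  })
  keys <- paste(rs$pairs$numerator, rs$pairs$denominator)
  is_planted <- keys %in% planted_keys(gt)
  for (tp in tstat[is_planted])
    expect_gte(mean(tp > tstat[!is_planted]), 0.95)
})
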