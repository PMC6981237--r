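# Shared fixtures: synthetic worlds with planted discriminant ratios,
# split into learning and validation halves, plus small oracles.

# Simulate one cohort and split it (first half of each class learns).
make_split_world <- function(seed, n_peaks = 72L, n_pairs = 2L,
                             effect = 2.5, noise_cv = 0.15,
                             coupling = 0.5, n_per_class = 20L,
                             n_replicates = 3L) {
  sim <- simulate_cohort(cohort_sim_config(
    n_samples_per_class = n_per_class, n_peaks = n_peaks,
    n_discriminant_ratio_pairs = n_pairs, ratio_effect_size = effect,
    intensity_noise_cv = noise_cv, pair_coupling_sdlog = coupling,
    n_replicates = n_replicates, seed = seed))
  avg <- average_replicates(sim$matrix)
  half <- n_per_class %/% 2L
  lr <- unlist(lapply(unique(avg$class_labels),
                      function(cl) which(avg$class_labels == cl)[seq_len(half)]))
  vr <- setdiff(seq_along(avg$class_labels), lr)
  sub <- function(rows) aligned_matrix(avg$sample_ids[rows],
                                       avg$class_labels[rows],
                                       avg$feature_mz,
                                       avg$intensities[rows, , drop = FALSE])
  learn <- sub(lr); valid <- sub(vr)
  list(learn = learn, valid = valid,
       ratios_learn = build_ratios(learn), ratios_valid = build_ratios(valid),
       ground_truth = sim$ground_truth)
}

# keys of the planted pairs in either orientation ("num den" strings)
planted_keys <- function(gt) {
  p <- gt$pairs
  c(paste(p$numerator, p$denominator), paste(p$denominator, p$numerator))
}

# does a selected set of ratio columns contain a planted pair?
contains_planted <- function(ratio_set, indices, gt) {
  sel <- paste(ratio_set$pairs$numerator[indices],
               ratio_set$pairs$denominator[indices])
  any(sel %in% planted_keys(gt))
}

# Independent Bayes-rule classifier for equal-covariance Gaussian classes:
# argmin over classes of mahalanobis(x, mu_k, S) - 2 log(prior_k).
# Deliberately coded through stats::mahalanobis, not the package's scores.
bayes_rule_predict <- function(X, y_train, X_train) {
  classes <- sort(unique(y_train))
  g <- length(classes); d <- ncol(X_train)
  mu <- lapply(classes, function(k) colMeans(X_train[y_train == k, , drop = FALSE]))
  S <- matrix(0, d, d)
  for (i in seq_along(classes)) {
    Xc <- sweep(X_train[y_train == classes[i], , drop = FALSE], 2, mu[[i]], "-")
    S <- S + crossprod(Xc)
  }
  S <- S / (nrow(X_train) - g)
  pri <- as.numeric(table(factor(y_train, levels = classes))) / length(y_train)
  crit <- sapply(seq_along(classes), function(i)
    stats::mahalanobis(X, mu[[i]], S) - 2 * log(pri[i]))
  classes[apply(as.matrix(crit), 1L, which.min)]
}

# balanced 3-class data with labels independent of X
null_world <- function(seed, n_per_class = 10L, d = 4L) {
  ratiomics:::with_seed(seed, list(
    X = matrix(rnorm(3 * n_per_class * d), ncol = d),
    y = rep(c("A", "B", "C"), each = n_per_class)))
}
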