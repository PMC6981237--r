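small_ga <- function(...) ga_config(population_size = 20, n_generations = 10,
                                    n_ga_runs = 1, seed = 3, ...)

test_that("evolution without crossover or mutation is a no-op on a uniform population", {
  w <- make_split_world(31, n_peaks = 5, n_pairs = 1)
  cfg <- ga_config(population_size = 6, n_generations = 5, n_ga_runs = 1,
                   crossover_prob = 0, mutation_prob = 0,
                   subset_size_range = c(2, 2), seed = 5)
  ga <- run_ga(w$ratios_learn, w$learn$class_labels, cfg)
  pop <- ga$runs[[1]]$population
  # only tournament copies of initial individuals can appear; with a
  # degenerate 2-member universe of moves disabled, the population is a
  # subset of the initial pool
  init <- ratiomics:::with_seed(5 + 1, {
    replicate(6, sort(sample.int(ncol(w$ratios_learn$ratios),
                                 sample.int(1L, 1L) + 1L)), simplify = FALSE)
  })
  expect_true(all(vapply(pop, paste, "", collapse = ",") %in%
                  vapply(init, paste, "", collapse = ",")))
})

test_that("a fixed seed reproduces the GA bit for bit", {
  w <- make_split_world(32, n_peaks = 6, n_pairs = 1)
  cfg <- small_ga()
  g1 <- run_ga(w$ratios_learn, w$learn$class_labels, cfg)
  g2 <- run_ga(w$ratios_learn, w$learn$class_labels, cfg)
  expect_identical(g1, g2)
})

test_that("elitism makes the best fitness monotone across generations", {
  w <- make_split_world(33, n_peaks = 8, n_pairs = 1)
  ga <- run_ga(w$ratios_learn, w$learn$class_labels,
               ga_config(population_size = 30, n_generations = 25,
                         n_ga_runs = 3, seed = 9))
  for (r in ga$runs) expect_true(all(diff(r$best_trace) >= 0))
})

test_that("subset sizes respect their bounds after every operator", {
  set.seed(14)
  rsize <- function(kmin, kmax) kmin + sample.int(kmax - kmin + 1L, 1L) - 1L
  for (i in 1:200) {
    kmin <- sample(1:3, 1); kmax <- kmin + sample(0:4, 1); n <- 40
    s1 <- sort(sample.int(n, rsize(kmin, kmax)))
    s2 <- sort(sample.int(n, rsize(kmin, kmax)))
    child <- ratiomics:::crossover_sets(s1, s2)
    expect_true(length(child) >= min(length(s1), length(s2)) &&
                length(child) <= max(length(s1), length(s2)))
    expect_true(all(child %in% union(s1, s2)))
    expect_false(any(duplicated(child)))
    mut <- ratiomics:::mutate_set(s1, n, kmin, kmax)
    expect_true(length(mut) >= kmin && length(mut) <= kmax)
    expect_false(any(duplicated(mut)))
    expect_true(all(mut >= 1 & mut <= n))
  }
  # final populations stay within bounds too
  w <- make_split_world(34, n_peaks = 8, n_pairs = 1)
  ga <- run_ga(w$ratios_learn, w$learn$class_labels,
               small_ga(subset_size_range = c(2, 4)))
  expect_true(all(lengths(ga$runs[[1]]$population) >= 2 &
                  lengths(ga$runs[[1]]$population) <= 4))
})

test_that("with one strongly planted ratio among 90, the GA finds the exhaustive best single", {
  hits <- 0L
  for (s in 1:20) {
    w <- make_split_world(400 + s, n_peaks = 10, n_pairs = 1,
                          effect = 3, coupling = 1.0)
    R <- w$ratios_learn$ratios
    y <- w$learn$class_labels
    ga <- run_ga(w$ratios_learn, y,
                 ga_config(population_size = 40, n_generations = 30,
                           n_ga_runs = 1, subset_size_range = c(1, 1),
                           seed = s))
    run <- ga$runs[[1]]
    best <- run$population[[which.max(run$fitness)]]
    # oracle: evaluate all 90 single-ratio solutions on the same folds
    folds <- ratiomics:::with_seed(s + 1 + 10000L,
      ratiomics:::make_stratified_folds(y, sort(unique(y)), 2L, 1L))
    yi <- as.integer(factor(y, levels = sort(unique(y)))) - 1L
    fit_all <- vapply(seq_len(ncol(R)), function(j)
      mean(ratiomics:::.cv_lda_kernel(R[, j, drop = FALSE], yi, folds, 3L, 2L, 1e-8)), 0)
    hits <- hits + (fit_all[best] == max(fit_all))
  }
  expect_gte(hits, 18L)   # >= 90% of runs match the enumerated optimum
})

test_that("solution ranking prefers validation accuracy, then fewer molecules", {
  # hand-built ratio feature sets: column 1 separates validation perfectly,
  # column 2 makes errors there; both are perfect on the learning set
  set.seed(21)
  yl <- rep(c("A", "B"), each = 10)
  yv <- rep(c("A", "B"), each = 10)
  sig <- function(y, flip = 0) {
    x <- ifelse(y == "A", 1, 10) * exp(rnorm(length(y), 0, 0.02))
    if (flip > 0) x[seq_len(flip)] <- 10 * x[seq_len(flip)]
    x
  }
  RL <- cbind(sig(yl), sig(yl))
  RV <- cbind(sig(yv), sig(yv, flip = 2))   # solution {2} loses 2 validation samples
  fs <- function(R, pairs) structure(list(
    pairs = pairs, ratios = R, source_feature_ids = seq_len(4),
    feature_mz = 100 + seq_len(4), log_ratios = FALSE),
    class = "ratio_feature_set")
  pairs <- data.frame(numerator = c(1, 3), denominator = c(2, 4))
  sel <- rank_and_select(list(1L, 2L), fs(RL, pairs), yl, fs(RV, pairs), yv,
                         cv_repeats = 5, seed = 2)
  expect_equal(sel$ratio_indices, 1L)
  expect_equal(sel$validation_accuracy, 1.0)

  # equal accuracies everywhere: the 2-molecule solution beats the 4-molecule one
  pairs2 <- data.frame(numerator = c(1, 1, 3), denominator = c(2, 2, 4))
  RL2 <- cbind(sig(yl), sig(yl), sig(yl))
  RV2 <- cbind(sig(yv), sig(yv), sig(yv))
  sel2 <- rank_and_select(list(c(2L, 3L), 1L), fs(RL2, pairs2), yl,
                          fs(RV2, pairs2), yv, cv_repeats = 5, seed = 2)
  expect_equal(sel2$ratio_indices, 1L)       # 2 molecules, 1 ratio
  expect_equal(sel2$n_molecules, 2L)

  # a single survivor is returned as-is
  sel3 <- rank_and_select(list(1L), fs(RL, pairs), yl, fs(RV, pairs), yv,
                          cv_repeats = 5, seed = 2)
  expect_equal(sel3$ratio_indices, 1L)
})

test_that("ranking warns and falls back to best-by-CV when nothing clears the bar", {
  w <- null_world(23, n_per_class = 6, d = 3)
  RL <- abs(w$X) + 1
  expect_warning(
    sel <- rank_and_select(list(1L, 2L), RL, w$y, RL, w$y,
                           cv_repeats = 5, seed = 2),
    "best solution by CV")
  expect_length(sel$ratio_indices, 1L)
})

test_that("solution evaluation reports training, CV and validation accuracies coherently", {
  w <- make_split_world(35, n_peaks = 6, n_pairs = 1, effect = 3,
                        coupling = 1.0)
  gt_col <- which(paste(w$ratios_learn$pairs$numerator,
                        w$ratios_learn$pairs$denominator) %in%
                  planted_keys(w$ground_truth))[1]
  ev <- evaluate_solution(gt_col, w$ratios_learn, w$learn$class_labels,
                          w$ratios_valid, w$valid$class_labels,
                          cv_repeats = 10, seed = 4)
  expect_gte(ev[["learning_accuracy"]], 0.95)
  expect_gte(ev[["cv_accuracy"]], 0.9)
  expect_gte(ev[["validation_accuracy"]], 0.9)
  expect_identical(ev, evaluate_solution(gt_col, w$ratios_learn,
                                         w$learn$class_labels, w$ratios_valid,
                                         w$valid$class_labels,
                                         cv_repeats = 10, seed = 4))
})

test_that("on label-free data the overfit gap appears: training beats CV and validation", {
  gaps <- t(vapply(1:50, function(s) {
    w <- null_world(600 + s, n_per_class = 10, d = 4)
    split <- rep(c(TRUE, FALSE), length.out = nrow(w$X))
    ev <- evaluate_solution(1:4, abs(w$X[split, ]) + 0.5, w$y[split],
                            abs(w$X[!split, ]) + 0.5, w$y[!split],
                            cv_repeats = 2, seed = s)
    c(train = ev[["learning_accuracy"]], cv = ev[["cv_accuracy"]],
      valid = ev[["validation_accuracy"]])
  }, numeric(3)))
  expect_lt(abs(mean(gaps[, "cv"]) - 1 / 3), 0.08)
  expect_lt(abs(mean(gaps[, "valid"]) - 1 / 3), 0.08)
  expect_gt(mean(gaps[, "train"]), mean(gaps[, "valid"]) + 0.1)
})
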