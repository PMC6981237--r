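pt_of <- function(id, rep, mz, h = rep(100, length(mz)))
  peak_table(id, rep, mz, h)

test_that("identical m/z lists align to a fully populated matrix", {
  mzs <- c(100.1, 150.2, 200.3)
  tabs <- list(pt_of("a", "1", mzs, c(1, 2, 3)),
               pt_of("b", "1", mzs, c(4, 5, 6)))
  mat <- align_peaks(tabs, cutoff = 0.001)
  expect_equal(ncol(mat$intensities), 3L)
  expect_equal(mat$feature_mz, mzs)
  expect_true(all(mat$intensities > 0))
  expect_equal(mat$intensities[2, ], c(4, 5, 6), ignore_attr = TRUE)
})

test_that("two close peaks merge below the cutoff and stay apart above it", {
  near <- list(pt_of("a", "1", 100.000), pt_of("b", "1", 100.001))
  expect_equal(ncol(align_peaks(near, cutoff = 0.005)$intensities), 1L)
  far <- list(pt_of("a", "1", 100.000), pt_of("b", "1", 100.100))
  expect_equal(ncol(align_peaks(far, cutoff = 0.005)$intensities), 2L)
})

test_that("gap-partitioned clustering is exact complete linkage", {
  set.seed(12)
  mz <- sort(c(runif(60, 100, 101), runif(60, 101.5, 103)))
  for (h in c(0.01, 0.05, 0.2)) {
    fast <- ratiomics:::cluster_mz(mz, h)
    full <- cutree(hclust(dist(mz), method = "complete"), h = h)
    # same partition up to label names
    expect_equal(length(unique(fast)), length(unique(full)))
    expect_true(all(tapply(full, fast, function(v) length(unique(v))) == 1))
    # complete-linkage guarantee: within-cluster spread bounded by cutoff
    expect_lte(max(tapply(mz, fast, function(v) diff(range(v)))), h)
  }
})

test_that("feature count is monotone non-increasing in the cutoff", {
  set.seed(3)
  tabs <- lapply(1:4, function(i) pt_of(paste0("s", i), "1",
                                        sort(runif(30, 100, 110))))
  pool <- ratiomics:::pool_peaks(tabs)
  counts <- vapply(c(1e-6, 0.01, 0.1, 1, 20),
                   function(h) length(unique(ratiomics:::cluster_mz(pool$mz, h))), 0L)
  expect_equal(counts[1], length(unique(pool$mz)))
  expect_equal(counts[length(counts)], 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the chosen cutoff minimizes same-spectrum co-clustering with ties toward larger cutoffs", {
  # well-separated peaks 0.5 Th apart within each spectrum
  tabs <- list(pt_of("a", "1", seq(100, 102, by = 0.5)),
               pt_of("b", "1", seq(100.001, 102.001, by = 0.5)))
  expect_equal(as.numeric(choose_cutoff(tabs, c(0.001, 1.0))), 0.001)

  # a single spectrum can never co-cluster against itself at tiny cutoffs;
  # ties resolve to the largest candidate with zero co-clustering
  single <- list(pt_of("a", "1", c(100, 100.5, 101)))
  expect_equal(as.numeric(choose_cutoff(single, c(0.001, 0.01, 0.1))), 0.1)

  # jittered replicates around 1.0-spaced centers: the objective rules out
  # a cutoff that merges neighbouring centers
  set.seed(5)
  centers <- seq(100, 109)
  tabs <- lapply(1:3, function(i)
    pt_of(paste0("s", i), "1", sort(centers + rnorm(10, sd = 0.002))))
  sel <- as.numeric(choose_cutoff(tabs, c(0.01, 0.1, 2.0)))
  expect_true(sel %in% c(0.01, 0.1))
})

test_that("replicate averaging is the column-wise mean within samples", {
  m <- aligned_matrix(rep(c("s1", "s2"), each = 3), rep(c("A", "B"), each = 3),
                      c(100, 200), matrix(c(0, 0, 3, 1, 1, 1,
                                            2, 4, 6, 5, 5, 5), ncol = 2),
                      replicate_ids = rep(c("1", "2", "3"), 2))
  avg <- average_replicates(m)
  expect_equal(avg$sample_ids, c("s1", "s2"))
  expect_equal(avg$intensities[, 1], c(1, 1), ignore_attr = TRUE)
  expect_equal(avg$intensities[, 2], c(4, 5), ignore_attr = TRUE)

  set.seed(8)
  X <- matrix(rlnorm(18), nrow = 6)
  m2 <- aligned_matrix(rep(c("u", "v"), each = 3), rep("A", 6),
                       c(1, 2, 3), X, replicate_ids = rep(c("1","2","3"), 2))
  avg2 <- average_replicates(m2)
  expect_equal(avg2$intensities[1, ], colMeans(X[1:3, ]), ignore_attr = TRUE)
  expect_equal(avg2$intensities[2, ], colMeans(X[4:6, ]), ignore_attr = TRUE)
  # identical triplicates pass through unchanged
  m3 <- aligned_matrix(rep("w", 3), rep("A", 3), c(1, 2),
                       matrix(rep(c(7, 9), each = 3), ncol = 2),
                       replicate_ids = c("1", "2", "3"))
  expect_equal(average_replicates(m3)$intensities[1, ], c(7, 9),
               ignore_attr = TRUE)
  expect_error(average_replicates(m, replicate_map = c("s1", NA, "s1", "s2", "s2", "s2")),
               "unmapped")
})

test_that("permuting input tables changes only row order", {
  set.seed(6)
  tabs <- lapply(1:4, function(i)
    pt_of(paste0("s", i), "1", sort(runif(15, 100, 105)), runif(15, 1e4, 1e6)))
  m1 <- align_peaks(tabs, cutoff = 0.01)
  m2 <- align_peaks(tabs[c(3, 1, 4, 2)], cutoff = 0.01)
  expect_equal(m1$feature_mz, m2$feature_mz)
  o <- match(m1$sample_ids, m2$sample_ids)
  expect_equal(m2$intensities[o, ], m1$intensities, ignore_attr = TRUE)
})
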