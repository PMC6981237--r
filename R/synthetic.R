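#' Configuration for simulating a raw multi-scan spectrum
#'
#' Describes one synthetic injection: Gaussian ion peaks on a linear
#' baseline with i.i.d. Gaussian noise, acquired over `n_scans` scans that
#' share one m/z grid. This emulates the profile-mode sum spectra a TOF
#' instrument produces over the elution window of interest.
#'
#' @param n_scans number of scans.
#' @param mz_range numeric length-2, grid limits in Th (low, high).
#' @param peak_centers m/z positions of the Gaussian peaks (Th), all within
#'   `mz_range`.
#' @param peak_heights peak amplitudes (arbitrary intensity units), same
#'   length as `peak_centers`, all >= 0.
#' @param peak_width_sigma Gaussian sigma in Th.
#' @param baseline_level constant baseline intensity.
#' @param baseline_drift_slope baseline slope, intensity per Th (applied to
#'   m/z minus the low end of the range).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param grid_step m/z grid spacing in Th.
#' @param seed integer seed; the same config always yields the same spectrum.
#' @return an object of class `spectrum_sim_config`.
#' @export
spectrum_sim_config <- function(n_scans = 10L,
                                mz_range = c(100, 1000),
                                peak_centers = numeric(),
                                peak_heights = numeric(),
                                peak_width_sigma = 0.02,
                                baseline_level = 0,
                                baseline_drift_slope = 0,
                                noise_sd = 0,
                                grid_step = 0.01,
                                seed = 1L) {
  n_scans <- check_count(n_scans, "n_scans")
  if (length(mz_range) != 2L || !is.numeric(mz_range) || mz_range[1] >= mz_range[2])
    stop_cfg("mz_range", "must be (low, high) with low < high")
  if (length(peak_centers) != length(peak_heights))
    stop_cfg("peak_centers", "must have the same length as peak_heights")
  if (length(peak_centers) &&
      (any(peak_centers <= mz_range[1]) || any(peak_centers >= mz_range[2])))
    stop_cfg("peak_centers", "must lie strictly within mz_range")
  if (length(peak_heights) && any(peak_heights < 0))
    stop_cfg("peak_heights", "must be >= 0")
  peak_width_sigma <- check_number(peak_width_sigma, "peak_width_sigma", min = 1e-12)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  baseline_level <- check_number(baseline_level, "baseline_level")
  baseline_drift_slope <- check_number(baseline_drift_slope, "baseline_drift_slope")
  grid_step <- check_number(grid_step, "grid_step", min = 1e-9)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    n_scans = n_scans, mz_range = as.numeric(mz_range),
    peak_centers = as.numeric(peak_centers),
    peak_heights = as.numeric(peak_heights),
    peak_width_sigma = peak_width_sigma,
    baseline_level = baseline_level,
    baseline_drift_slope = baseline_drift_slope,
    noise_sd = noise_sd, grid_step = grid_step, seed = seed
  ), class = "spectrum_sim_config")
}

#' Raw multi-scan spectrum container
#'
#' @param sample_id,replicate_id identifying tokens.
#' @param mz strictly increasing shared m/z grid (Th).
#' @param intensity matrix of non-negative intensities, one row per scan,
#'   columns matching `mz`.
#' @return an object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(sample_id, replicate_id, mz, intensity) {
  mz <- as.numeric(mz)
  intensity <- as.matrix(intensity)
  if (any(diff(mz) <= 0)) stop("m/z grid must be strictly increasing")
  if (ncol(intensity) != length(mz))
    stop("intensity columns must match the m/z grid")
  if (nrow(intensity) < 1L) stop("a raw spectrum needs at least one scan")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(sample_id = as.character(sample_id),
                 replicate_id = as.character(replicate_id),
                 mz = mz, intensity = intensity),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("raw_spectrum '%s' (replicate %s): %d scans x %d grid points, m/z %.4f-%.4f\n",
              x$sample_id, x$replicate_id, nrow(x$intensity), length(x$mz),
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' Simulate a raw multi-scan spectrum
#'
#' Each scan is the sum of Gaussian peaks (amplitude = configured height),
#' a linear baseline `baseline_level + drift_slope * (mz - low)`, and
#' i.i.d. Gaussian noise; negative values are clipped to zero.
#'
#' @param cfg a [spectrum_sim_config()].
#' @param sample_id,replicate_id tokens stored in the result.
#' @return a [raw_spectrum()].
#' @export
simulate_spectrum <- function(cfg, sample_id = "sim", replicate_id = "1") {
  if (!inherits(cfg, "spectrum_sim_config"))
    stop_cfg("cfg", "must be a spectrum_sim_config")
  mz <- seq(cfg$mz_range[1], cfg$mz_range[2], by = cfg$grid_step)
  signal <- numeric(length(mz))
  for (k in seq_along(cfg$peak_centers)) {
    signal <- signal + cfg$peak_heights[k] *
      exp(-(mz - cfg$peak_centers[k])^2 / (2 * cfg$peak_width_sigma^2))
  }
  baseline <- cfg$baseline_level + cfg$baseline_drift_slope * (mz - cfg$mz_range[1])
  clean <- signal + baseline
  inten <- with_seed(cfg$seed, {
    m <- matrix(rnorm(cfg$n_scans * length(mz), sd = cfg$noise_sd),
                nrow = cfg$n_scans)
    sweep(m, 2L, clean, "+")
  })
  inten[inten < 0] <- 0
  raw_spectrum(sample_id, replicate_id, mz, inten)
}

#' Configuration for simulating a class-structured intensity cohort
#'
#' Generates an aligned samples-by-peaks intensity matrix for `n_classes`
#' groups whose classes differ only in a few planted peak-intensity
#' *ratios*, while absolute intensities fluctuate per injection — the
#' regime in which ratio features outperform raw intensities.
#'
#' The generative model per injection r of biological sample s (class c):
#' \deqn{I_{rp} = \mu_p \; e^{c}(p) \; f_r \; g_{rq(p)} \; \epsilon_{rp}}
#' where \eqn{\mu_p} is the cohort-level base intensity of peak p,
#' \eqn{e^{c}(p)} = `ratio_effect_size`^(c-1) if p is the numerator of a
#' planted pair (1 otherwise), \eqn{f_r} is a per-injection log-normal
#' scale factor (sdlog = `injection_scale_sd`), \eqn{g_{rq}} a log-normal
#' fluctuation (sdlog = `pair_coupling_sdlog`) shared by the two peaks of
#' planted pair q — so their ratio cancels it while either peak alone does
#' not — and \eqn{\epsilon_{rp}} mean-one multiplicative log-normal noise
#' with coefficient of variation `intensity_noise_cv`.
#'
#' @param n_classes number of classes (default 3).
#' @param n_samples_per_class biological samples per class.
#' @param n_replicates technical replicates (injections) per sample.
#' @param n_peaks number of aligned peaks (columns).
#' @param n_discriminant_ratio_pairs number of planted ratio pairs; uses
#'   `2 * n_discriminant_ratio_pairs` distinct peaks.
#' @param ratio_effect_size multiplicative between-class step applied to
#'   each planted numerator peak (1 = no signal).
#' @param injection_scale_sd sdlog of the per-injection global factor.
#' @param intensity_noise_cv per-peak multiplicative noise CV.
#' @param pair_coupling_sdlog sdlog of the fluctuation shared within each
#'   planted pair; > 0 makes the planted pair itself (not just its
#'   numerator peak) the statistically optimal ratio.
#' @param seed integer seed.
#' @return an object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_classes = 3L,
                              n_samples_per_class = 10L,
                              n_replicates = 3L,
                              n_peaks = 72L,
                              n_discriminant_ratio_pairs = 2L,
                              ratio_effect_size = 2,
                              injection_scale_sd = 0.5,
                              intensity_noise_cv = 0.15,
                              pair_coupling_sdlog = 0.5,
                              seed = 1L) {
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  n_samples_per_class <- check_count(n_samples_per_class, "n_samples_per_class")
  n_replicates <- check_count(n_replicates, "n_replicates")
  n_peaks <- check_count(n_peaks, "n_peaks", min = 2L)
  n_discriminant_ratio_pairs <-
    check_count(n_discriminant_ratio_pairs, "n_discriminant_ratio_pairs", min = 0L)
  if (2L * n_discriminant_ratio_pairs > n_peaks)
    stop_cfg("n_discriminant_ratio_pairs", "needs 2 distinct peaks per pair (2*pairs <= n_peaks)")
  ratio_effect_size <- check_number(ratio_effect_size, "ratio_effect_size", min = 1e-9)
  injection_scale_sd <- check_number(injection_scale_sd, "injection_scale_sd", min = 0)
  intensity_noise_cv <- check_number(intensity_noise_cv, "intensity_noise_cv", min = 0)
  pair_coupling_sdlog <- check_number(pair_coupling_sdlog, "pair_coupling_sdlog", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    n_classes = n_classes, n_samples_per_class = n_samples_per_class,
    n_replicates = n_replicates, n_peaks = n_peaks,
    n_discriminant_ratio_pairs = n_discriminant_ratio_pairs,
    ratio_effect_size = ratio_effect_size,
    injection_scale_sd = injection_scale_sd,
    intensity_noise_cv = intensity_noise_cv,
    pair_coupling_sdlog = pair_coupling_sdlog, seed = seed
  ), class = "cohort_sim_config")
}

#' Aligned samples-by-features intensity matrix
#'
#' @param sample_ids character, one per row.
#' @param class_labels character, one per row.
#' @param feature_mz strictly increasing consensus m/z per column.
#' @param intensities numeric matrix, rows = samples, cols = features;
#'   0 marks a missing peak (pre-imputation).
#' @param replicate_ids optional character, one per row; `NULL` after
#'   replicate averaging.
#' @return an object of class `aligned_matrix`.
#' @export
aligned_matrix <- function(sample_ids, class_labels, feature_mz, intensities,
                           replicate_ids = NULL) {
  intensities <- as.matrix(intensities)
  if (length(sample_ids) != nrow(intensities))
    stop("one sample id per row required")
  if (length(class_labels) != nrow(intensities))
    stop("one class label per row required")
  if (length(feature_mz) != ncol(intensities))
    stop("one consensus m/z per column required")
  if (is.unsorted(feature_mz, strictly = TRUE))
    stop("feature_mz must be strictly increasing")
  if (!is.null(replicate_ids) && length(replicate_ids) != nrow(intensities))
    stop("one replicate id per row required")
  dimnames(intensities) <- list(NULL, sprintf("mz%.4f", feature_mz))
  structure(list(sample_ids = as.character(sample_ids),
                 class_labels = as.character(class_labels),
                 feature_mz = as.numeric(feature_mz),
                 intensities = intensities,
                 replicate_ids = if (is.null(replicate_ids)) NULL else as.character(replicate_ids)),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("aligned_matrix: %d rows (%s) x %d features, classes: %s\n",
              nrow(x$intensities),
              if (is.null(x$replicate_ids)) "samples" else "injections",
              ncol(x$intensities),
              paste(unique(x$class_labels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.aligned_matrix <- function(x) dim(x$intensities)

#' Simulate a class-structured cohort with planted discriminant ratios
#'
#' @param cfg a [cohort_sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{matrix}{an [aligned_matrix()] with one row per injection
#'       (replicate); average with [average_replicates()].}
#'     \item{ground_truth}{list: `pairs` — data.frame of planted
#'       (numerator, denominator) column indices; `class_ratio_means` —
#'       classes x pairs matrix of expected ratio means (includes the
#'       exact log-normal noise bias `1 + cv^2`); `class_levels`.}
#'   }
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_sim_config"))
    stop_cfg("cfg", "must be a cohort_sim_config")
  with_seed(cfg$seed, {
    p <- cfg$n_peaks
    n_bio <- cfg$n_classes * cfg$n_samples_per_class
    n_rows <- n_bio * cfg$n_replicates
    classes <- paste0("C", seq_len(cfg$n_classes))

    feature_mz <- sort(runif(p, 150, 1000))
    base_mu <- 10^runif(p, 4.5, 6)

    # planted pairs occupy distinct peaks, chosen at random
    n_pairs <- cfg$n_discriminant_ratio_pairs
    pair_peaks <- sample.int(p, 2L * n_pairs)
    pairs <- if (n_pairs > 0L)
      data.frame(numerator = pair_peaks[seq_len(n_pairs)],
                 denominator = pair_peaks[n_pairs + seq_len(n_pairs)])
    else data.frame(numerator = integer(), denominator = integer())

    sample_ids <- rep(sprintf("s%03d", seq_len(n_bio)), each = cfg$n_replicates)
    class_idx <- rep(rep(seq_len(cfg$n_classes), each = cfg$n_samples_per_class),
                     each = cfg$n_replicates)
    replicate_ids <- rep(as.character(seq_len(cfg$n_replicates)), times = n_bio)

    # class effect enters through the planted numerator peaks only
    effect <- matrix(1, nrow = cfg$n_classes, ncol = p)
    if (n_pairs > 0L)
      for (q in seq_len(n_pairs))
        effect[, pairs$numerator[q]] <- cfg$ratio_effect_size^(seq_len(cfg$n_classes) - 1L)

    sdlog_noise <- sqrt(log1p(cfg$intensity_noise_cv^2))
    inj <- rlnorm(n_rows, 0, cfg$injection_scale_sd)
    noise <- matrix(rlnorm(n_rows * p, -sdlog_noise^2 / 2, sdlog_noise),
                    nrow = n_rows)
    X <- sweep(noise, 2L, base_mu, "*") * effect[class_idx, , drop = FALSE] * inj
    if (n_pairs > 0L && cfg$pair_coupling_sdlog > 0) {
      for (q in seq_len(n_pairs)) {
        g <- rlnorm(n_rows, 0, cfg$pair_coupling_sdlog)
        X[, pairs$numerator[q]] <- X[, pairs$numerator[q]] * g
        X[, pairs$denominator[q]] <- X[, pairs$denominator[q]] * g
      }
    }

    # expected ratio mean: mu_i/mu_j * effect^(c-1) * E[eps_i/eps_j]
    ratio_bias <- exp(sdlog_noise^2)
    crm <- matrix(NA_real_, nrow = cfg$n_classes, ncol = n_pairs)
    if (n_pairs > 0L)
      for (q in seq_len(n_pairs))
        crm[, q] <- base_mu[pairs$numerator[q]] / base_mu[pairs$denominator[q]] *
          cfg$ratio_effect_size^(seq_len(cfg$n_classes) - 1L) * ratio_bias

    list(
      matrix = aligned_matrix(sample_ids, classes[class_idx], feature_mz, X,
                              replicate_ids = replicate_ids),
      ground_truth = list(pairs = pairs, class_ratio_means = crm,
                          class_levels = classes)
    )
  })
}
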