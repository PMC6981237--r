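# Preprocessing: one injection's multi-scan spectrum -> validated peak table.
# Scan-window summation concentrates the ions eluting in the window of
# interest; local-regression baseline subtraction removes chemical noise;
# detection validates local maxima against an absolute threshold, a
# signal-to-noise rule and a robust-spread rule.

#' Peak-detection parameters
#'
#' Defaults follow the conventional settings for TOF fingerprint spectra:
#' smoothing/search window `span = 5` grid points, local-noise span
#' `sm_span = 1`, absolute intensity floor `zerothrsh = 20000`,
#' signal-to-noise factor `son = 1.5`, robust-spread factor
#' `mad_mult = 1.64`, baseline window `baseline_bandwidth = 0.1` of the m/z
#' range, and scan window 240:295. `area_w` (half-width, as a fraction, for
#' peak-area integration) is accepted and stored but inert: no downstream
#' step uses peak areas.
#'
#' @param span odd integer >= 3, smoothing / local-maximum window size.
#' @param sm_span number of neighbours on each side of a candidate excluded
#'   from the local-noise estimate.
#' @param zerothrsh absolute minimum peak height.
#' @param area_w stored for interface fidelity; unused.
#' @param son required ratio of peak height to local noise.
#' @param mad_mult required ratio of peak height to the MAD of the smoothed
#'   signal in the window.
#' @param baseline_bandwidth local-regression window as a fraction of the
#'   m/z range.
#' @param scan_window integer (first, last) scan indices to sum.
#' @return an object of class `peak_params`.
#' @export
peak_params <- function(span = 5L, sm_span = 1L, zerothrsh = 20000,
                        area_w = 0.05, son = 1.5, mad_mult = 1.64,
                        baseline_bandwidth = 0.1,
                        scan_window = c(240L, 295L)) {
  span <- check_count(span, "span", min = 3L)
  if (span %% 2L == 0L) stop_cfg("span", "must be odd")
  sm_span <- check_count(sm_span, "sm_span", min = 0L)
  zerothrsh <- check_number(zerothrsh, "zerothrsh", min = 0)
  son <- check_number(son, "son", min = 1e-12)
  mad_mult <- check_number(mad_mult, "mad_mult", min = 0)
  baseline_bandwidth <- check_number(baseline_bandwidth, "baseline_bandwidth",
                                     min = 1e-9, max = 1)
  area_w <- check_number(area_w, "area_w", min = 0)
  if (length(scan_window) != 2L || scan_window[1] > scan_window[2])
    stop_cfg("scan_window", "must be (first, last) with first <= last")
  structure(list(span = span, sm_span = sm_span, zerothrsh = zerothrsh,
                 area_w = area_w, son = son, mad_mult = mad_mult,
                 baseline_bandwidth = baseline_bandwidth,
                 scan_window = as.integer(scan_window)),
            class = "peak_params")
}

#' Detected peaks for one injection
#'
#' @param sample_id,replicate_id identifying tokens.
#' @param mz apex m/z values (Th), sorted, unique.
#' @param height peak heights (> 0).
#' @return an object of class `peak_table`.
#' @export
peak_table <- function(sample_id, replicate_id, mz, height) {
  o <- order(mz)
  mz <- as.numeric(mz)[o]; height <- as.numeric(height)[o]
  if (length(mz) && any(diff(mz) == 0)) stop("duplicate peak m/z")
  if (any(height <= 0)) stop("peak heights must be > 0")
  structure(list(sample_id = as.character(sample_id),
                 replicate_id = as.character(replicate_id),
                 peaks = data.frame(mz = mz, height = height)),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table '%s' (replicate %s): %d peaks\n",
              x$sample_id, x$replicate_id, nrow(x$peaks)))
  invisible(x)
}

#' Sum scans over an inclusive window
#'
#' @param spec a [raw_spectrum()].
#' @param window integer (first, last) scan indices, inclusive; clipped
#'   windows are an error.
#' @return list with `mz` (the shared grid) and `intensity` (elementwise
#'   sum over the window).
#' @export
sum_scan_window <- function(spec, window = c(240L, 295L)) {
  stopifnot(inherits(spec, "raw_spectrum"))
  n <- nrow(spec$intensity)
  if (length(window) != 2L || window[1] < 1L || window[2] > n || window[1] > window[2])
    stop(sprintf("scan window (%s, %s) out of range 1..%d", window[1], window[2], n))
  rows <- seq.int(window[1], window[2])
  list(mz = spec$mz, intensity = colSums(spec$intensity[rows, , drop = FALSE]))
}

#' Subtract a local-regression baseline
#'
#' The baseline is estimated by robust locally weighted regression
#' ([stats::lowess()]) with a smoother window spanning `bandwidth` of the
#' m/z range, then subtracted; negative residuals are floored at 0. Robust
#' reweighting keeps narrow peaks from inflating the baseline.
#'
#' @param mz m/z grid.
#' @param intensity intensities, same length as `mz` (>= 10 points).
#' @param bandwidth window width as a fraction of the m/z range.
#' @return baseline-subtracted intensity vector (>= 0).
#' @export
subtract_baseline <- function(mz, intensity, bandwidth = 0.1) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) < 10L) stop("need at least 10 points to estimate a baseline")
  bandwidth <- check_number(bandwidth, "bandwidth", min = 1e-9, max = 1)
  base <- lowess(mz, intensity, f = bandwidth, iter = 4L)$y
  pmax(intensity - base, 0)
}

# moving average over the `span` nearest neighbours (centred window,
# truncated at the edges)
smooth_ma <- function(x, span) {
  half <- span %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect validated peaks in a baseline-subtracted spectrum
#'
#' The spectrum is smoothed by a moving average over the `span` nearest
#' neighbours. Local maxima of the smoothed signal within each span window
#' become candidates (ties between adjacent equal maxima keep the lowest
#' m/z). A candidate of smoothed height h at grid point i is validated iff
#' all of:
#' \itemize{
#'   \item h >= `zerothrsh`;
#'   \item h >= `son` x local noise, the noise being the MAD of
#'     (raw - smoothed) over the window's other points, i.e. excluding the
#'     candidate and its `sm_span` neighbours on each side;
#'   \item h > `mad_mult` x MAD of the smoothed signal in the window.
#' }
#'
#' @param mz m/z grid (baseline-subtracted input expected).
#' @param intensity intensity vector, same length.
#' @param params a [peak_params()].
#' @param sample_id,replicate_id tokens for the returned table.
#' @return a [peak_table()]; apex m/z values are grid points and heights
#'   are the smoothed signal at the apex.
#' @export
detect_peaks <- function(mz, intensity, params = peak_params(),
                         sample_id = "", replicate_id = "") {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  n <- length(mz)
  empty <- peak_table(sample_id, replicate_id, numeric(), numeric())
  if (n == 0L) return(empty)
  span <- max(params$span, 3L)
  half <- span %/% 2L
  sm <- smooth_ma(intensity, span)
  resid <- intensity - sm

  keep_mz <- numeric(); keep_h <- numeric()
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- lo:hi
    h <- sm[i]
    if (h < params$zerothrsh) next
    if (h < max(sm[w])) next                    # not the window maximum
    if (any(sm[w] == h & w < i)) next           # tie: keep lowest m/z
    excl <- abs(w - i) <= params$sm_span
    noise_pts <- resid[w[!excl]]
    local_noise <- if (length(noise_pts)) mad(noise_pts, center = 0) else 0
    if (h < params$son * local_noise) next
    if (h <= params$mad_mult * mad(sm[w])) next
    keep_mz <- c(keep_mz, mz[i]); keep_h <- c(keep_h, h)
  }
  if (!length(keep_mz)) return(empty)
  peak_table(sample_id, replicate_id, keep_mz, keep_h)
}

#' Preprocess one injection: sum, baseline-subtract, detect
#'
#' @param spec a [raw_spectrum()].
#' @param params a [peak_params()]; its `scan_window` is clipped to the
#'   scans actually present.
#' @return a [peak_table()].
#' @export
preprocess_spectrum <- function(spec, params = peak_params()) {
  stopifnot(inherits(spec, "raw_spectrum"))
  n <- nrow(spec$intensity)
  win <- c(max(1L, min(params$scan_window[1], n)), min(params$scan_window[2], n))
  summed <- sum_scan_window(spec, win)
  corrected <- subtract_baseline(summed$mz, summed$intensity,
                                 params$baseline_bandwidth)
  detect_peaks(summed$mz, corrected, params,
               sample_id = spec$sample_id, replicate_id = spec$replicate_id)
}
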