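# Ordered ion-intensity ratio features and the exact combinatorics of the
# ratio-subset search space. Ratios are invariant to any per-injection
# global intensity factor, which is the whole point of using them.

#' Build all ordered intensity ratios over a feature subset
#'
#' For every ordered pair (i, j), i != j, of the selected features, the
#' ratio matrix column (i, j) holds `intensity[, i] / intensity[, j]`.
#' Zeros are imputed beforehand with half the smallest positive value of
#' their column so every ratio is finite and positive.
#'
#' @param matrix an [aligned_matrix()].
#' @param feature_subset integer column indices (>= 2 of them); default all.
#' @param log_ratios if `TRUE`, natural-log-transform the ratio matrix.
#'   Off by default: downstream counts and models operate on raw ratios.
#' @return an object of class `ratio_feature_set`: list with `pairs`
#'   (data.frame numerator/denominator, original column indices), `ratios`
#'   (samples x pairs matrix, columns named "mzA/mzB"),
#'   `source_feature_ids`, `feature_mz`, `log_ratios`.
#' @export
build_ratios <- function(matrix, feature_subset = NULL, log_ratios = FALSE) {
  stopifnot(inherits(matrix, "aligned_matrix"))
  sub <- feature_subset %||% seq_len(ncol(matrix$intensities))
  sub <- as.integer(sub)
  if (length(sub) < 2L) stop("need at least 2 features to form ratios")
  if (any(sub < 1L | sub > ncol(matrix$intensities))) stop("feature subset out of range")
  X <- matrix$intensities[, sub, drop = FALSE]
  X <- impute_zeros(X)
  p <- ncol(X)
  num <- rep(seq_len(p), each = p - 1L)
  den <- unlist(lapply(seq_len(p), function(i) seq_len(p)[-i]))
  R <- X[, num, drop = FALSE] / X[, den, drop = FALSE]
  mz <- matrix$feature_mz[sub]
  colnames(R) <- sprintf("%.4f/%.4f", mz[num], mz[den])
  structure(list(
    pairs = data.frame(numerator = sub[num], denominator = sub[den]),
    ratios = R,
    source_feature_ids = sub,
    feature_mz = matrix$feature_mz[sub],
    log_ratios = isTRUE(log_ratios)
  ), class = "ratio_feature_set")
}

#' @export
print.ratio_feature_set <- function(x, ...) {
  cat(sprintf("ratio_feature_set: %d samples x %d ordered ratios over %d features%s\n",
              nrow(x$ratios), ncol(x$ratios), length(x$source_feature_ids),
              if (x$log_ratios) " (log scale)" else ""))
  invisible(x)
}

# half-minimum imputation of zero / missing intensities, columnwise
impute_zeros <- function(X) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j]) | X[, j] <= 0
    if (any(bad)) {
      pos <- X[!bad, j]
      fill <- if (length(pos)) min(pos) / 2 else 1
      X[bad, j] <- fill
    }
  }
  X
}

#' Number of ordered intensity ratios over p peaks
#'
#' @param p number of peaks (>= 2).
#' @return `p * (p - 1)` as an exact integer-valued double.
#' @export
count_ordered_ratios <- function(p) {
  p <- check_count(p, "p", min = 2L)
  as.numeric(p) * (p - 1)
}

#' Number of ratio subsets of bounded size, exactly
#'
#' Computes \eqn{\sum_{k=kmin}^{kmax} \binom{n}{k}} in exact
#' arbitrary-precision integer arithmetic — the search-space size a
#' wrapper selector over ratio subsets faces.
#'
#' @param n_ratios number of candidate ratios.
#' @param kmin,kmax subset size bounds, `1 <= kmin <= kmax <= n_ratios`.
#' @return an exact big integer of class `ratiomics_bigint`; use
#'   `as.character()` for all digits or `as.numeric()` for a double
#'   approximation.
#' @export
count_subsets <- function(n_ratios, kmin = 1L, kmax = 10L) {
  n_ratios <- check_count(n_ratios, "n_ratios")
  kmin <- check_count(kmin, "kmin")
  kmax <- check_count(kmax, "kmax")
  if (!(kmin <= kmax && kmax <= n_ratios))
    stop("need 1 <= kmin <= kmax <= n_ratios")
  total <- 0
  term <- big_from_int(1)                     # C(n, 0)
  for (k in seq_len(kmax)) {
    term <- big_div_small(big_mul_small(term, n_ratios - k + 1L), k)
    if (k >= kmin) total <- big_add(total, term)
  }
  structure(total, class = "ratiomics_bigint")
}
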