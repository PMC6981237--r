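# Alignment: pool detected peaks over all injections and merge them into
# consensus features by complete-linkage hierarchical clustering on m/z.
# Complete linkage bounds the m/z spread of every feature by the cut
# height. The cutoff is chosen to minimize co-clustering of distinct ions
# from the same spectrum.

# Pool peaks from a list of peak tables into one data.frame
pool_peaks <- function(tables) {
  if (!length(tables)) stop("no peak tables supplied")
  lapply(tables, function(t) stopifnot(inherits(t, "peak_table")))
  df <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    if (!nrow(t$peaks)) return(NULL)
    data.frame(spectrum = i, sample_id = t$sample_id,
               replicate_id = t$replicate_id,
               mz = t$peaks$mz, height = t$peaks$height)
  }))
  if (is.null(df) || !nrow(df)) stop("all peak tables are empty")
  df[order(df$mz), , drop = FALSE]
}

# Complete-linkage cluster assignment of sorted m/z values, cut at `cutoff`.
# For tractability the sorted pool is first split where consecutive gaps
# exceed `max_gap` (>= cutoff): complete linkage can never merge across such
# a gap at height <= cutoff, so clustering each segment separately is exact.
cluster_mz <- function(mz_sorted, cutoff, max_gap = cutoff) {
  n <- length(mz_sorted)
  if (n == 1L) return(1L)
  stopifnot(max_gap >= cutoff)
  seg <- cumsum(c(1L, as.integer(diff(mz_sorted) > max_gap)))
  cl <- integer(n)
  nxt <- 0L
  for (s in unique(seg)) {
    idx <- which(seg == s)
    if (length(idx) == 1L) {
      cl[idx] <- nxt + 1L
      nxt <- nxt + 1L
    } else {
      hc <- hclust(dist(mz_sorted[idx]), method = "complete")
      k <- cutree(hc, h = cutoff)
      cl[idx] <- nxt + k
      nxt <- nxt + max(k)
    }
  }
  # renumber in order of ascending consensus m/z
  means <- vapply(split(mz_sorted, cl), mean, 0)
  relabel <- integer(max(cl))
  relabel[as.integer(names(means))] <- rank(means, ties.method = "first")
  relabel[cl]
}

#' Align peak tables into a consensus feature matrix
#'
#' All peak m/z values, pooled over injections, are clustered by
#' complete-linkage hierarchical clustering with absolute m/z difference
#' (Th) as the distance; the tree is cut at `cutoff` and each cluster
#' becomes one consensus feature whose m/z is the mean of its member peaks.
#' A spectrum's feature intensity is its member peak height; if several
#' peaks of one spectrum fall in the same cluster their heights are summed.
#' Rows missing a member peak get 0 (pre-imputation).
#'
#' @param tables list of [peak_table()] objects (>= 2 unless a single
#'   spectrum is being projected).
#' @param cutoff cut height in Th, or `"auto"` to call [choose_cutoff()]
#'   with its default candidate grid.
#' @return an [aligned_matrix()] at injection level (one row per peak
#'   table), with class labels `NA` (attach labels downstream), plus
#'   attribute `"features"`: a data.frame (feature id, consensus m/z,
#'   number of member peaks).
#' @export
align_peaks <- function(tables, cutoff = "auto") {
  df <- pool_peaks(tables)
  if (identical(cutoff, "auto")) cutoff <- choose_cutoff(tables)
  cutoff <- check_number(cutoff, "cutoff", min = 0)
  cl <- cluster_mz(df$mz, cutoff)
  feat_mz <- vapply(split(df$mz, cl), mean, 0)
  o <- order(feat_mz)
  feat_mz <- feat_mz[o]
  col_of <- match(cl, as.integer(names(feat_mz)))
  n_feat <- length(feat_mz)
  n_spec <- length(tables)
  X <- matrix(0, nrow = n_spec, ncol = n_feat)
  for (r in seq_len(nrow(df)))
    X[df$spectrum[r], col_of[r]] <- X[df$spectrum[r], col_of[r]] + df$height[r]
  n_members <- as.integer(table(factor(col_of, levels = seq_len(n_feat))))
  mat <- aligned_matrix(
    sample_ids = vapply(tables, function(t) t$sample_id, ""),
    class_labels = rep(NA_character_, n_spec),
    feature_mz = as.numeric(feat_mz),
    intensities = X,
    replicate_ids = vapply(tables, function(t) t$replicate_id, "")
  )
  attr(mat, "cutoff") <- cutoff
  attr(mat, "features") <- data.frame(feature = seq_len(n_feat),
                                      mz = as.numeric(feat_mz),
                                      n_members = n_members)
  mat
}

# number of clusters at `cutoff` that contain >= 2 peaks from one spectrum
count_coclustering <- function(df, cutoff) {
  cl <- cluster_mz(df$mz, cutoff)
  key <- paste(cl, df$spectrum)
  sum(tapply(duplicated(key), cl, any))
}

#' Choose the alignment cutoff
#'
#' Evaluates each candidate cut height by the number of clusters that merge
#' two or more peaks of the *same* spectrum — distinct ions that should stay
#' distinct — and returns the candidate minimizing that count. Ties are
#' broken toward the larger cutoff (fewer split features).
#'
#' @param tables list of [peak_table()] objects.
#' @param candidate_cutoffs numeric candidates in Th; default a 20-point
#'   logarithmic grid on 0.001–0.5.
#' @return the selected cutoff (Th), with the per-candidate objective in
#'   attribute `"objective"`.
#' @export
choose_cutoff <- function(tables,
                          candidate_cutoffs = 10^seq(log10(0.001), log10(0.5),
                                                     length.out = 20)) {
  if (length(candidate_cutoffs) < 1L) stop("need at least one candidate cutoff")
  df <- pool_peaks(tables)
  obj <- vapply(candidate_cutoffs, function(h) count_coclustering(df, h), 0)
  o <- order(obj, -candidate_cutoffs)  # min objective, ties -> larger cutoff
  sel <- candidate_cutoffs[o[1]]
  attr(sel, "objective") <- data.frame(cutoff = candidate_cutoffs, coclustered = obj)
  sel
}

#' Average technical replicates
#'
#' Arithmetic mean of each feature across an injection's technical
#' replicates, giving one row per biological sample. Class labels must be
#' constant within a sample.
#'
#' @param mat an injection-level [aligned_matrix()].
#' @param replicate_map optional character vector mapping each row to its
#'   biological sample; defaults to the matrix's `sample_ids`.
#' @return an [aligned_matrix()] with `replicate_ids = NULL`, rows ordered
#'   by first appearance of each sample.
#' @export
average_replicates <- function(mat, replicate_map = NULL) {
  stopifnot(inherits(mat, "aligned_matrix"))
  map <- replicate_map %||% mat$sample_ids
  if (length(map) != nrow(mat$intensities))
    stop("replicate map must name every row (unmapped replicate)")
  if (anyNA(map)) stop("replicate map must name every row (unmapped replicate)")
  samples <- unique(map)
  X <- matrix(0, nrow = length(samples), ncol = ncol(mat$intensities))
  labs <- character(length(samples))
  for (i in seq_along(samples)) {
    rows <- which(map == samples[i])
    X[i, ] <- colMeans(mat$intensities[rows, , drop = FALSE])
    lab <- unique(mat$class_labels[rows])
    if (length(lab) != 1L)
      stop("class label differs between replicates of sample ", samples[i])
    labs[i] <- lab
  }
  aligned_matrix(samples, labs, mat$feature_mz, X)
}
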