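# Exact-mass annotation of consensus features against a compound database,
# with signed relative mass errors in ppm.

#' Signed relative mass error in ppm
#'
#' Computed as `(theoretical - experimental) / theoretical * 1e6`: an
#' experimental mass *below* the theoretical one gives a *positive* error.
#' (The opposite sign convention is also in circulation; this one is fixed
#' here and used consistently by [annotate()].)
#'
#' @param experimental_mz,theoretical_mz positive masses in Th; vectorized.
#' @return signed ppm error(s).
#' @export
ppm_error <- function(experimental_mz, theoretical_mz) {
  if (any(experimental_mz <= 0) || any(theoretical_mz <= 0))
    stop("masses must be > 0")
  (theoretical_mz - experimental_mz) / theoretical_mz * 1e6
}

#' Annotate consensus features by exact mass
#'
#' Each feature is matched to every database entry within `tol_ppm` of its
#' consensus m/z; features matching several entries are flagged ambiguous,
#' unmatched features are omitted.
#'
#' @param matrix an [aligned_matrix()], or a numeric vector of feature m/z
#'   values.
#' @param db a [compound_db()].
#' @param tol_ppm tolerance in ppm (> 0). The default 10 ppm is a customary
#'   bound for a well-calibrated TOF.
#' @return data.frame: `feature` (column index), `mz`, `name`,
#'   `theoretical_mz`, `ppm`, `ambiguous`.
#' @export
annotate <- function(matrix, db, tol_ppm = 10) {
  tol_ppm <- check_number(tol_ppm, "tol_ppm", min = 1e-12)
  mzs <- if (inherits(matrix, "aligned_matrix")) matrix$feature_mz else as.numeric(matrix)
  empty <- data.frame(feature = integer(), mz = numeric(), name = character(),
                      theoretical_mz = numeric(), ppm = numeric(),
                      ambiguous = logical())
  if (!inherits(db, "compound_db") || !nrow(db)) {
    warning("empty compound database: nothing annotated")
    return(empty)
  }
  hits <- lapply(seq_along(mzs), function(i) {
    err <- ppm_error(mzs[i], db$theoretical_mz)
    j <- which(abs(err) <= tol_ppm)
    if (!length(j)) return(NULL)
    data.frame(feature = i, mz = mzs[i], name = db$name[j],
               theoretical_mz = db$theoretical_mz[j], ppm = err[j],
               ambiguous = length(j) > 1L)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}
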