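# File formats: a plain two-column text dialect for spectra, CSV for peak
# tables / aligned matrices / compound databases. mzML is read through mzR
# when the file extension asks for it.

#' Write a raw spectrum to the two-column text dialect
#'
#' Format: `# sample=<id> replicate=<id>` on the first line, then for each
#' scan a `# scan=<k>` header followed by `m/z<TAB>intensity` lines.
#'
#' @param spec a [raw_spectrum()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_txt <- function(spec, path) {
  stopifnot(inherits(spec, "raw_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample=%s replicate=%s", spec$sample_id, spec$replicate_id), con)
  for (k in seq_len(nrow(spec$intensity))) {
    writeLines(sprintf("# scan=%d", k), con)
    writeLines(paste(format(spec$mz, trim = TRUE, digits = 10),
                     format(spec$intensity[k, ], trim = TRUE, digits = 10),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a raw spectrum from the two-column text dialect
#'
#' @param path file written by [write_spectrum_txt()].
#' @return a [raw_spectrum()].
#' @export
read_spectrum_txt <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty spectrum file: ", path)
  sample_id <- sub(".*sample=(\\S+).*", "\\1", lines[1])
  replicate_id <- sub(".*replicate=(\\S+).*", "\\1", lines[1])
  scan_starts <- grep("^# scan=", lines)
  if (!length(scan_starts)) stop("no '# scan=' headers in ", path)
  ends <- c(scan_starts[-1] - 1L, length(lines))
  scans <- lapply(seq_along(scan_starts), function(i) {
    block <- lines[(scan_starts[i] + 1L):ends[i]]
    block <- block[nzchar(block) & !startsWith(block, "#")]
    m <- matrix(as.numeric(unlist(strsplit(block, "[\t ]+"))), ncol = 2L, byrow = TRUE)
    m
  })
  mz <- scans[[1]][, 1]
  inten <- do.call(rbind, lapply(scans, function(m) {
    if (nrow(m) != length(mz) || max(abs(m[, 1] - mz)) > 1e-9)
      stop("scans do not share one m/z grid in ", path)
    m[, 2]
  }))
  raw_spectrum(sample_id, replicate_id, mz, inten)
}

#' Read a raw spectrum from mzML (or the text dialect, by extension)
#'
#' mzML is read through the \pkg{mzR} parser. All scans must share one m/z
#' grid (profile-mode acquisition); sample and replicate ids default to the
#' file name.
#'
#' @param path input file; `.mzML` is parsed with mzR, anything else with
#'   [read_spectrum_txt()].
#' @param sample_id,replicate_id optional identifying tokens.
#' @return a [raw_spectrum()].
#' @export
read_spectrum <- function(path, sample_id = NULL, replicate_id = "1") {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h)
    if (is.matrix(pk)) pk <- list(pk)
    mz <- pk[[1]][, 1]
    inten <- do.call(rbind, lapply(pk, function(m) m[, 2]))
    raw_spectrum(sample_id %||% basename(path), replicate_id, mz, inten)
  } else {
    sp <- read_spectrum_txt(path)
    if (!is.null(sample_id)) sp$sample_id <- sample_id
    sp
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a peak table CSV
#'
#' Columns: sample_id, replicate_id, mz, height.
#'
#' @param table a [peak_table()].
#' @param path CSV file.
#' @return `path` (write) or a [peak_table()] (read).
#' @export
write_peak_table_csv <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(sample_id = table$sample_id,
                   replicate_id = table$replicate_id,
                   mz = table$peaks$mz, height = table$peaks$height)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table_csv
#' @export
read_peak_table_csv <- function(path) {
  df <- read.csv(path)
  peak_table(df$sample_id[1] %||% "", df$replicate_id[1] %||% "",
             mz = df$mz, height = df$height)
}

#' Write an aligned matrix to CSV
#'
#' Dialect: first column `sample_id`, second `class`, remaining columns one
#' per consensus feature, headed by its m/z. For replicate-level matrices
#' the sample id is written as `sample#replicate`.
#'
#' @param mat an [aligned_matrix()].
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_aligned_csv <- function(mat, path) {
  stopifnot(inherits(mat, "aligned_matrix"))
  ids <- if (is.null(mat$replicate_ids)) mat$sample_ids
         else paste(mat$sample_ids, mat$replicate_ids, sep = "#")
  df <- data.frame(sample_id = ids, class = mat$class_labels,
                   mat$intensities, check.names = FALSE)
  colnames(df)[-(1:2)] <- format(mat$feature_mz, trim = TRUE, digits = 10)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an aligned matrix from CSV
#'
#' @param path file written by [write_aligned_csv()].
#' @return an [aligned_matrix()].
#' @export
read_aligned_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  reps <- NULL
  if (any(grepl("#", ids, fixed = TRUE))) {
    reps <- sub("^.*#", "", ids)
    ids <- sub("#[^#]*$", "", ids)
  }
  aligned_matrix(ids, as.character(df[[2]]),
                 feature_mz = as.numeric(colnames(df)[-(1:2)]),
                 intensities = as.matrix(df[, -(1:2), drop = FALSE]),
                 replicate_ids = reps)
}

#' Read a compound database CSV
#'
#' Expects columns `name` and `theoretical_mz` (positive, names unique).
#'
#' @param path CSV file.
#' @return a data.frame of class `compound_db`.
#' @export
read_compound_db <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "theoretical_mz") %in% names(df)))
    stop("compound database needs columns 'name' and 'theoretical_mz'")
  compound_db(df$name, df$theoretical_mz)
}

#' Construct a compound database
#'
#' @param name unique compound names.
#' @param theoretical_mz positive theoretical m/z values (Th).
#' @return a data.frame of class `compound_db`.
#' @export
compound_db <- function(name, theoretical_mz) {
  if (anyDuplicated(name)) stop("compound names must be unique")
  if (any(theoretical_mz <= 0)) stop("theoretical_mz must be > 0")
  structure(data.frame(name = as.character(name),
                       theoretical_mz = as.numeric(theoretical_mz),
                       stringsAsFactors = FALSE),
            class = c("compound_db", "data.frame"))
}
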