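# End-to-end workflow: spectra (or a simulated cohort, or pre-aligned
# matrices) -> peak tables -> aligned features -> annotation -> ordered
# ratios -> GA selection ranked on independent validation data -> RF
# benchmark. Every stage's output is written to the output directory and
# re-loadable; a manifest records the seed and parameters.

#' Pipeline configuration
#'
#' Exactly one input source must be given: `spectra_manifest` (CSV with
#' columns file, sample_id, replicate_id, class, set — set is "learning" or
#' "validation"), or `learning_matrix`/`validation_matrix` (aligned-matrix
#' CSVs), or `simulate = TRUE` (synthetic cohort from `cohort_config`,
#' split half/half into learning and validation samples per class).
#'
#' @param out_dir output directory (created if missing).
#' @param spectra_manifest path to a spectra manifest CSV, or `NULL`.
#' @param learning_matrix,validation_matrix aligned-matrix CSV paths, or
#'   `NULL`.
#' @param simulate simulate the cohort instead of reading files.
#' @param cohort_config a [cohort_sim_config()] (when `simulate`).
#' @param peak_params a [peak_params()] for preprocessing.
#' @param alignment_cutoff cut height in Th or `"auto"`.
#' @param compound_db path to a compound database CSV, or `NULL` to skip
#'   annotation.
#' @param annotation_ppm annotation tolerance (ppm).
#' @param annotated_only restrict ratio building to annotated features
#'   (requires `compound_db`).
#' @param ga a [ga_config()].
#' @param rf_n_trees_grid,rf_mtry_grid RF tuning grids ([rf_full()]).
#' @param rf_top_k top-importance sizes for reduced forests.
#' @param cv_repeats CV repeats for ranking and reporting.
#' @param seed master seed, recorded in every artifact.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            spectra_manifest = NULL,
                            learning_matrix = NULL, validation_matrix = NULL,
                            simulate = FALSE,
                            cohort_config = cohort_sim_config(),
                            peak_params = ratiomics::peak_params(),
                            alignment_cutoff = "auto",
                            compound_db = NULL, annotation_ppm = 10,
                            annotated_only = !is.null(compound_db),
                            ga = ga_config(),
                            rf_n_trees_grid = c(250L, 500L, 1000L),
                            rf_mtry_grid = NULL,
                            rf_top_k = c(6L, 2L),
                            cv_repeats = 30L,
                            seed = 1L) {
  sources <- c(!is.null(spectra_manifest),
               !is.null(learning_matrix) || !is.null(validation_matrix),
               isTRUE(simulate))
  if (sum(sources) != 1L)
    stop_cfg("input", "needs exactly one of spectra_manifest, learning/validation_matrix, simulate")
  if (!is.null(learning_matrix) && is.null(validation_matrix))
    stop_cfg("validation_matrix", "is required alongside learning_matrix")
  if (isTRUE(annotated_only) && is.null(compound_db))
    stop_cfg("compound_db", "is required when annotated_only = TRUE")
  structure(list(out_dir = out_dir, spectra_manifest = spectra_manifest,
                 learning_matrix = learning_matrix,
                 validation_matrix = validation_matrix,
                 simulate = isTRUE(simulate), cohort_config = cohort_config,
                 peak_params = peak_params,
                 alignment_cutoff = alignment_cutoff,
                 compound_db = compound_db, annotation_ppm = annotation_ppm,
                 annotated_only = isTRUE(annotated_only), ga = ga,
                 rf_n_trees_grid = rf_n_trees_grid,
                 rf_mtry_grid = rf_mtry_grid, rf_top_k = rf_top_k,
                 cv_repeats = cv_repeats,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# split an averaged aligned matrix into learning/validation halves,
# stratified by class (first half of each class learns)
split_cohort <- function(mat) {
  idx_l <- integer(); idx_v <- integer()
  for (cl in unique(mat$class_labels)) {
    rows <- which(mat$class_labels == cl)
    h <- ceiling(length(rows) / 2)
    idx_l <- c(idx_l, rows[seq_len(h)])
    idx_v <- c(idx_v, rows[-seq_len(h)])
  }
  subset_rows <- function(rows) aligned_matrix(
    mat$sample_ids[rows], mat$class_labels[rows], mat$feature_mz,
    mat$intensities[rows, , drop = FALSE])
  list(learning = subset_rows(idx_l), validation = subset_rows(idx_v))
}

load_pipeline_input <- function(cfg) {
  if (cfg$simulate) {
    pipeline_log("input", "simulating cohort (seed %d)", cfg$cohort_config$seed)
    sim <- simulate_cohort(cfg$cohort_config)
    avg <- average_replicates(sim$matrix)
    c(split_cohort(avg), list(ground_truth = sim$ground_truth))
  } else if (!is.null(cfg$spectra_manifest)) {
    man <- read.csv(cfg$spectra_manifest, stringsAsFactors = FALSE)
    need <- c("file", "sample_id", "replicate_id", "class", "set")
    if (!all(need %in% names(man)))
      stop("spectra manifest needs columns: ", paste(need, collapse = ", "))
    base <- dirname(cfg$spectra_manifest)
    tabs <- lapply(seq_len(nrow(man)), function(i) {
      f <- man$file[i]
      if (!file.exists(f)) f <- file.path(base, man$file[i])
      sp <- read_spectrum(f, sample_id = man$sample_id[i],
                          replicate_id = man$replicate_id[i])
      preprocess_spectrum(sp, cfg$peak_params)
    })
    pipeline_log("preprocess", "%d injections, %s peaks each",
                 length(tabs),
                 paste(range(vapply(tabs, function(t) nrow(t$peaks), 0L)),
                       collapse = "-"))
    mat <- align_peaks(tabs, cutoff = cfg$alignment_cutoff)
    pipeline_log("align", "%d consensus features (cutoff %.4g Th)",
                 ncol(mat$intensities), attr(mat, "cutoff"))
    mat$class_labels <- man$class[match(paste(mat$sample_ids, mat$replicate_ids),
                                        paste(man$sample_id, man$replicate_id))]
    avg <- average_replicates(mat)
    set_of <- man$set[match(avg$sample_ids, man$sample_id)]
    keep <- function(s) aligned_matrix(
      avg$sample_ids[set_of == s], avg$class_labels[set_of == s],
      avg$feature_mz, avg$intensities[set_of == s, , drop = FALSE])
    list(learning = keep("learning"), validation = keep("validation"),
         features = attr(mat, "features"))
  } else {
    list(learning = read_aligned_csv(cfg$learning_matrix),
         validation = read_aligned_csv(cfg$validation_matrix))
  }
}

#' Run the complete discrimination pipeline
#'
#' Executes preprocess -> align -> annotate -> ratios -> GA selection ->
#' evaluation -> RF benchmark on the configured input, writing every
#' stage's artifact under `cfg$out_dir`: the learning/validation matrices,
#' the annotation table, the selected solution (JSON), a benchmark CSV of
#' GA+LDA versus RF rows, per-run GA fitness traces, and a manifest (JSON)
#' with seed, parameters and package version. A stage failure aborts with
#' the stage name; artifacts already written are retained.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) list: `solution` (a `ga_solution`),
#'   `benchmark` (data.frame), `annotation`, `learning`, `validation`,
#'   `ga_runs`, `rf_reports`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  input <- run_stage("input", load_pipeline_input(cfg))
  learn <- input$learning; valid <- input$validation
  write_aligned_csv(learn, file.path(cfg$out_dir, "learning_matrix.csv"))
  write_aligned_csv(valid, file.path(cfg$out_dir, "validation_matrix.csv"))
  if (!is.null(input$features))
    write.csv(input$features, file.path(cfg$out_dir, "features.csv"),
              row.names = FALSE)

  ann <- NULL
  feature_subset <- seq_along(learn$feature_mz)
  if (!is.null(cfg$compound_db)) {
    ann <- run_stage("annotate", {
      db <- read_compound_db(cfg$compound_db)
      annotate(learn, db, tol_ppm = cfg$annotation_ppm)
    })
    write.csv(ann, file.path(cfg$out_dir, "annotation.csv"), row.names = FALSE)
    pipeline_log("annotate", "%d features annotated", length(unique(ann$feature)))
    if (cfg$annotated_only) {
      feature_subset <- sort(unique(ann$feature))
      if (length(feature_subset) < 2L)
        stop("pipeline stage 'annotate' failed: fewer than 2 annotated features")
    }
  }

  ratios_l <- run_stage("ratios", build_ratios(learn, feature_subset))
  ratios_v <- run_stage("ratios", build_ratios(valid, feature_subset))
  pipeline_log("ratios", "%d ordered ratios over %d features",
               ncol(ratios_l$ratios), length(feature_subset))

  ga_runs <- run_stage("select", run_ga(ratios_l, learn$class_labels, cfg$ga))
  traces <- do.call(rbind, lapply(seq_along(ga_runs$runs), function(r)
    data.frame(run = r,
               generation = seq_along(ga_runs$runs[[r]]$best_trace) - 1L,
               best_fitness = ga_runs$runs[[r]]$best_trace)))
  write.csv(traces, file.path(cfg$out_dir, "ga_fitness_trace.csv"),
            row.names = FALSE)
  solution <- run_stage("select", rank_and_select(
    ga_runs, ratios_l, learn$class_labels, ratios_v, valid$class_labels,
    cv_repeats = cfg$cv_repeats, seed = cfg$seed))
  pipeline_log("select", "solution: %d ratio(s), validation accuracy %.3f",
               length(solution$ratio_indices), solution$validation_accuracy)

  sol_json <- list(
    seed = cfg$seed,
    ratio_indices = solution$ratio_indices,
    ratio_names = solution$pair_names,
    pairs = solution$pairs,
    n_molecules = solution$n_molecules,
    molecule_names = if (!is.null(ann) && !is.null(solution$pairs)) {
      feats <- unique(c(solution$pairs$numerator, solution$pairs$denominator))
      unique(ann$name[ann$feature %in% feats])
    },
    learning_accuracy = solution$learning_accuracy,
    cv_accuracy = solution$cv_accuracy,
    validation_accuracy = solution$validation_accuracy)
  jsonlite::write_json(sol_json, file.path(cfg$out_dir, "solution.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  rf_reports <- run_stage("rf-benchmark", {
    full <- rf_full(ratios_l, learn$class_labels, ratios_v, valid$class_labels,
                    n_trees_grid = cfg$rf_n_trees_grid,
                    mtry_grid = cfg$rf_mtry_grid,
                    cv_repeats = cfg$cv_repeats, seed = cfg$seed)
    reduced <- lapply(cfg$rf_top_k[cfg$rf_top_k <= ncol(ratios_l$ratios)],
                      function(k) rf_reduced(
      full, ratios_l, learn$class_labels, ratios_v, valid$class_labels,
      top_k = k, n_trees_grid = cfg$rf_n_trees_grid,
      mtry_grid = cfg$rf_mtry_grid, cv_repeats = cfg$cv_repeats,
      seed = cfg$seed))
    c(list(full), reduced)
  })

  benchmark <- rbind(
    data.frame(method = "GA + LDA",
               n_ratios_in_model = length(solution$ratio_indices),
               learning_accuracy = solution$learning_accuracy,
               cv2_accuracy = solution$cv_accuracy,
               validation_accuracy = solution$validation_accuracy),
    do.call(rbind, lapply(rf_reports, function(r)
      data.frame(method = "RF", n_ratios_in_model = r$n_ratios_in_model,
                 learning_accuracy = r$learning_accuracy,
                 cv2_accuracy = r$cv2_accuracy,
                 validation_accuracy = r$validation_accuracy))))
  write.csv(benchmark, file.path(cfg$out_dir, "benchmark.csv"),
            row.names = FALSE)

  manifest <- list(
    package = "ratiomics",
    version = as.character(utils::packageVersion("ratiomics")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    parameters = list(
      alignment_cutoff = cfg$alignment_cutoff,
      annotation_ppm = cfg$annotation_ppm,
      annotated_only = cfg$annotated_only,
      peak_params = unclass(cfg$peak_params),
      ga = unclass(cfg$ga),
      rf_n_trees_grid = cfg$rf_n_trees_grid,
      rf_top_k = cfg$rf_top_k,
      cv_repeats = cfg$cv_repeats))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(solution = solution, benchmark = benchmark, annotation = ann,
                 learning = learn, validation = valid, ga_runs = ga_runs,
                 rf_reports = rf_reports, manifest = manifest,
                 ground_truth = input$ground_truth))
}
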