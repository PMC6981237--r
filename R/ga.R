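# Genetic-algorithm wrapper selection over ratio subsets. Individuals are
# variable-length sets of ratio-column indices (size bounded by
# subset_size_range); fitness is stratified 2-fold cross-validated LDA
# accuracy on the subset's columns. Several independent runs feed a
# multi-stage ranking: re-scored by repeated CV, filtered at an accuracy
# threshold, then judged on an independent validation set with parsimony
# tie-breaks.

#' Genetic-algorithm configuration
#'
#' @param population_size individuals per generation.
#' @param n_generations generations per run.
#' @param subset_size_range integer (min, max) ratios per individual.
#' @param crossover_prob probability a child is produced by crossover.
#' @param mutation_prob per-individual mutation probability.
#' @param n_ga_runs independent GA runs (different seeds).
#' @param elitism number of best individuals copied unchanged.
#' @param tournament_size selection tournament size.
#' @param fitness_cv_folds folds for the fitness CV (default 2).
#' @param fitness_cv_repeats CV repeats inside the fitness (default 1).
#' @param seed master seed; run r uses `seed + r`.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, n_generations = 200L,
                      subset_size_range = c(1L, 10L),
                      crossover_prob = 0.8, mutation_prob = 0.2,
                      n_ga_runs = 5L, elitism = 2L, tournament_size = 3L,
                      fitness_cv_folds = 2L, fitness_cv_repeats = 1L,
                      seed = 1L) {
  population_size <- check_count(population_size, "population_size", min = 2L)
  n_generations <- check_count(n_generations, "n_generations", min = 0L)
  if (length(subset_size_range) != 2L ||
      subset_size_range[1] < 1L || subset_size_range[1] > subset_size_range[2])
    stop_cfg("subset_size_range", "must be (min, max) with 1 <= min <= max")
  crossover_prob <- check_number(crossover_prob, "crossover_prob", 0, 1)
  mutation_prob <- check_number(mutation_prob, "mutation_prob", 0, 1)
  n_ga_runs <- check_count(n_ga_runs, "n_ga_runs")
  elitism <- check_count(elitism, "elitism", min = 0L)
  if (elitism >= population_size) stop_cfg("elitism", "must be < population_size")
  tournament_size <- check_count(tournament_size, "tournament_size")
  fitness_cv_folds <- check_count(fitness_cv_folds, "fitness_cv_folds", min = 2L)
  fitness_cv_repeats <- check_count(fitness_cv_repeats, "fitness_cv_repeats")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(population_size = population_size,
                 n_generations = n_generations,
                 subset_size_range = as.integer(subset_size_range),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 n_ga_runs = n_ga_runs, elitism = elitism,
                 tournament_size = tournament_size,
                 fitness_cv_folds = fitness_cv_folds,
                 fitness_cv_repeats = fitness_cv_repeats,
                 seed = seed),
            class = "ga_config")
}

ratio_matrix_of <- function(ratios) {
  if (inherits(ratios, "ratio_feature_set")) ratios$ratios else as.matrix(ratios)
}

#' Run the genetic algorithm over ratio subsets
#'
#' Each run initializes `population_size` random subsets (sizes uniform in
#' `subset_size_range`), then iterates: elitism carries the best
#' individuals unchanged; the rest of the next generation is produced by
#' tournament selection followed (with probability `crossover_prob`) by
#' subset-exchange crossover — the child samples, without replacement, from
#' the union of both parents' ratios, at a size drawn between the parent
#' sizes — and per-individual mutation that replaces, adds, or drops one
#' ratio (equal probability among the moves the size bounds allow).
#' Fitness is the stratified `fitness_cv_folds`-fold cross-validated LDA
#' accuracy of the subset's ratio columns, on one fixed split per run so
#' that fitness is deterministic and cacheable; all stochasticity flows
#' from `cfg$seed`.
#'
#' @param ratios a [build_ratios()] result (or plain samples x ratios
#'   matrix), all values finite.
#' @param y class labels, >= 2 classes.
#' @param cfg a [ga_config()].
#' @return an object of class `ga_runs`: list with `runs` — one element per
#'   run holding `population` (list of sorted index vectors), `fitness`,
#'   and `best_trace` (best fitness per generation, initial population
#'   first) — plus `cfg` and `n_ratios`.
#' @export
run_ga <- function(ratios, y, cfg = ga_config()) {
  R <- ratio_matrix_of(ratios)
  if (!all(is.finite(R))) stop("ratio matrix must be finite")
  y <- as.character(y)
  if (nrow(R) != length(y)) stop("one label per sample required")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need >= 2 classes")
  n_ratios <- ncol(R)
  kmin <- cfg$subset_size_range[1]
  kmax <- min(cfg$subset_size_range[2], n_ratios)
  if (kmin > n_ratios) stop_cfg("subset_size_range", "exceeds the number of ratios")
  y_int <- as.integer(factor(y, levels = classes)) - 1L

  runs <- lapply(seq_len(cfg$n_ga_runs), function(run) {
    run_seed <- cfg$seed + run
    folds <- with_seed(run_seed + 10000L,
                       make_stratified_folds(y, classes, cfg$fitness_cv_folds,
                                             cfg$fitness_cv_repeats))
    cache <- new.env(parent = emptyenv())
    fitness_of <- function(idx) {
      key <- paste(idx, collapse = ",")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      acc <- mean(.cv_lda_kernel(R[, idx, drop = FALSE], y_int, folds,
                                 length(classes), cfg$fitness_cv_folds, 1e-8))
      cache[[key]] <- acc
      acc
    }
    with_seed(run_seed, {
      pop <- replicate(cfg$population_size,
                       sort(sample.int(n_ratios, sample.int(kmax - kmin + 1L, 1L) + kmin - 1L)),
                       simplify = FALSE)
      fit <- vapply(pop, fitness_of, 0)
      best_trace <- max(fit)
      for (gen in seq_len(cfg$n_generations)) {
        o <- order(fit, decreasing = TRUE)
        new_pop <- pop[o[seq_len(cfg$elitism)]]
        while (length(new_pop) < cfg$population_size) {
          if (runif(1) < cfg$crossover_prob) {
            p1 <- pop[[tournament_pick(fit, cfg$tournament_size)]]
            p2 <- pop[[tournament_pick(fit, cfg$tournament_size)]]
            child <- crossover_sets(p1, p2)
          } else {
            child <- pop[[tournament_pick(fit, cfg$tournament_size)]]
          }
          if (runif(1) < cfg$mutation_prob)
            child <- mutate_set(child, n_ratios, kmin, kmax)
          new_pop[[length(new_pop) + 1L]] <- child
        }
        pop <- new_pop
        fit <- vapply(pop, fitness_of, 0)
        best_trace <- c(best_trace, max(fit))
      }
      list(population = pop, fitness = fit, best_trace = best_trace)
    })
  })
  structure(list(runs = runs, cfg = cfg, n_ratios = n_ratios),
            class = "ga_runs")
}

#' @export
print.ga_runs <- function(x, ...) {
  best <- vapply(x$runs, function(r) max(r$fitness), 0)
  cat(sprintf("ga_runs: %d runs over %d ratios; best fitness per run: %s\n",
              length(x$runs), x$n_ratios,
              paste(sprintf("%.3f", best), collapse = ", ")))
  invisible(x)
}

# index of the tournament winner (ties toward the earlier individual)
tournament_pick <- function(fit, size) {
  cand <- sample.int(length(fit), min(size, length(fit)))
  cand[which.max(fit[cand])]
}

crossover_sets <- function(p1, p2) {
  pool <- union(p1, p2)
  lo <- min(length(p1), length(p2)); hi <- max(length(p1), length(p2))
  size <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  sort(pool[sample.int(length(pool), size)])
}

mutate_set <- function(idx, n_ratios, kmin, kmax) {
  moves <- c("replace",
             if (length(idx) < kmax && length(idx) < n_ratios) "add",
             if (length(idx) > kmin) "drop")
  move <- moves[sample.int(length(moves), 1L)]
  outside <- setdiff(seq_len(n_ratios), idx)
  if (move == "replace" && length(outside)) {
    idx[sample.int(length(idx), 1L)] <- outside[sample.int(length(outside), 1L)]
  } else if (move == "add") {
    idx <- c(idx, outside[sample.int(length(outside), 1L)])
  } else if (move == "drop") {
    idx <- idx[-sample.int(length(idx), 1L)]
  }
  sort(idx)
}

#' Evaluate a ratio subset on learning and validation data
#'
#' @param indices ratio-column indices of the solution.
#' @param ratios_learn,ratios_valid [build_ratios()] results (or matrices)
#'   with identical columns, for the learning and validation samples.
#' @param y_learn,y_valid class labels.
#' @param cv_repeats repeats of the stratified 2-fold CV (default 30).
#' @param seed seed for the CV splits.
#' @return named numeric: `learning_accuracy` (training accuracy of the
#'   full-learning-set fit), `cv_accuracy` (repeated 2-fold CV mean),
#'   `validation_accuracy` (full-learning-set fit scored on validation).
#' @export
evaluate_solution <- function(indices, ratios_learn, y_learn,
                              ratios_valid, y_valid,
                              cv_repeats = 30L, seed = 1L) {
  RL <- ratio_matrix_of(ratios_learn)[, indices, drop = FALSE]
  RV <- ratio_matrix_of(ratios_valid)[, indices, drop = FALSE]
  y_learn <- as.character(y_learn); y_valid <- as.character(y_valid)
  model <- fit_lda(RL, y_learn)
  learn_acc <- mean(predict(model, RL) == y_learn)
  cv_acc <- cross_validate(RL, y_learn, k = 2L, n_repeats = cv_repeats,
                           seed = seed)$mean_accuracy
  valid_acc <- mean(predict(model, RV) == y_valid)
  c(learning_accuracy = learn_acc, cv_accuracy = cv_acc,
    validation_accuracy = valid_acc)
}

# distinct sorted-index solutions pooled over all final populations
distinct_solutions <- function(ga_runs) {
  all_pop <- unlist(lapply(ga_runs$runs, `[[`, "population"), recursive = FALSE)
  keys <- vapply(all_pop, paste, "", collapse = ",")
  all_pop[!duplicated(keys)]
}

#' Rank GA solutions and select the final fingerprint
#'
#' Implements the multi-stage selection: (1) every distinct
#' final-generation solution is re-scored by `cv_repeats`-times-repeated
#' stratified 2-fold CV on the learning set; (2) solutions above
#' `accuracy_threshold` survive; (3) each survivor's LDA model, fit on the
#' whole learning set, is scored on the independent validation set; (4) the
#' winner maximizes validation accuracy, with ties broken by fewest
#' distinct features (molecules), then fewest ratios, then highest CV
#' accuracy, then the lexicographically smallest index set (a canonical
#' last resort that makes selection deterministic). If no solution clears
#' the threshold, the best-by-CV solution is returned with a prominent
#' warning.
#'
#' @param ga_runs a [run_ga()] result, or a list of index vectors to rank.
#' @param ratios_learn,ratios_valid [build_ratios()] results (or matrices)
#'   with identical ratio columns.
#' @param y_learn,y_valid class labels.
#' @param cv_repeats CV repeats for re-scoring (default 30).
#' @param accuracy_threshold survival threshold on CV accuracy (default 0.8).
#' @param seed seed for the re-scoring CV splits (shared by all solutions,
#'   so ranking compares like with like).
#' @return an object of class `ga_solution`: `ratio_indices`, `pairs`
#'   (numerator/denominator feature ids, when available), `n_molecules`,
#'   `learning_accuracy`, `cv_accuracy`, `validation_accuracy`, and the
#'   ranking table of all evaluated solutions in `ranking`.
#' @export
rank_and_select <- function(ga_runs, ratios_learn, y_learn,
                            ratios_valid, y_valid,
                            cv_repeats = 30L, accuracy_threshold = 0.8,
                            seed = 1L) {
  sols <- if (inherits(ga_runs, "ga_runs")) distinct_solutions(ga_runs)
          else lapply(ga_runs, function(s) sort(as.integer(s)))
  if (!length(sols)) stop("no solutions to rank")
  RL <- ratio_matrix_of(ratios_learn)
  RV <- ratio_matrix_of(ratios_valid)
  if (ncol(RL) != ncol(RV))
    stop("learning and validation ratio sets must share their columns")
  y_learn <- as.character(y_learn); y_valid <- as.character(y_valid)
  pairs <- if (inherits(ratios_learn, "ratio_feature_set")) ratios_learn$pairs else NULL

  n_mol <- function(idx) {
    if (is.null(pairs)) NA_integer_
    else length(unique(c(pairs$numerator[idx], pairs$denominator[idx])))
  }
  cv <- vapply(sols, function(idx)
    cross_validate(RL[, idx, drop = FALSE], y_learn, k = 2L,
                   n_repeats = cv_repeats, seed = seed)$mean_accuracy, 0)

  surv <- which(cv > accuracy_threshold)
  if (!length(surv)) {
    warning("no solution exceeded a CV accuracy of ", accuracy_threshold,
            "; returning the best solution by CV accuracy", call. = FALSE)
    surv <- which(cv == max(cv))
  }
  ev <- t(vapply(surv, function(s) {
    idx <- sols[[s]]
    model <- fit_lda(RL[, idx, drop = FALSE], y_learn)
    c(learning_accuracy =
        mean(predict(model, RL[, idx, drop = FALSE]) == y_learn),
      validation_accuracy =
        mean(predict(model, RV[, idx, drop = FALSE]) == y_valid))
  }, numeric(2)))

  mol <- vapply(surv, function(s) n_mol(sols[[s]]), 0L)
  sizes <- lengths(sols[surv])
  mol_rank <- if (all(is.na(mol))) 2L * sizes else mol
  # final canonical tie-break: lexicographically smallest index set, so the
  # selection is a deterministic function of the candidate pool
  lex <- vapply(sols[surv], function(i) paste(sprintf("%09d", i), collapse = ","), "")
  o <- order(-ev[, "validation_accuracy"], mol_rank, sizes, -cv[surv], lex)
  w <- surv[o[1]]; wrow <- o[1]

  ranking <- data.frame(
    solution = vapply(sols[surv], paste, "", collapse = ","),
    n_ratios = sizes, n_molecules = mol, cv_accuracy = cv[surv],
    learning_accuracy = ev[, "learning_accuracy"],
    validation_accuracy = ev[, "validation_accuracy"])
  ranking <- ranking[o, , drop = FALSE]
  rownames(ranking) <- NULL

  structure(list(ratio_indices = sols[[w]],
                 pairs = if (!is.null(pairs)) pairs[sols[[w]], , drop = FALSE] else NULL,
                 pair_names = if (!is.null(colnames(RL))) colnames(RL)[sols[[w]]] else NULL,
                 n_molecules = n_mol(sols[[w]]),
                 learning_accuracy = unname(ev[wrow, "learning_accuracy"]),
                 cv_accuracy = unname(cv[w]),
                 validation_accuracy = unname(ev[wrow, "validation_accuracy"]),
                 n_evaluated = length(sols),
                 ranking = ranking),
            class = "ga_solution")
}

#' @export
print.ga_solution <- function(x, ...) {
  cat("ga_solution:", length(x$ratio_indices), "ratio(s)")
  if (!is.null(x$pair_names)) cat(" [", paste(x$pair_names, collapse = ", "), "]")
  cat(sprintf("\n  learning %.3f | cv %.3f | validation %.3f | %s molecules\n",
              x$learning_accuracy, x$cv_accuracy, x$validation_accuracy,
              x$n_molecules))
  invisible(x)
}

#' Exhaustively rank all ratio subsets of bounded size
#'
#' Enumerates every subset with size in `size_range` and applies exactly
#' the ranking of [rank_and_select()]. Tractable only for small ratio
#' counts; used as the ground-truth selector against which the GA search is
#' validated.
#'
#' @inheritParams rank_and_select
#' @param size_range integer (min, max) subset sizes.
#' @return a `ga_solution`.
#' @export
exhaustive_select <- function(ratios_learn, y_learn, ratios_valid, y_valid,
                              size_range = c(1L, 2L), cv_repeats = 30L,
                              accuracy_threshold = 0.8, seed = 1L) {
  n <- ncol(ratio_matrix_of(ratios_learn))
  sols <- list()
  for (k in seq.int(size_range[1], min(size_range[2], n)))
    sols <- c(sols, combn(n, k, simplify = FALSE))
  rank_and_select(sols, ratios_learn, y_learn, ratios_valid, y_valid,
                  cv_repeats = cv_repeats,
                  accuracy_threshold = accuracy_threshold, seed = seed)
}
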