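# Random-forest benchmark: the usual biomarker-discovery baseline the
# ratio/GA workflow is compared against. A forest on all ordered ratios is
# tuned by out-of-bag accuracy, ranked by permutation importance, and
# reduced forests are refit on the top-ranked ratios; each model reports
# learning, repeated-2-fold-CV, and validation accuracies.

#' Random forest on all ratios, tuned by out-of-bag accuracy
#'
#' Grid-searches the number of trees and the per-split candidate count
#' (`mtry`) by OOB accuracy, refits the winner, and reports learning
#' accuracy, `cv_repeats`-times-repeated stratified 2-fold CV accuracy,
#' validation accuracy, and the permutation-importance ranking of the
#' ratios (mean decrease in accuracy).
#'
#' @param ratios_learn,ratios_valid [build_ratios()] results (or matrices)
#'   with identical ratio columns.
#' @param y_learn,y_valid class labels.
#' @param n_trees_grid candidate forest sizes (default 250, 500, 1000).
#' @param mtry_grid candidate per-split counts; default `sqrt(p)`, `p/10`,
#'   `p/3` (deduplicated, floored at 1).
#' @param cv_repeats repeats of the stratified 2-fold CV (default 30).
#' @param seed integer seed controlling all forest and fold randomness.
#' @return an object of class `rf_report`: `n_ratios_in_model`,
#'   `learning_accuracy`, `cv2_accuracy`, `validation_accuracy`,
#'   `top_ratios_by_importance` (data.frame: ratio index, name, importance,
#'   sorted decreasing), `n_trees`, `mtry`, `oob_grid`.
#' @export
rf_full <- function(ratios_learn, y_learn, ratios_valid, y_valid,
                    n_trees_grid = c(250L, 500L, 1000L),
                    mtry_grid = NULL, cv_repeats = 30L, seed = 1L) {
  RL <- ratio_matrix_of(ratios_learn)
  RV <- ratio_matrix_of(ratios_valid)
  if (ncol(RL) != ncol(RV))
    stop("learning and validation ratio sets must share their columns")
  yl <- factor(as.character(y_learn))
  yv <- as.character(y_valid)
  p <- ncol(RL)
  if (is.null(mtry_grid))
    mtry_grid <- unique(pmax(1L, floor(c(sqrt(p), p / 10, p / 3))))
  mtry_grid <- unique(pmin(pmax(as.integer(mtry_grid), 1L), p))
  if (!length(n_trees_grid) || !length(mtry_grid))
    stop("degenerate tuning grid")

  grid <- expand.grid(n_trees = as.integer(n_trees_grid), mtry = mtry_grid)
  grid$oob_accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fit <- with_seed(seed + i, randomForest::randomForest(
      RL, yl, ntree = grid$n_trees[i], mtry = grid$mtry[i]))
    grid$oob_accuracy[i] <- 1 - fit$err.rate[grid$n_trees[i], "OOB"]
  }
  best <- which.max(grid$oob_accuracy)   # ties -> first (smaller model)

  final <- with_seed(seed, randomForest::randomForest(
    RL, yl, ntree = grid$n_trees[best], mtry = grid$mtry[best],
    importance = TRUE))
  imp <- randomForest::importance(final, type = 1L)[, 1L]
  ord <- order(imp, decreasing = TRUE)
  top <- data.frame(ratio = ord,
                    name = colnames(RL)[ord] %||% as.character(ord),
                    importance = unname(imp[ord]))

  learn_acc <- mean(as.character(predict(final, RL)) == as.character(yl))
  valid_acc <- mean(as.character(predict(final, RV)) == yv)
  cv2 <- rf_cv2(RL, as.character(yl), grid$n_trees[best], grid$mtry[best],
                cv_repeats, seed)

  structure(list(n_ratios_in_model = p,
                 learning_accuracy = learn_acc,
                 cv2_accuracy = cv2,
                 validation_accuracy = valid_acc,
                 top_ratios_by_importance = top,
                 n_trees = grid$n_trees[best], mtry = grid$mtry[best],
                 oob_grid = grid),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf(paste0("rf_report: %d ratios, ntree %d, mtry %d\n",
                     "  learning %.3f | 2-fold cv %.3f | validation %.3f\n"),
              x$n_ratios_in_model, x$n_trees, x$mtry,
              x$learning_accuracy, x$cv2_accuracy, x$validation_accuracy))
  invisible(x)
}

# repeated stratified 2-fold CV accuracy of a fixed-parameter forest
rf_cv2 <- function(X, y, n_trees, mtry, n_repeats, seed) {
  if (n_repeats < 1L) return(NA_real_)
  classes <- sort(unique(y))
  folds <- with_seed(seed + 777L,
                     make_stratified_folds(y, classes, 2L, n_repeats))
  accs <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    fold_acc <- numeric(2L)
    for (f in 1:2) {
      tr <- folds[, r] != f
      fit <- with_seed(seed + 1000L * r + f, randomForest::randomForest(
        X[tr, , drop = FALSE], factor(y[tr], levels = classes),
        ntree = n_trees, mtry = min(mtry, ncol(X))))
      pred <- as.character(predict(fit, X[!tr, , drop = FALSE]))
      fold_acc[f] <- mean(pred == y[!tr])
    }
    accs[r] <- mean(fold_acc)
  }
  mean(accs)
}

#' Reduced random forest on the top-ranked ratios
#'
#' Keeps the `top_k` ratios by the full model's permutation importance and
#' refits (grid-tuned on the reduced columns), reporting the same three
#' accuracies.
#'
#' @param full_report an [rf_full()] result.
#' @param top_k number of top-importance ratios to keep.
#' @inheritParams rf_full
#' @return an `rf_report`; `top_ratios_by_importance$ratio` indexes the
#'   original ratio columns.
#' @export
rf_reduced <- function(full_report, ratios_learn, y_learn,
                       ratios_valid, y_valid, top_k,
                       n_trees_grid = c(250L, 500L, 1000L),
                       mtry_grid = NULL, cv_repeats = 30L, seed = 1L) {
  stopifnot(inherits(full_report, "rf_report"))
  RL <- ratio_matrix_of(ratios_learn)
  RV <- ratio_matrix_of(ratios_valid)
  top_k <- check_count(top_k, "top_k")
  if (top_k > nrow(full_report$top_ratios_by_importance))
    stop("top_k exceeds the number of ranked ratios")
  keep <- full_report$top_ratios_by_importance$ratio[seq_len(top_k)]
  rep <- rf_full(RL[, keep, drop = FALSE], y_learn,
                 RV[, keep, drop = FALSE], y_valid,
                 n_trees_grid = n_trees_grid, mtry_grid = mtry_grid,
                 cv_repeats = cv_repeats, seed = seed)
  rep$top_ratios_by_importance$ratio <-
    keep[rep$top_ratios_by_importance$ratio]
  rep$top_ratios_by_importance$name <-
    colnames(RL)[rep$top_ratios_by_importance$ratio] %||%
    rep$top_ratios_by_importance$name
  rep
}
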