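# Linear discriminant analysis: the classifier whose cross-validated
# accuracy scores candidate ratio subsets, and the final discrimination
# model. Gaussian classes with one pooled covariance; a small relative
# ridge keeps the pooled covariance invertible for tiny feature panels.

#' Fit a linear discriminant model
#'
#' Equal-covariance Gaussian discriminant: per-class feature means, pooled
#' within-class covariance (denominator n - g) with a relative ridge
#' `ridge * trace(S)/d` added to the diagonal, and empirical class priors.
#'
#' @param X numeric samples x features matrix.
#' @param y class labels (character or factor), >= 2 classes, each with
#'   >= 2 samples.
#' @param ridge relative ridge factor (default 1e-8); 0 disables it.
#' @return an object of class `lda_model`.
#' @export
fit_lda <- function(X, y, ridge = 1e-8) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("one label per row required")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need >= 2 classes")
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2L))
    stop("every class needs >= 2 samples (offender: ",
         names(counts)[which.min(counts)], ")")
  d <- ncol(X)
  if (d > nrow(X))
    warning("more features (", d, ") than samples (", nrow(X), "): model is ill-posed")
  g <- length(classes)
  means <- matrix(0, g, d, dimnames = list(classes, colnames(X)))
  for (k in classes) means[k, ] <- colMeans(X[y == k, , drop = FALSE])
  S <- matrix(0, d, d)
  for (k in classes) {
    Xc <- sweep(X[y == k, , drop = FALSE], 2L, means[k, ], "-")
    S <- S + crossprod(Xc)
  }
  S <- S / max(nrow(X) - g, 1L)
  if (ridge > 0) diag(S) <- diag(S) + ridge * sum(diag(S)) / d
  structure(list(class_means = means,
                 pooled_covariance = S,
                 priors = as.numeric(counts) / nrow(X),
                 classes = classes,
                 ridge = ridge),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: %d classes (%s), %d features\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              ncol(x$class_means)))
  invisible(x)
}

#' Predict classes from a linear discriminant model
#'
#' Argmax over classes of
#' `log(prior_k) + x' S^{-1} mu_k - 0.5 mu_k' S^{-1} mu_k`;
#' exact score ties go to the earlier class label.
#'
#' @param object an `lda_model`.
#' @param newdata samples x features matrix with matching feature count.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  d <- ncol(object$class_means)
  if (ncol(X) != d)
    stop("newdata has ", ncol(X), " features; model expects ", d)
  W <- solve(object$pooled_covariance, t(object$class_means))   # d x g
  consts <- -0.5 * colSums(t(object$class_means) * W) + log(object$priors)
  scores <- sweep(X %*% W, 2L, consts, "+")
  object$classes[max.col(scores, ties.method = "first")]
}

#' Cross-validated LDA accuracy
#'
#' Per repeat: a stratified random k-fold split (fold sizes within each
#' class differ by at most one); LDA is fit on each training fold and
#' scored on the held-out fold; fold accuracies are averaged. The result
#' averages over repeats. All randomness flows from `seed`.
#'
#' @param X samples x features matrix.
#' @param y class labels; every class needs >= `k` samples.
#' @param k number of folds (default 2).
#' @param n_repeats number of independent repeats (default 1).
#' @param seed integer seed.
#' @param ridge relative ridge for the LDA fits.
#' @return an object of class `cv_result`: list with `fold_accuracies`
#'   (per-repeat fold-averaged accuracies), `mean_accuracy`, `k`,
#'   `n_repeats`, `seed`.
#' @export
cross_validate <- function(X, y, k = 2L, n_repeats = 1L, seed = 1L,
                           ridge = 1e-8) {
  X <- as.matrix(X)
  y <- as.character(y)
  k <- check_count(k, "k", min = 2L)
  n_repeats <- check_count(n_repeats, "n_repeats")
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  if (any(counts < k))
    stop("every class needs >= k samples for stratified ", k, "-fold CV")
  folds <- with_seed(seed, make_stratified_folds(y, classes, k, n_repeats))
  acc <- .cv_lda_kernel(X, as.integer(factor(y, levels = classes)) - 1L,
                        folds, length(classes), k, ridge)
  structure(list(fold_accuracies = as.numeric(acc),
                 mean_accuracy = mean(acc),
                 k = k, n_repeats = n_repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold x %d repeats, mean accuracy %.4f\n",
              x$k, x$n_repeats, x$mean_accuracy))
  invisible(x)
}

# n x n_repeats integer matrix of fold ids in 1..k, stratified by class
make_stratified_folds <- function(y, classes, k, n_repeats) {
  n <- length(y)
  folds <- matrix(0L, nrow = n, ncol = n_repeats)
  for (r in seq_len(n_repeats)) {
    for (cl in classes) {
      idx <- which(y == cl)
      folds[sample(idx), r] <- rep_len(seq_len(k), length(idx))
    }
  }
  folds
}
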