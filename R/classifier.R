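#' Class-balanced train/test split
#'
#' Samples each class without replacement into a training set of
#' `round(train_frac * n_class)` members; the remainder is the test set.
#' Deterministic under `seed`.
#'
#' @param labels Named character vector (names = sample ids) or factor
#'   of class labels.
#' @param train_frac Training fraction (default 0.8).
#' @param seed RNG seed.
#' @return List of class `split_plan`: `train_ids`, `test_ids`, `seed`.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1L) {
  ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  labels <- as.character(labels)
  if (any(table(labels) < 2)) {
    stop("every class needs at least 2 samples to split")
  }
  set.seed(seed)
  train <- character(0)
  for (cl in sort(unique(labels))) {
    members <- ids[labels == cl]
    n_train <- round(train_frac * length(members))
    train <- c(train, sample(members, n_train))
  }
  structure(list(train_ids = sort(train),
                 test_ids = sort(setdiff(ids, train)),
                 seed = as.integer(seed)),
            class = "split_plan")
}

# stratified fold assignment so every CV fold sees both classes
.stratified_foldid <- function(y, folds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  foldid
}

#' LASSO-regularized logistic regression with cross-validated lambda
#'
#' Fits an L1-penalized (`alpha = 1`) binomial model over a lambda grid
#' with stratified k-fold cross-validation and keeps the
#' deviance-minimizing lambda (the `lambda.min` convention). Predictors
#' are standardized internally on the training data; coefficients are
#' reported on the original scale.
#'
#' @param X Numeric matrix, samples x features (>= 2 features).
#' @param y Binary labels (logical, 0/1, or two-level factor/character;
#'   `positive` names the positive class for character/factor input).
#' @param folds Number of CV folds (default 10).
#' @param lambda_grid Optional lambda sequence (glmnet default if NULL).
#' @param positive Positive class label for non-numeric `y`.
#' @param rule `"min"` (default, CV-deviance-minimizing lambda) or
#'   `"1se"`.
#' @return List of class `lasso_fit`: `lambda_grid`, `chosen_lambda`,
#'   `coefficients` (intercept + per-feature, original scale),
#'   `nonzero` (feature names with nonzero coefficient),
#'   `cv_deviance`, and the underlying `cv.glmnet` object (`fit`).
#' @export
fit_lasso_logistic <- function(X, y, folds = 10, lambda_grid = NULL,
                               positive = NULL, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  yb <- .binarize(y, positive)
  if (min(table(yb)) < folds) {
    stop("smallest class (n = ", min(table(yb)),
         ") cannot populate ", folds, " stratified folds")
  }
  foldid <- .stratified_foldid(yb, folds)
  cv <- glmnet::cv.glmnet(X, yb, family = "binomial", alpha = 1,
                          foldid = foldid, lambda = lambda_grid,
                          type.measure = "deviance", standardize = TRUE)
  s <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.numeric(stats::coef(cv, s = s))
  names(beta) <- rownames(stats::coef(cv, s = s))
  structure(list(lambda_grid = cv$lambda, chosen_lambda = s,
                 coefficients = beta,
                 nonzero = names(beta)[-1][beta[-1] != 0],
                 cv_deviance = cv$cvm, fit = cv),
            class = "lasso_fit")
}

.binarize <- function(y, positive = NULL) {
  if (is.logical(y)) return(as.numeric(y))
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1)))
    return(y)
  }
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2) stop("y must have exactly two classes")
  if (is.null(positive)) positive <- lv[2]
  as.numeric(y == positive)
}

#' Predicted class probabilities from a lasso_fit
#'
#' @param object A `lasso_fit`.
#' @param newdata Matrix of samples x features.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, newx = as.matrix(newdata),
                            s = object$chosen_lambda, type = "response"))
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive scores
#' above a random negative, with ties contributing 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (see [fit_lasso_logistic()] for accepted
#'   encodings).
#' @param positive Positive class label for non-numeric `labels`.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels, positive = NULL) {
  yb <- .binarize(labels, positive)
  n_pos <- sum(yb == 1)
  n_neg <- sum(yb == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUC")
  }
  r <- rank(scores)
  (sum(r[yb == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Consensus feature selection over repeated fits
#'
#' The consensus set comprises features with a nonzero coefficient in
#' every repeat (strict all-repeats rule); the per-feature selection
#' frequency is retained.
#'
#' @param fits List of `lasso_fit` objects over repeats.
#' @return List with `consensus` (sorted feature ids), `nonzero_count`
#'   (named integer vector over the feature universe) and `n_repeats`.
#' @export
consensus_select <- function(fits) {
  stopifnot(length(fits) >= 1)
  universe <- names(fits[[1]]$coefficients)[-1]
  counts <- setNames(integer(length(universe)), universe)
  for (f in fits) counts[f$nonzero] <- counts[f$nonzero] + 1L
  list(consensus = sort(universe[counts == length(fits)]),
       nonzero_count = counts, n_repeats = length(fits))
}

#' Repeated class-balanced LASSO selection and evaluation protocol
#'
#' The full marker-selection procedure: optionally restrict to the top
#' `k_top` features of a supplied ranking, then repeat `n_repeats` times
#' {class-balanced 80/20 split, stratified 10-fold cross-validated LASSO
#' logistic fit on the training split, held-out scoring of the test
#' split}, take the consensus of features nonzero in every repeat, and
#' summarize the held-out AUC distribution. Repeat seeds are derived
#' from the master seed and logged.
#'
#' @param X Numeric matrix, samples x features, sample ids as rownames.
#' @param y Class labels, one per row of `X` (two classes).
#' @param feature_ranking Optional character vector of feature names,
#'   best first, from which the top `k_top` are used.
#' @param k_top Number of top-ranked features to keep (requires
#'   `feature_ranking`).
#' @param n_repeats Number of split/fit repeats (default 100).
#' @param folds CV folds within each training split (default 10).
#' @param train_frac Training fraction (default 0.8).
#' @param positive Positive class label.
#' @param seed Master seed.
#' @return Object of class `consensus_report`: `consensus_set`,
#'   `nonzero_count`, `auc` (per repeat), `auc_median`, `auc_iqr`,
#'   `chosen_lambdas`, `repeat_seeds`, `n_repeats`, `params`.
#' @export
run_protocol <- function(X, y, feature_ranking = NULL, k_top = NULL,
                         n_repeats = 100, folds = 10, train_frac = 0.8,
                         positive = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  if (!is.null(feature_ranking)) {
    if (is.null(k_top)) k_top <- length(feature_ranking)
    if (k_top > length(feature_ranking)) {
      stop("k_top exceeds the ", length(feature_ranking),
           " ranked features")
    }
    keep <- feature_ranking[seq_len(k_top)]
    if (!all(keep %in% colnames(X))) {
      stop("ranked features missing from X: ",
           paste(utils::head(setdiff(keep, colnames(X))), collapse = ", "))
    }
    X <- X[, keep, drop = FALSE]
  }
  y <- setNames(as.character(y), rownames(X))
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  fits <- vector("list", n_repeats)
  auc <- numeric(n_repeats)
  lam <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    plan <- stratified_split(y, train_frac, repeat_seeds[r])
    fit <- fit_lasso_logistic(X[plan$train_ids, , drop = FALSE],
                              y[plan$train_ids], folds = folds,
                              positive = positive)
    scores <- predict(fit, X[plan$test_ids, , drop = FALSE])
    auc[r] <- evaluate_auc(scores, y[plan$test_ids], positive)
    lam[r] <- fit$chosen_lambda
    fits[[r]] <- fit
  }
  cons <- consensus_select(fits)
  structure(list(consensus_set = cons$consensus,
                 nonzero_count = cons$nonzero_count,
                 auc = auc,
                 auc_median = stats::median(auc),
                 auc_iqr = unname(stats::quantile(auc, c(0.25, 0.75))),
                 chosen_lambdas = lam,
                 repeat_seeds = repeat_seeds,
                 n_repeats = n_repeats,
                 params = list(k_top = ncol(X), folds = folds,
                               train_frac = train_frac, seed = seed,
                               positive = positive)),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("Consensus LASSO report:", x$n_repeats, "repeats over",
      length(x$nonzero_count), "features\n")
  cat(sprintf("  held-out AUC median %.3f (IQR %.3f-%.3f)\n",
              x$auc_median, x$auc_iqr[1], x$auc_iqr[2]))
  if (length(x$consensus_set)) {
    cat("  consensus classifiers (nonzero in all repeats):\n")
    cat("   ", paste(x$consensus_set, collapse = ", "), "\n")
  } else {
    cat("  consensus set empty\n")
  }
  invisible(x)
}

#' @export
plot.consensus_report <- function(x, ...) {
  graphics::boxplot(x$auc, ylab = "held-out AUC",
                    main = sprintf("%d repeats; consensus size %d",
                                   x$n_repeats, length(x$consensus_set)),
                    ...)
  invisible(x)
}

#' One-versus-all-others consensus protocols
#'
#' Runs [run_protocol()] once per class, with that class as positive and
#' all other samples pooled as the negative class.
#'
#' @param X Samples x features matrix.
#' @param y Multiclass labels (>= 2 classes).
#' @param ... Passed to [run_protocol()] (e.g. `feature_ranking`,
#'   `k_top`, `n_repeats`).
#' @param seed Master seed; each class uses a seed derived from it.
#' @return Named list of `consensus_report`s, one per class.
#' @export
one_vs_rest <- function(X, y, ..., seed = 1L) {
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2) stop("need at least two classes")
  out <- vector("list", length(classes))
  names(out) <- classes
  for (i in seq_along(classes)) {
    cl <- classes[i]
    y_bin <- ifelse(as.character(y) == cl, cl, "rest")
    out[[cl]] <- run_protocol(X, y_bin, ..., positive = cl,
                              seed = seed + i)
  }
  out
}
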