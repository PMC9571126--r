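#' Fit a multi-target linear regression model
#'
#' Ordinary least squares per target (equivalently one multi-output linear
#' fit) on the given feature columns. Rank-deficient designs are handled by
#' the minimum-norm solution via the Moore-Penrose pseudo-inverse rather than
#' raising an error, so constant (degenerate) features get a zero coefficient
#' once min-max scaling has mapped them to a zero column.
#'
#' @param X Scaled feature matrix (rows = users, columns named by question
#'   id).
#' @param Y Scaled (possibly weighted) target matrix, columns named by goal
#'   id.
#' @return An object of class `mtr_model` with per-target intercepts and a
#'   targets x features coefficient matrix.
#' @export
fit_mtr <- function(X, Y) {
  assert_matrix(X, "X"); assert_matrix(Y, "Y")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same row count",
                               call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 rows to fit", call. = FALSE)
  if (ncol(Y) < 1) stop("need at least 1 target", call. = FALSE)
  A <- cbind(`(intercept)` = 1, X)
  qa <- qr(A)
  coefs <- if (qa$rank == ncol(A)) {
    qr.coef(qa, Y)
  } else {
    MASS::ginv(A) %*% Y  # minimum-norm solution for rank-deficient designs
  }
  coefs <- matrix(coefs, nrow = ncol(A), ncol = ncol(Y))
  B <- t(coefs[-1, , drop = FALSE])
  dimnames(B) <- list(colnames(Y), colnames(X))
  structure(list(
    intercept = stats::setNames(coefs[1, ], colnames(Y)),
    coef = B,
    features = colnames(X),
    targets = colnames(Y)
  ), class = "mtr_model")
}

#' Predict scaled quality scores
#'
#' @param object An `mtr_model`.
#' @param X Feature matrix with the model's feature columns.
#' @param ... Unused.
#' @return Users x targets matrix of predictions in the scaled target space.
#' @export
predict.mtr_model <- function(object, X, ...) {
  assert_matrix(X, "X")
  if (ncol(X) != ncol(object$coef)) {
    stop("X has ", ncol(X), " columns; model expects ", ncol(object$coef),
         call. = FALSE)
  }
  if (!is.null(colnames(X)) && !is.null(object$features) &&
      !identical(colnames(X), object$features)) {
    if (!setequal(colnames(X), object$features)) {
      stop("X columns do not match model features", call. = FALSE)
    }
    X <- X[, object$features, drop = FALSE]
  }
  out <- X %*% t(object$coef)
  sweep(out, 2, object$intercept, "+")
}

#' @export
print.mtr_model <- function(x, ...) {
  cat("Multi-target linear model:", length(x$targets), "targets,",
      length(x$features), "features\n")
  invisible(x)
}

#' Cross-validated feature-importance ranking
#'
#' Rows are partitioned into `k` seeded contiguous folds of a uniform
#' permutation. On each fold's training part the multi-target linear model is
#' fitted on all features; the per-fold importance of a question is the mean
#' over targets of the absolute coefficient (coefficients are comparable
#' because features are min-max scaled). The final importance is the mean
#' over folds. Ranking is descending by importance with ties broken by schema
#' question order, i.e. column order of `X`.
#'
#' @param X Scaled feature matrix (all candidate questions).
#' @param Y Scaled — and, in the personalised arm, weighted — target matrix.
#' @param k Fold count (default 5).
#' @param seed Fold seed.
#' @return A tibble `question_id, importance, rank`, sorted by rank.
#' @export
cv_feature_importance <- function(X, Y, k = 5, seed = 0) {
  assert_matrix(X, "X"); assert_matrix(Y, "Y")
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  n <- nrow(X)
  if (n < k) stop("fewer rows (", n, ") than folds (", k, ")", call. = FALSE)
  perm <- withr::with_seed(seed, sample.int(n))
  fold_sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  fold_assign <- rep(seq_len(k), times = fold_sizes)
  imp <- matrix(0, nrow = k, ncol = ncol(X))
  for (f in seq_len(k)) {
    train_rows <- perm[fold_assign != f]
    m <- fit_mtr(X[train_rows, , drop = FALSE], Y[train_rows, , drop = FALSE])
    imp[f, ] <- colMeans(abs(m$coef))
  }
  importance <- colMeans(imp)
  ord <- order(-importance, seq_along(importance))
  tibble::tibble(
    question_id = colnames(X)[ord],
    importance = importance[ord],
    rank = seq_along(ord),
    schema_index = ord
  )
}

#' Select the top-n questions of an importance ranking
#'
#' Takes the first `n` ranked questions and returns them re-ordered to schema
#' question order, so subsets display in questionnaire order and nested
#' subsets (`n = 4` inside `n = 6` ...) are easy to compare.
#'
#' @param ranking A ranking tibble from [cv_feature_importance()].
#' @param n Number of questions to keep (1..number of questions).
#' @return Character vector of question ids in schema order.
#' @export
select_top_n <- function(ranking, n) {
  if (n < 1 || n > nrow(ranking)) {
    stop("n must be between 1 and ", nrow(ranking), call. = FALSE)
  }
  top <- ranking[ranking$rank <= n, ]
  top$question_id[order(top$schema_index)]
}

#' Select n questions uniformly at random
#'
#' @param schema An [ffq_schema].
#' @param n Number of questions.
#' @param seed Draw seed.
#' @return Character vector of question ids in schema order.
#' @export
select_random_n <- function(schema, n, seed) {
  q <- question_ids(schema)
  if (n < 1 || n > length(q)) {
    stop("n must be between 1 and ", length(q), call. = FALSE)
  }
  idx <- withr::with_seed(seed, sample.int(length(q), n))
  q[sort(idx)]
}

#' Per-goal test error in portions per day
#'
#' Predictions and truths are inverse-scaled back to portions per day before
#' the error is computed, so errors across goals and arms are on the common
#' questionnaire scale. The default metric is the mean absolute error over
#' test users; root-mean-square error is available via `metric = "rmse"`.
#'
#' @param model An `mtr_model`.
#' @param X_test Scaled test features restricted to the model's subset.
#' @param Y_test Scaled test targets (same goal columns as the model).
#' @param target_params `minmax_params` for the target columns.
#' @param metric `"mae"` or `"rmse"`.
#' @return Named non-negative numeric vector, one entry per goal.
#' @export
per_goal_test_error <- function(model, X_test, Y_test, target_params,
                                metric = c("mae", "rmse")) {
  metric <- match.arg(metric)
  if (nrow(X_test) == 0) stop("empty test set", call. = FALSE)
  pred <- inverse_minmax(predict(model, X_test), target_params)
  truth <- inverse_minmax(Y_test, target_params)
  resid <- pred - truth
  err <- switch(metric,
                mae = colMeans(abs(resid)),
                rmse = sqrt(colMeans(resid^2)))
  stats::setNames(as.numeric(err), colnames(Y_test))
}
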