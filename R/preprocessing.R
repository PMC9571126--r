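#' Fit per-column min-max scaling parameters
#'
#' Parameters are computed on the rows passed in — in the standard pipeline
#' the training rows only, so the test set never leaks into the scaling.
#'
#' @param m Numeric matrix (rows = users).
#' @return An object of class `minmax_params` holding per-column `min` and
#'   `max`.
#' @export
fit_minmax <- function(m) {
  assert_matrix(m)
  if (nrow(m) == 0 || ncol(m) == 0) stop("matrix is empty", call. = FALSE)
  structure(list(min = apply(m, 2, min), max = apply(m, 2, max),
                 columns = colnames(m)),
            class = "minmax_params")
}

#' Apply min-max scaling
#'
#' Maps `x` to `(x - min) / (max - min)` per column. Values from the fitting
#' rows land in `[0, 1]`; other rows (e.g. the test set) may fall outside and
#' are deliberately not clipped. Degenerate (constant) columns map to 0.
#'
#' @param m Numeric matrix.
#' @param params A `minmax_params` from [fit_minmax()].
#' @return Scaled matrix of the same shape.
#' @export
apply_minmax <- function(m, params) {
  assert_matrix(m)
  check_params_shape(m, params)
  rng <- params$max - params$min
  out <- sweep(m, 2, params$min, "-")
  nondeg <- rng > 0
  out[, nondeg] <- sweep(out[, nondeg, drop = FALSE], 2, rng[nondeg], "/")
  out[, !nondeg] <- 0
  out
}

#' Invert min-max scaling
#'
#' Exact algebraic inverse of [apply_minmax()] for non-degenerate columns;
#' degenerate columns are restored to their constant. Needed to express
#' prediction errors back in portions per day.
#'
#' @inheritParams apply_minmax
#' @return Matrix on the original scale.
#' @export
inverse_minmax <- function(m, params) {
  assert_matrix(m)
  check_params_shape(m, params)
  rng <- params$max - params$min
  out <- sweep(m, 2, rng, "*")
  sweep(out, 2, params$min, "+")
}

check_params_shape <- function(m, params) {
  if (!inherits(params, "minmax_params")) {
    stop("params must come from fit_minmax()", call. = FALSE)
  }
  if (ncol(m) != length(params$min)) {
    stop("matrix has ", ncol(m), " columns; params have ",
         length(params$min), call. = FALSE)
  }
  invisible(NULL)
}

subset_params <- function(params, cols) {
  idx <- if (is.character(cols)) match(cols, params$columns) else cols
  if (anyNA(idx)) stop("unknown column in scaling params", call. = FALSE)
  structure(list(min = params$min[idx], max = params$max[idx],
                 columns = params$columns[idx]),
            class = "minmax_params")
}

#' Split rows into train and test sets in a 3:1 ratio
#'
#' A seeded uniform permutation of the rows; the first `ceiling(0.75 * n)`
#' permuted rows form the training set.
#'
#' @param n_rows Number of rows (>= 8, so 5-fold cross-validation on the
#'   training part stays feasible).
#' @param seed Split seed.
#' @return A list with integer vectors `train` and `test`.
#' @export
split_train_test <- function(n_rows, seed) {
  if (n_rows < 8) stop("need at least 8 rows for a 3:1 split with 5-fold CV",
                       call. = FALSE)
  perm <- withr::with_seed(seed, sample.int(n_rows))
  n_train <- ceiling(0.75 * n_rows)
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[-seq_len(n_train)]))
}

#' Prepare split and scaled experiment data
#'
#' Splits responses 3:1, computes quality scores, fits min-max parameters for
#' features and targets and returns everything the experiment arms need.
#' With `scaling_scope = "train"` (default) scaling parameters come from the
#' training rows only; `"all"` fits them on the full dataset.
#'
#' @param responses Users x questions matrix (portions/day).
#' @param schema An [ffq_schema].
#' @param seed Master seed; the split uses a derived sub-seed.
#' @param scaling_scope `"train"` or `"all"`.
#' @return A list of class `ffq_experiment_data` with scaled feature/target
#'   train and test matrices, the scaling parameters and the split indices.
#' @export
prepare_experiment_data <- function(responses, schema, seed,
                                    scaling_scope = c("train", "all")) {
  scaling_scope <- match.arg(scaling_scope)
  scores <- compute_quality_scores(responses, schema)
  split <- split_train_test(nrow(responses), derive_seed(seed, "split"))
  fit_rows <- if (scaling_scope == "train") split$train else
    seq_len(nrow(responses))
  x_params <- fit_minmax(responses[fit_rows, , drop = FALSE])
  y_params <- fit_minmax(scores[fit_rows, , drop = FALSE])
  structure(list(
    X_train = apply_minmax(responses[split$train, , drop = FALSE], x_params),
    X_test = apply_minmax(responses[split$test, , drop = FALSE], x_params),
    Y_train = apply_minmax(scores[split$train, , drop = FALSE], y_params),
    Y_test = apply_minmax(scores[split$test, , drop = FALSE], y_params),
    x_params = x_params, y_params = y_params, split = split,
    schema = schema
  ), class = "ffq_experiment_data")
}
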