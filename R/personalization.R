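#' Distance from predicted quality scores to goal thresholds
#'
#' Computes `max((y_pred - y_opt) * y_adj, 0)` elementwise, where `y_adj` is
#' +1 for at-most goals and -1 for at-least goals. The distance is positive
#' exactly when the goal is violated — the predicted score over-reaches an
#' at-most threshold or falls short of an at-least threshold — and zero when
#' the goal is met (including exactly at the threshold).
#'
#' @param y_pred Numeric vector of predicted scores (any common scale with
#'   `y_opt`; in the pipeline both live in the scaled target space).
#' @param y_opt Threshold vector, same length.
#' @param y_adj Sign vector of -1/+1 values, same length.
#' @return Non-negative distance vector.
#' @export
distance_to_threshold <- function(y_pred, y_opt, y_adj) {
  if (length(y_pred) != length(y_opt) || length(y_pred) != length(y_adj)) {
    stop("y_pred, y_opt and y_adj must have equal length", call. = FALSE)
  }
  if (!all(y_adj %in% c(-1, 1))) {
    stop("y_adj entries must be -1 or +1", call. = FALSE)
  }
  pmax((y_pred - y_opt) * y_adj, 0)
}

#' Transform threshold distances into goal weights
#'
#' Distances are scaled to `[0, 1]` by dividing by the largest distance, so
#' the most-violated goal always gets weight 1 and the others keep weights
#' proportional to their violation. A floor `epsilon` keeps every activated
#' goal in the regression — a zero weight would erase its target column and
#' make its coefficients (and error) meaningless. When no goal is violated
#' all weights fall back to 1 (uniform), reducing personalised selection to
#' the static one. `scaling = "minmax"` offers the alternative reading where
#' the least-violated goal is mapped to the floor.
#'
#' @param dist Non-negative distance vector.
#' @param floor Weight floor epsilon in `[0, 1)`; default 0.05.
#' @param scaling `"max"` (divide by max, default) or `"minmax"`.
#' @return Weight vector in `[floor, 1]`, or all 1 when nothing is violated.
#' @export
distances_to_weights <- function(dist, floor = 0.05,
                                 scaling = c("max", "minmax")) {
  scaling <- match.arg(scaling)
  if (any(dist < 0)) stop("distances must be non-negative", call. = FALSE)
  if (max(dist) == 0) return(rep(1, length(dist)))
  w <- switch(scaling,
              max = dist / max(dist),
              minmax = if (max(dist) > min(dist)) {
                (dist - min(dist)) / (max(dist) - min(dist))
              } else {
                rep(1, length(dist))
              })
  pmax(w, floor)
}

#' Re-scale target columns by goal weights
#'
#' Multiplies each target column by its goal weight. After this the quality
#' scores are deliberately no longer on a common `[0, 1]` interval: goals
#' further from their threshold carry larger values and are therefore treated
#' as more important by the subsequent feature-importance computation.
#'
#' @param Y Users x activated-goals matrix (scaled target space).
#' @param w Weight vector, one entry per column of `Y`.
#' @return Weighted target matrix.
#' @export
reweight_targets <- function(Y, w) {
  assert_matrix(Y, "Y")
  if (ncol(Y) != length(w)) {
    stop("Y has ", ncol(Y), " columns; weights have length ", length(w),
         call. = FALSE)
  }
  sweep(Y, 2, w, "*")
}

#' Map portions-per-day thresholds into the scaled target space
#'
#' Applies the target min-max transform to the thresholds so predicted scores
#' and thresholds are commensurable. Thresholds of degenerate (constant)
#' target columns map to 0, matching the scaling rule for those columns.
#'
#' @param thresholds Named threshold vector (portions/day).
#' @param target_params `minmax_params` fitted on the target columns, in the
#'   same column order.
#' @return Scaled threshold vector.
#' @export
scale_thresholds <- function(thresholds, target_params) {
  rng <- target_params$max - target_params$min
  out <- ifelse(rng > 0, (thresholds - target_params$min) / rng, 0)
  stats::setNames(as.numeric(out), names(thresholds))
}

#' Personalised question selection
#'
#' The two-step personalised pipeline. Step 1 is the static pipeline:
#' cross-validated importance on the unweighted activated targets, top-n
#' subset, model fit on the training rows and prediction on the evaluation
#' rows. Step 2 turns the predictions into weights — mean predicted score per
#' activated goal (population mode) or one user's predicted scores (user
#' mode), distance to the scaled thresholds, distances scaled to `[0, 1]` —
#' re-scales the training targets by those weights, recomputes the
#' cross-validated importance and reselects the top-n subset. With uniform
#' weights (no violation, or a single activated goal) step 2 reproduces the
#' static subset exactly.
#'
#' @param prep An `ffq_experiment_data` from [prepare_experiment_data()].
#' @param active Character vector of activated goal ids (>= 1).
#' @param n Subset size (1..number of questions).
#' @param seed Master seed; cross-validation folds use a derived sub-seed.
#' @param config An [experiment_config()]; supplies the fold count, weight
#'   floor, weight scaling, error metric and weight mode.
#' @param user_id Row name in the evaluation rows, required for
#'   `weight_mode = "user"`.
#' @return A list with `subset` (personalised), `static_subset`, `weights`
#'   (named by goal), and the two rankings.
#' @export
personalised_selection <- function(prep, active, n, seed,
                                   config = experiment_config(),
                                   user_id = NULL) {
  stopifnot(inherits(prep, "ffq_experiment_data"))
  check_active(prep$schema, active)
  Y_train <- prep$Y_train[, active, drop = FALSE]
  folds_seed <- derive_seed(seed, "folds")
  ranking1 <- cv_feature_importance(prep$X_train, Y_train,
                                    k = config$k_folds, seed = folds_seed)
  static_subset <- select_top_n(ranking1, n)
  model1 <- fit_mtr(prep$X_train[, static_subset, drop = FALSE], Y_train)
  pred <- predict(model1, prep$X_test[, static_subset, drop = FALSE])
  y_pred <- if (config$weight_mode == "user") {
    if (is.null(user_id) || !user_id %in% rownames(pred)) {
      stop("weight_mode 'user' needs a user_id present in the evaluation rows",
           call. = FALSE)
    }
    pred[user_id, ]
  } else {
    colMeans(pred)
  }
  y_params_active <- subset_params(prep$y_params, active)
  y_opt <- scale_thresholds(goal_thresholds(prep$schema, active),
                            y_params_active)
  y_adj <- goal_adjustments(prep$schema, active)
  dist <- distance_to_threshold(y_pred, y_opt, y_adj)
  w <- distances_to_weights(dist, floor = config$weight_floor,
                            scaling = config$weight_scaling)
  ranking2 <- cv_feature_importance(prep$X_train, reweight_targets(Y_train, w),
                                    k = config$k_folds, seed = folds_seed)
  list(subset = select_top_n(ranking2, n),
       static_subset = static_subset,
       weights = stats::setNames(w, active),
       static_ranking = ranking1,
       personalised_ranking = ranking2)
}

check_active <- function(schema, active) {
  if (length(active) < 1) stop("need at least one activated goal",
                               call. = FALSE)
  unknown <- setdiff(active, goal_ids(schema))
  if (length(unknown) > 0) {
    stop("unknown goal id: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(active)) stop("duplicated activated goal", call. = FALSE)
  invisible(active)
}
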