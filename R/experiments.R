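#' Experiment configuration
#'
#' Collects the knobs of the three-arm comparison in one validated object.
#'
#' @param arms Subset of `c("random", "static", "personalised")`.
#' @param feature_counts Question-subset sizes to sweep; the standard grid
#'   layouts give 4 (2x2), 6 (3x2), 9 (3x3) and 12 (4x3).
#' @param goal_combinations Explicit list of activated-goal id vectors, or
#'   `NULL` to sample `n_combinations` combinations stratified by size from
#'   all sets with at least `min_active` goals.
#' @param min_active Minimum number of activated goals (default 2; a single
#'   activated goal makes the personalised arm coincide with the static one).
#' @param n_combinations How many combinations to sample when
#'   `goal_combinations` is `NULL`.
#' @param n_users Synthetic population size per seed.
#' @param seeds Integer vector of master seeds.
#' @param error_metric `"mae"` or `"rmse"`.
#' @param weight_floor Personalised weight floor epsilon.
#' @param weight_scaling `"max"` or `"minmax"` (see [distances_to_weights()]).
#' @param scaling_scope `"train"` or `"all"` (see
#'   [prepare_experiment_data()]).
#' @param k_folds Cross-validation fold count for feature importance.
#' @param weight_mode `"population"` or `"user"`.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(arms = c("random", "static", "personalised"),
                              feature_counts = c(4, 6, 9, 12),
                              goal_combinations = NULL,
                              min_active = 2,
                              n_combinations = 60,
                              n_users = 1000,
                              seeds = 1:10,
                              error_metric = c("mae", "rmse"),
                              weight_floor = 0.05,
                              weight_scaling = c("max", "minmax"),
                              scaling_scope = c("train", "all"),
                              k_folds = 5,
                              weight_mode = c("population", "user")) {
  arms <- match.arg(arms, several.ok = TRUE)
  if (length(arms) == 0 || length(feature_counts) == 0 || length(seeds) == 0) {
    stop("arms, feature_counts and seeds must be non-empty", call. = FALSE)
  }
  structure(list(
    arms = arms,
    feature_counts = as.integer(feature_counts),
    goal_combinations = goal_combinations,
    min_active = as.integer(min_active),
    n_combinations = as.integer(n_combinations),
    n_users = as.integer(n_users),
    seeds = as.integer(seeds),
    error_metric = match.arg(error_metric),
    weight_floor = weight_floor,
    weight_scaling = match.arg(weight_scaling),
    scaling_scope = match.arg(scaling_scope),
    k_folds = as.integer(k_folds),
    weight_mode = match.arg(weight_mode)
  ), class = "experiment_config")
}

#' Enumerate activated-goal combinations
#'
#' All subsets with at least `min_active` goals, ordered by increasing size
#' and lexicographically by schema goal order within each size — a
#' deterministic enumeration. For 11 goals and `min_active = 2` there are
#' `2^11 - 1 - 11 = 2036` such subsets.
#'
#' @param goals Character vector of goal ids (schema order), or an integer
#'   goal count (ids then default to `g1, g2, ...`).
#' @param min_active Minimum subset size.
#' @return List of character vectors.
#' @export
enumerate_goal_combinations <- function(goals, min_active = 2) {
  if (is.numeric(goals) && length(goals) == 1) {
    goals <- paste0("g", seq_len(goals))
  }
  n <- length(goals)
  if (min_active < 1 || min_active > n) {
    stop("min_active must be between 1 and ", n, call. = FALSE)
  }
  out <- list()
  for (size in seq(min_active, n)) {
    sets <- utils::combn(goals, size, simplify = FALSE)
    out <- c(out, sets)
  }
  out
}

#' Sample goal combinations stratified by activated-goal count
#'
#' Cycles over the subset sizes, drawing one not-yet-chosen combination per
#' size per pass, so every size is represented as evenly as the pool allows.
#'
#' @param combinations List of goal-id vectors (e.g. from
#'   [enumerate_goal_combinations()]).
#' @param n_sample Number of combinations to keep.
#' @param seed Sampling seed.
#' @return List of goal-id vectors, ordered by size then draw order.
#' @export
sample_goal_combinations <- function(combinations, n_sample, seed) {
  if (n_sample >= length(combinations)) return(combinations)
  sizes <- lengths(combinations)
  by_size <- split(seq_along(combinations), sizes)
  chosen <- integer(0)
  withr::with_seed(derive_seed(seed, "sample"), {
    pools <- lapply(by_size, function(idx) idx[sample.int(length(idx))])
    while (length(chosen) < n_sample) {
      for (s in seq_along(pools)) {
        if (length(pools[[s]]) > 0 && length(chosen) < n_sample) {
          chosen <- c(chosen, pools[[s]][1])
          pools[[s]] <- pools[[s]][-1]
        }
      }
    }
  })
  combinations[sort(chosen)]
}

#' Run one experiment arm on prepared data
#'
#' Selects a question subset according to the arm — uniformly at random,
#' by cross-validated feature importance treating all activated goals equally
#' (static), or by the two-step personalised pipeline — then refits the
#' multi-target model on the training rows restricted to that subset and
#' evaluates it once on the held-out test rows, reporting per-activated-goal
#' errors in portions per day.
#'
#' @param arm One of `"random"`, `"static"`, `"personalised"`.
#' @param n_features Subset size.
#' @param active Character vector of activated goal ids.
#' @param prep An `ffq_experiment_data` from [prepare_experiment_data()].
#' @param seed Master seed (sub-seeds derived per randomness source).
#' @param config An [experiment_config()].
#' @return A list with `errors` (named per-goal vector, portions/day),
#'   `subset` (question ids) and `weights` (personalised arm only, else
#'   `NULL`).
#' @export
run_arm <- function(arm = c("random", "static", "personalised"),
                    n_features, active, prep, seed,
                    config = experiment_config()) {
  arm <- match.arg(arm)
  stopifnot(inherits(prep, "ffq_experiment_data"))
  check_active(prep$schema, active)
  Y_train <- prep$Y_train[, active, drop = FALSE]
  Y_test <- prep$Y_test[, active, drop = FALSE]
  weights <- NULL
  subset <- switch(
    arm,
    random = select_random_n(prep$schema, n_features,
                             derive_seed(seed, "random",
                                         offset = n_features)),
    static = {
      ranking <- cv_feature_importance(prep$X_train, Y_train,
                                       k = config$k_folds,
                                       seed = derive_seed(seed, "folds"))
      select_top_n(ranking, n_features)
    },
    personalised = {
      ps <- personalised_selection(prep, active, n_features, seed, config)
      weights <- ps$weights
      ps$subset
    }
  )
  model <- fit_mtr(prep$X_train[, subset, drop = FALSE], Y_train)
  errors <- per_goal_test_error(model, prep$X_test[, subset, drop = FALSE],
                                Y_test,
                                subset_params(prep$y_params, active),
                                metric = config$error_metric)
  list(errors = errors, subset = subset, weights = weights)
}

#' Run the full three-arm sweep
#'
#' Full factorial over arms x feature counts x activated-goal combinations x
#' seeds. For each seed a fresh synthetic population is generated (unless
#' `responses` is supplied), split 3:1 and scaled; all arms of a seed share
#' the same split and scaling so they are compared on identical data. A
#' failing cell is recorded as an error row, not raised.
#'
#' @param config An [experiment_config()].
#' @param schema An [ffq_schema]; default [default_schema()].
#' @param responses Optional fixed users x questions matrix used for every
#'   seed; by default [default_population()] responses are simulated per seed.
#' @param verbose Emit per-seed progress messages.
#' @return A tibble with one row per (arm, n_features, active set, seed,
#'   activated goal): columns `arm, n_features, active_set, n_active, seed,
#'   goal, error, weight, status, message`.
#' @export
run_sweep <- function(config = experiment_config(), schema = default_schema(),
                      responses = NULL, verbose = FALSE) {
  combos <- config$goal_combinations
  if (is.null(combos)) {
    all_combos <- enumerate_goal_combinations(goal_ids(schema),
                                              config$min_active)
    combos <- sample_goal_combinations(all_combos, config$n_combinations,
                                       seed = min(config$seeds))
  }
  rows <- vector("list", 0)
  for (seed in config$seeds) {
    if (verbose) message("seed ", seed)
    resp <- responses
    if (is.null(resp)) {
      spec <- default_population(config$n_users, derive_seed(seed, "data"))
      resp <- simulate_responses(spec, schema)
    }
    prep <- prepare_experiment_data(resp, schema, seed,
                                    scaling_scope = config$scaling_scope)
    for (ci in seq_along(combos)) {
      active <- combos[[ci]]
      for (n in config$feature_counts) {
        for (arm in config$arms) {
          rec <- tryCatch({
            res <- run_arm(arm, n, active, prep, seed, config)
            w <- res$weights
            tibble::tibble(
              arm = arm, n_features = n,
              active_set = paste(active, collapse = "+"),
              n_active = length(active), seed = seed,
              goal = names(res$errors),
              error = as.numeric(res$errors),
              weight = if (is.null(w)) NA_real_ else as.numeric(w[names(res$errors)]),
              status = "ok", message = NA_character_)
          }, error = function(e) {
            tibble::tibble(
              arm = arm, n_features = n,
              active_set = paste(active, collapse = "+"),
              n_active = length(active), seed = seed,
              goal = NA_character_, error = NA_real_, weight = NA_real_,
              status = "error", message = conditionMessage(e))
          })
          rows[[length(rows) + 1]] <- rec
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Aggregate sweep errors by activated-goal count
#'
#' Mean error over combinations of the same size, over seeds and over
#' activated goals, keyed by `(arm, n_features, n_active)`.
#'
#' @param result A sweep tibble from [run_sweep()].
#' @return A tibble `arm, n_features, n_active, mean_error, n_cells`.
#' @export
aggregate_by_active_count <- function(result) {
  if (nrow(result) == 0) stop("empty sweep result", call. = FALSE)
  ok <- result[result$status == "ok", , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(ok, .data$arm, .data$n_features, .data$n_active),
    mean_error = mean(.data$error),
    n_cells = dplyr::n(),
    .groups = "drop")
}

#' Per-goal error bar panels for one subset size
#'
#' One panel per activated-goal count, bars per goal coloured by arm —
#' mirroring the per-goal comparison layout of the three selection methods.
#'
#' @param result A sweep tibble from [run_sweep()].
#' @param n_features Which subset size to display.
#' @return A ggplot object.
#' @export
plot_error_by_goal <- function(result, n_features = 9) {
  ok <- result[result$status == "ok" & result$n_features == n_features, ,
               drop = FALSE]
  agg <- dplyr::summarise(
    dplyr::group_by(ok, .data$arm, .data$n_active, .data$goal),
    mean_error = mean(.data$error), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$goal, y = .data$mean_error,
                                    fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~n_active, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "error (portions/day)",
                  title = paste0("Per-goal test error, ", n_features,
                                 " questions shown")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Aggregated error trends by activated-goal count and subset size
#'
#' One panel per arm; lines are subset sizes; the x axis is the number of
#' activated goals.
#'
#' @param aggregate A tibble from [aggregate_by_active_count()].
#' @return A ggplot object.
#' @export
plot_error_trends <- function(aggregate) {
  ggplot2::ggplot(aggregate,
                  ggplot2::aes(x = .data$n_active, y = .data$mean_error,
                               colour = factor(.data$n_features))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "activated goals", y = "mean error (portions/day)",
                  colour = "questions shown") +
    ggplot2::theme_minimal()
}
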