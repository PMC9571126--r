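test_that("goal-combination enumeration matches closed forms and brute force", {
  e3 <- enumerate_goal_combinations(3, 2)
  expect_equal(e3, list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"),
                        c("g1", "g2", "g3")))
  expect_length(enumerate_goal_combinations(11, 11), 1)
  expect_error(enumerate_goal_combinations(5, 0), "min_active")
  # brute-force power-set cross-check for 6 goals
  goals <- paste0("g", 1:6)
  brute <- Filter(function(x) length(x) >= 2,
                  lapply(seq_len(2^6 - 1), function(mask) {
                    goals[bitwAnd(mask, 2^(0:5)) > 0]
                  }))
  e6 <- enumerate_goal_combinations(goals, 2)
  expect_equal(length(e6), length(brute))
  key <- function(l) sort(vapply(l, function(x) paste(sort(x), collapse = "+"), ""))
  expect_equal(key(e6), key(brute))
})

test_that("stratified sampling covers sizes evenly and is deterministic", {
  combos <- enumerate_goal_combinations(11, 2)
  sm <- sample_goal_combinations(combos, 20, seed = 1)
  expect_length(sm, 20)
  expect_identical(sm, sample_goal_combinations(combos, 20, seed = 1))
  # every size 2..11 appears at least once and at most thrice
  tab <- table(lengths(sm))
  expect_setequal(names(tab), as.character(2:11))
  expect_true(all(tab <= 3))
  # asking for more than exist returns everything
  expect_length(sample_goal_combinations(combos[1:5], 99, seed = 1), 5)
})

test_that("with all 24 questions selected the three arms coincide", {
  s <- default_schema_cached()
  resp <- simulate_responses(default_population(300, 2), s)
  prep <- prepare_experiment_data(resp, s, seed = 2)
  active <- c("sugar", "water", "oil")
  rs <- lapply(c("random", "static", "personalised"), run_arm,
               n_features = 24, active = active, prep = prep, seed = 2)
  expect_identical(rs[[1]]$subset, rs[[2]]$subset)
  expect_identical(rs[[2]]$subset, rs[[3]]$subset)
  expect_equal(rs[[1]]$errors, rs[[2]]$errors, tolerance = 1e-10)
  expect_equal(rs[[2]]$errors, rs[[3]]$errors, tolerance = 1e-10)
})

test_that("static arm drives a planted goal's error to zero", {
  # targets equal to single questions: selecting those questions at
  # n = |planted| must give near-zero error
  s <- default_schema_cached()
  resp <- random_responses(400, s, seed = 41)
  # overwrite two goals' contributing questions with single distinct items
  prep <- prepare_experiment_data(resp, s, seed = 41)
  active <- c("water", "oil", "dried_fruit", "sweet_drinks")  # single-question goals
  r <- run_arm("static", 4, active, prep, seed = 41)
  expect_setequal(r$subset, c("water", "olive_oil", "dried_fruit", "sweet_drinks"))
  expect_lt(max(r$errors), 1e-6)
})

test_that("sweep bookkeeping: one record per activated goal per cell", {
  s <- default_schema_cached()
  combos <- list(c("sugar", "water"), c("oil", "milk", "proteins"))
  cfg <- experiment_config(feature_counts = c(4, 12), seeds = 1:2,
                           goal_combinations = combos, n_users = 150)
  res <- run_sweep(cfg, s)
  expect_true(all(res$status == "ok"))
  # 3 arms x 2 counts x 2 seeds x (2 + 3 activated goals) records
  expect_equal(nrow(res), 3 * 2 * 2 * 5)
  expect_true(all(res$error >= 0))
  # personalised rows carry weights; others do not
  expect_true(all(is.na(res$weight[res$arm != "personalised"])))
  expect_true(all(!is.na(res$weight[res$arm == "personalised"])))
  # determinism: identical config reproduces the result exactly
  expect_identical(res, run_sweep(cfg, s))
})

test_that("aggregation by activated-goal count equals a loop oracle", {
  res <- tibble::tibble(
    arm = c("static", "static", "static", "random"),
    n_features = c(4, 4, 4, 4),
    active_set = c("a+b", "a+c", "a+b+c", "a+b"),
    n_active = c(2, 2, 3, 2),
    seed = 1,
    goal = c("a", "a", "a", "a"),
    error = c(0.2, 0.4, 0.5, 0.3),
    weight = NA_real_, status = "ok", message = NA_character_)
  agg <- aggregate_by_active_count(res)
  expect_equal(agg$mean_error[agg$arm == "static" & agg$n_active == 2], 0.3)
  expect_equal(agg$mean_error[agg$arm == "static" & agg$n_active == 3], 0.5)
  expect_equal(agg$mean_error[agg$arm == "random"], 0.3)
  # single record aggregates to itself
  agg1 <- aggregate_by_active_count(res[4, ])
  expect_equal(agg1$mean_error, 0.3)
  expect_error(aggregate_by_active_count(res[0, ]), "empty")
})

test_that("a failing cell becomes an error record, not a crash", {
  s <- default_schema_cached()
  cfg <- experiment_config(feature_counts = c(4, 30),  # 30 > 24 must fail
                           seeds = 1,
                           goal_combinations = list(c("sugar", "water")),
                           n_users = 100)
  res <- run_sweep(cfg, s)
  expect_true(any(res$status == "error"))
  expect_true(any(res$status == "ok"))
  expect_true(all(!is.na(res$message[res$status == "error"])))
})

test_that("sweep plots build without error", {
  s <- default_schema_cached()
  cfg <- experiment_config(feature_counts = c(4, 9), seeds = 1,
                           goal_combinations = list(c("sugar", "water")),
                           n_users = 100)
  res <- run_sweep(cfg, s)
  expect_s3_class(plot_error_by_goal(res, 9), "ggplot")
  expect_s3_class(plot_error_trends(aggregate_by_active_count(res)), "ggplot")
})

test_that("directional trends hold on the default population at default sampling", {
  # default sampling: 60 combinations stratified by size, 10 seeds
  s <- default_schema_cached()
  combos <- sample_goal_combinations(
    enumerate_goal_combinations(goal_ids(s), 2), 60, seed = 1)
  cfg <- experiment_config(goal_combinations = combos, n_users = 1000,
                           seeds = 1:10)
  res <- run_sweep(cfg, s)
  expect_true(all(res$status == "ok"))
  # record count: arms x counts x sum(|active|) x seeds, no silent drops
  expect_equal(nrow(res), 3 * 4 * sum(lengths(combos)) * 10)
  # (a) mean error non-increasing in the number of shown questions, per arm
  by_arm_n <- aggregate(error ~ arm + n_features, data = res, mean)
  for (a in unique(by_arm_n$arm)) {
    curve <- by_arm_n[by_arm_n$arm == a, ]
    curve <- curve[order(curve$n_features), "error"]
    expect_true(all(diff(curve) <= 0))
  }
  # (b) mean error non-decreasing in the number of activated goals
  by_k <- aggregate(error ~ n_active, data = res, mean)
  by_k <- by_k[order(by_k$n_active), ]
  expect_true(all(diff(by_k$error) >= 0))
  # (c) personalised <= static on the maximum-weight goal, on average
  pw <- res[res$arm == "personalised", ]
  pw <- do.call(rbind, lapply(
    split(pw, list(pw$seed, pw$active_set, pw$n_features), drop = TRUE),
    function(d) d[which.max(d$weight), ]))
  st <- res[res$arm == "static", ]
  key <- function(d) paste(d$seed, d$active_set, d$n_features, d$goal)
  match_idx <- match(key(pw), key(st))
  expect_true(mean(pw$error) <= mean(st$error[match_idx]))
})
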