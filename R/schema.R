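#' Construct an FFQ schema
#'
#' An FFQ schema describes the questionnaire structure: the ordered food-item
#' questions, the nutrition goals with their portions-per-day thresholds and
#' threshold directions, and the question-to-goal mapping. Question order is
#' fixed and serves as the tie-breaking order throughout the package.
#'
#' @param questions A data frame with columns `id`, `label`, `portion_unit`.
#' @param goals A data frame with columns `id`, `label`, `threshold`,
#'   `direction` (`"at_least"` or `"at_most"`) and a list-column `questions`
#'   of contributing question ids.
#' @return An object of class `ffq_schema`.
#' @export
ffq_schema <- function(questions, goals) {
  questions <- tibble::as_tibble(questions)
  goals <- tibble::as_tibble(goals)
  schema <- structure(list(questions = questions, goals = goals),
                      class = "ffq_schema")
  validate_schema(schema)
}

validate_schema <- function(schema) {
  q <- schema$questions
  g <- schema$goals
  for (col in c("id", "label", "portion_unit")) {
    if (!col %in% names(q)) stop("questions are missing field '", col, "'",
                                 call. = FALSE)
  }
  for (col in c("id", "label", "threshold", "direction", "questions")) {
    if (!col %in% names(g)) stop("goals are missing field '", col, "'",
                                 call. = FALSE)
  }
  if (anyDuplicated(q$id)) {
    stop("duplicate question id: ",
         paste(unique(q$id[duplicated(q$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(g$id)) {
    stop("duplicate goal id: ",
         paste(unique(g$id[duplicated(g$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(g$threshold)) || any(g$threshold < 0)) {
    stop("goal threshold must be a non-negative number (goal: ",
         paste(g$id[!is.finite(g$threshold) | g$threshold < 0],
               collapse = ", "), ")",
         call. = FALSE)
  }
  bad_dir <- !g$direction %in% c("at_least", "at_most")
  if (any(bad_dir)) {
    stop("invalid direction '", paste(g$direction[bad_dir], collapse = ", "),
         "' (goal: ", paste(g$id[bad_dir], collapse = ", "),
         "); must be 'at_least' or 'at_most'", call. = FALSE)
  }
  for (i in seq_len(nrow(g))) {
    contrib <- g$questions[[i]]
    if (length(contrib) == 0) {
      stop("goal '", g$id[i], "' has no contributing questions", call. = FALSE)
    }
    unknown <- setdiff(contrib, q$id)
    if (length(unknown) > 0) {
      stop("goal '", g$id[i], "' references unknown question id: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  schema
}

#' Load an FFQ schema from a JSON or YAML file
#'
#' The file must contain `questions: [{id, label, portion_unit}]` and
#' `goals: [{id, label, threshold, direction, questions}]`. All schema
#' invariants (unique ids, known question references, non-negative
#' thresholds, valid direction tokens) are checked on load.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated [ffq_schema] object.
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (is.null(raw$questions) || is.null(raw$goals)) {
    stop("schema file must contain 'questions' and 'goals'", call. = FALSE)
  }
  field <- function(rec, nm, id) {
    if (is.null(rec[[nm]])) {
      stop("missing field '", nm, "' in schema entry '", id %||% "?", "'",
           call. = FALSE)
    }
    rec[[nm]]
  }
  questions <- tibble::tibble(
    id = vapply(raw$questions, function(r) as.character(field(r, "id", r$id)), ""),
    label = vapply(raw$questions, function(r) as.character(field(r, "label", r$id)), ""),
    portion_unit = vapply(raw$questions,
                          function(r) as.character(r$portion_unit %||% "portions/day"), "")
  )
  goals <- tibble::tibble(
    id = vapply(raw$goals, function(r) as.character(field(r, "id", r$id)), ""),
    label = vapply(raw$goals, function(r) as.character(field(r, "label", r$id)), ""),
    threshold = vapply(raw$goals, function(r) as.numeric(field(r, "threshold", r$id)), 0),
    direction = vapply(raw$goals, function(r) as.character(field(r, "direction", r$id)), ""),
    questions = lapply(raw$goals,
                       function(r) unname(vapply(field(r, "questions", r$id),
                                                 as.character, "")))
  )
  ffq_schema(questions, goals)
}

#' The default 24-question, 11-goal Mediterranean-diet FFQ schema
#'
#' Loads the schema bundled with the package: 24 food-item questions answered
#' in portions per day and 11 nutrition goals (fruit & vegetables,
#' carbohydrates, proteins, milk, oil, water, dried fruit, processed meats,
#' sweets/snacks, sweet drinks, sugar). The question-to-goal mapping and the
#' per-goal thresholds are editable configuration, not measured reference
#' values; override them by editing a copy of the bundled JSON file.
#'
#' @return A validated [ffq_schema] object.
#' @export
default_schema <- function() {
  load_schema(system.file("extdata", "ffq_schema.json", package = "ffqreduce"))
}

#' @export
print.ffq_schema <- function(x, ...) {
  cat("FFQ schema:", nrow(x$questions), "questions,",
      nrow(x$goals), "goals\n")
  invisible(x)
}

#' Question and goal ids in schema order
#'
#' @param schema An [ffq_schema].
#' @return Character vector of ids in schema (tie-breaking) order.
#' @export
question_ids <- function(schema) schema$questions$id

#' @rdname question_ids
#' @export
goal_ids <- function(schema) schema$goals$id

#' Question-to-goal mapping matrix
#'
#' @param schema An [ffq_schema].
#' @return A |questions| x |goals| 0/1 matrix; entry (q, g) is 1 when
#'   question q contributes to goal g.
#' @export
goal_mapping_matrix <- function(schema) {
  q <- question_ids(schema)
  g <- goal_ids(schema)
  M <- matrix(0, nrow = length(q), ncol = length(g), dimnames = list(q, g))
  for (i in seq_along(g)) {
    M[schema$goals$questions[[i]], i] <- 1
  }
  M
}

#' Signed threshold adjustments for a set of goals
#'
#' Encodes the threshold direction as the sign convention used by the
#' threshold-distance computation: `at_most` goals get +1 (violated when the
#' score over-reaches the threshold), `at_least` goals get -1 (violated when
#' the score falls short).
#'
#' @param schema An [ffq_schema].
#' @param goals Character vector of goal ids (default: all).
#' @return Named numeric vector of -1/+1 values.
#' @export
goal_adjustments <- function(schema, goals = goal_ids(schema)) {
  idx <- match(goals, schema$goals$id)
  if (anyNA(idx)) {
    stop("unknown goal id: ", paste(goals[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(ifelse(schema$goals$direction[idx] == "at_most", 1, -1),
                  goals)
}

#' Per-goal thresholds in portions per day
#'
#' @inheritParams goal_adjustments
#' @return Named numeric vector of thresholds.
#' @export
goal_thresholds <- function(schema, goals = goal_ids(schema)) {
  idx <- match(goals, schema$goals$id)
  if (anyNA(idx)) {
    stop("unknown goal id: ", paste(goals[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(schema$goals$threshold[idx], goals)
}

#' Compute goal quality scores from questionnaire responses
#'
#' The quality score of a goal is the unweighted sum of the portions-per-day
#' answers of its contributing questions, which keeps scores on the same
#' portions-per-day scale as the answers.
#'
#' @param responses A users x questions numeric matrix (portions/day,
#'   non-negative) with question ids as column names, e.g. from
#'   [simulate_responses()] or [read_responses()].
#' @param schema An [ffq_schema].
#' @return A users x goals matrix of quality scores; row names carry over.
#' @export
compute_quality_scores <- function(responses, schema) {
  assert_matrix(responses, "responses")
  q <- question_ids(schema)
  if (ncol(responses) != length(q)) {
    stop("responses have ", ncol(responses), " columns; schema has ",
         length(q), " questions", call. = FALSE)
  }
  if (!is.null(colnames(responses)) && !identical(colnames(responses), q)) {
    if (!setequal(colnames(responses), q)) {
      stop("response columns do not match schema question ids", call. = FALSE)
    }
    responses <- responses[, q, drop = FALSE]
  }
  responses %*% goal_mapping_matrix(schema)
}

#' Read a response table from CSV
#'
#' Expects a `user_id` first column followed by one column per schema
#' question (portions/day). Completeness and non-negativity are enforced.
#'
#' @param path CSV file path.
#' @param schema An [ffq_schema].
#' @return A users x questions matrix with user ids as row names.
#' @export
read_responses <- function(path, schema) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"user_id" %in% names(df)) {
    stop("response CSV must have a 'user_id' column", call. = FALSE)
  }
  q <- question_ids(schema)
  missing <- setdiff(q, names(df))
  if (length(missing) > 0) {
    stop("response CSV is missing question columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, q, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$user_id)
  if (anyNA(m)) stop("response table contains missing values", call. = FALSE)
  if (any(m < 0)) stop("response values must be non-negative", call. = FALSE)
  m
}

#' Write a response table to CSV
#'
#' @param responses A users x questions matrix (row names = user ids).
#' @param path Output CSV path.
#' @export
write_responses <- function(responses, path) {
  df <- data.frame(user_id = rownames(responses) %||%
                     as.character(seq_len(nrow(responses))),
                   responses, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
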