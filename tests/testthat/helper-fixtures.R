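# Shared fixtures: built in code at test time, no stored data.

default_schema_cached <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- default_schema()
    s
  }
})

# A tiny hand-rolled 3-question / 2-goal schema for unit tests.
toy_schema <- function() {
  ffq_schema(
    questions = tibble::tibble(
      id = c("fruit", "vegetables", "sugar"),
      label = c("Fruit", "Vegetables", "Sugar"),
      portion_unit = "portions/day"),
    goals = tibble::tibble(
      id = c("fruit_veg", "sugar"),
      label = c("Fruit and vegetables", "Sugar"),
      threshold = c(5, 2),
      direction = c("at_least", "at_most"),
      questions = list(c("fruit", "vegetables"), "sugar"))
  )
}

# Write a schema list to a temp JSON file and return the path.
write_schema_json <- function(lst) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(lst, path, auto_unbox = TRUE)
  path
}

# Random response-like matrix with question-id column names.
random_responses <- function(n, schema, seed = 1) {
  q <- ffqreduce:::question_ids(schema)
  withr::with_seed(seed, {
    m <- matrix(runif(n * length(q), 0, 4), nrow = n,
                dimnames = list(NULL, q))
  })
  m
}

# Planted-structure dataset: each target is a noiseless copy of one question.
# Non-planted questions are independent noise.
planted_data <- function(n = 400, planted = c(3, 7, 11), n_q = 24, seed = 5) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * n_q), nrow = n,
                dimnames = list(NULL, paste0("q", seq_len(n_q))))
  })
  Y <- X[, planted, drop = FALSE]
  colnames(Y) <- paste0("t", seq_along(planted))
  list(X = X, Y = Y, planted = planted)
}
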