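#' Derive a stream-specific sub-seed from a master seed
#'
#' One master seed drives the whole experiment; the generator, the train/test
#' split, the cross-validation folds and the random-arm draw each get their own
#' derived sub-seed so the three arms are compared on identical splits while
#' their independent random choices do not collide.
#'
#' @param seed Master seed (integer).
#' @param stream One of `"data"`, `"split"`, `"folds"`, `"random"`,
#'   `"sample"`, `"profile"`.
#' @param offset Optional extra integer offset (used e.g. to vary the
#'   random-arm draw with the feature count).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream, offset = 0L) {
  streams <- c(data = 1, split = 2, folds = 3, random = 4, sample = 5,
               profile = 6)
  if (!stream %in% names(streams)) {
    stop("unknown seed stream: ", stream, call. = FALSE)
  }
  s <- (as.numeric(seed) %% 1048576) * 1021 +
    streams[[stream]] * 7919 + as.numeric(offset) * 131
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  invisible(x)
}
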