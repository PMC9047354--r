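#' Derive a reproducible child seed from a top-level seed
#'
#' One top-level seed fans out to per-stage child seeds so that each pipeline
#' stage (simulation, splitting, model fitting, ...) can be re-run in
#' isolation and still reproduce its part of a full run. The derivation is a
#' fixed integer hash of the stage name folded into the parent seed; it is
#' deterministic and keeps the result inside the 32-bit positive integer
#' range that `set.seed()` accepts.
#'
#' @param seed parent integer seed.
#' @param stage character scalar naming the stage (e.g. `"simulate"`).
#' @param index optional integer, for per-iteration seeds within a stage.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # fold with distinct primes; keep strictly inside [1, 2^31 - 2]
  x <- (abs(seed) %% 2147483647) * 48271 + h * 7919 + index * 104729
  as.integer(x %% 2147483629 + 1)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate that a value is a single fraction in [0, 1]
#' @noRd
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' @noRd
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}
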