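#' Derive a child seed from a parent seed and integer tags
#'
#' Deterministic integer mixing used to give every subject, channel and
#' cross-validation fold its own reproducible RNG stream. The result is
#' always a non-negative integer below 2^31, safe for [set.seed()].
#'
#' @param ... integer scalars: a parent seed followed by any number of tags
#'   (subject index, channel index, fold index, ...).
#' @return a single integer seed.
#' @export
mix_seed <- function(...) {
  vals <- c(...)
  stopifnot(length(vals) >= 1, all(is.finite(vals)))
  m <- 2147483629 # largest prime below 2^31; keeps products < 2^53 in doubles
  s <- 0
  for (v in vals) {
    s <- (s * 69069 + (abs(round(v)) %% m) + 1) %% m
  }
  as.integer(s)
}

# internal: stop with a consistent message for invalid arguments
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE) {
  check_that(is.numeric(x) && length(x) == 1 && is.finite(x),
             sprintf("'%s' must be a finite numeric scalar", name))
  if (positive) check_that(x > 0, sprintf("'%s' must be > 0", name))
  if (nonneg) check_that(x >= 0, sprintf("'%s' must be >= 0", name))
  if (integerish) check_that(abs(x - round(x)) < 1e-8,
                             sprintf("'%s' must be a whole number", name))
  invisible(TRUE)
}
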