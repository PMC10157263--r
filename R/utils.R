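#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a global seed
#'
#' All randomness in the package flows from one user-supplied integer seed.
#' Independent stages draw from sub-streams obtained by adding a fixed,
#' documented offset, keeping every derived seed inside the 32-bit integer
#' range.
#'
#' @param seed integer global seed.
#' @param offset fixed non-negative integer offset identifying the sub-stream.
#' @return an integer seed usable with [set.seed()].
#' @export
substream_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483629)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  as.numeric(x)
}
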