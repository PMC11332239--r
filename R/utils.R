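# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for an independent random stream
#'
#' Sub-generators (taxonomy, images, ratings, ...) each draw from their own
#' stream so that, e.g., adding photos to a scenario does not perturb the
#' taxonomy. The derived seed stays below 2^31 - 1.
#'
#' @param seed Base integer seed.
#' @param stream Stream name (character) or small integer offset.
#' @return An integer seed.
#' @keywords internal
sub_seed <- function(seed, stream) {
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  as.integer((abs(as.numeric(seed)) * 2654435 + as.numeric(stream) * 97) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Largest-remainder integer apportionment
#'
#' Splits `n` units across categories proportionally to `p` so that the counts
#' are integers summing exactly to `n` and each count is within one unit of
#' `n * p`.
#'
#' @param n Total count.
#' @param p Non-negative weights (normalised internally).
#' @return Integer vector of counts, same length and names as `p`.
#' @keywords internal
apportion <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  exact <- n * p
  k <- floor(exact)
  rem <- n - sum(k)
  if (rem > 0) {
    # ties broken by index for determinism
    ord <- order(exact - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(k), names(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
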