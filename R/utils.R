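#' Derive a reproducible sub-seed for a pipeline stage
#'
#' All randomness in a run flows from one master seed. Each stage (and each
#' field within a stage) draws from its own stream, seeded by a deterministic
#' hash of the master seed, the stage name and an index. This lets any stage
#' be re-run in isolation while reproducing the exact stream it saw inside a
#' full run.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label, e.g. `"simulate"`.
#' @param index Non-negative integer distinguishing units within a stage.
#' @return A positive integer below 2^31.
#' @export
subseed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # double-precision arithmetic stays exact below 2^53
  x <- (abs(seed) %% 2147483647) * 40503 + (h %% 65521) * 69621 + index * 7919
  as.integer(x %% 2147483629) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Pixel offsets of a centred digital disc
#'
#' @param r_px Integer radius in pixels.
#' @return Two-column matrix of (dy, dx) offsets with dy^2 + dx^2 <= r_px^2.
#' @keywords internal
disc_offsets <- function(r_px) {
  g <- seq(-r_px, r_px)
  dd <- expand.grid(dy = g, dx = g)
  as.matrix(dd[dd$dy^2 + dd$dx^2 <= r_px^2, , drop = FALSE])
}

# stop with a classed condition so callers can test error categories
poldep_abort <- function(message, class) {
  abort(message, class = c(class, "poldep_error"))
}
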