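#' @keywords internal
"_PACKAGE"

# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Deterministic child seed
#'
#' Derives a reproducible per-unit seed (e.g. per shoal, per fish) from
#' a base seed and an index, kept within the 32-bit integer range.
#' Used throughout the pipeline so that one base seed determines every
#' stochastic component.
#'
#' @param seed base seed (integer).
#' @param k unit index (integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("shoalkin_invalid_input", "shoalkin_error")))
}

stop_no_cycle <- function(msg = "no cycle detected in tail-tip signal") {
  stop(errorCondition(msg, class = c("shoalkin_no_cycle", "shoalkin_error")))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stop_invalid("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_invalid("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Centered running mean with odd window, edges handled by shrinking the
# window symmetrically; a zero-phase low-pass used on oscillation signals.
running_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < 3L) return(x)
  half <- width %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  w <- pmin(seq_len(n) - lo, hi - seq_len(n))
  lo <- seq_len(n) - w
  hi <- seq_len(n) + w
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
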