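#' @keywords internal
"_PACKAGE"

# Argument validation helpers. All user-facing errors go through these so the
# condition classes are stable for callers and for the CLI exit-code mapping.

stop_invalid <- function(msg, class = "ivcmad_invalid_argument") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_flag <- function(cond, msg) {
  if (!isTRUE(cond)) stop_invalid(msg)
  invisible(TRUE)
}

check_count <- function(x, min = 0L, name = deparse(substitute(x))) {
  check_flag(is.numeric(x) && length(x) == 1L && is.finite(x) &&
               x == trunc(x) && x >= min,
             sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the base RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so package functions never leak global RNG state.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Counter-based substream derivation: every image / epoch / step gets its own
# seed as a pure function of (master seed, stream labels), so no generator
# state is shared across objects. Knuth multiplicative hashing mod 2^31 - 1,
# with the product split into 16-bit halves so every intermediate stays well
# below 2^53 and no double-precision rounding can drop a component.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  k <- 506952114            # 2654435761 mod m
  mulmod <- function(a, b) {
    hi <- b %/% 65536
    lo <- b %% 65536
    (((a * hi) %% m) * 65536 + a * lo) %% m
  }
  h <- 0
  for (p in c(seed, ...)) {
    h <- (mulmod(h, k) + (as.numeric(p) %% m)) %% m
  }
  as.integer(h)
}

# Clip numeric values into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero (text reports use 3 decimals in this convention).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
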