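#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Run code under a fixed RNG state, restoring the caller's state afterwards.
# Seeds derived from a user seed stay below 2^31 - 1.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483646L))
  }
  force(code)
}

# Derive a reproducible sub-seed from a master seed and a fixed stream offset.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric comparison tolerance used for cost equality throughout the DP and
# backtracking (integer-valued schemes are exact in double arithmetic).
COST_TOL <- 1e-9

near <- function(a, b, tol = COST_TOL) {
  (is.infinite(a) & is.infinite(b) & sign(a) == sign(b)) | abs(a - b) <= tol
}
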