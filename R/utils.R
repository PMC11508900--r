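# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats predict
#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic steps in the package go through
# this so a single root seed makes a whole run reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation: one root seed fans out into named
# stream seeds (pseudo-absences, splits, model fits, shuffles) so stages
# stay independent of each other's consumption of random numbers.
# Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629) + 1L
}

# Round-half-up, used for the evaluation-fraction point counts.
round_half_up <- function(x) floor(x + 0.5)

clamp01 <- function(x) pmin(1, pmax(0, x))

# Linear-interpolation quantile (type 7), named for clarity at call sites.
interp_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x) && x >= 0
}

#' Earth radius used throughout the package
#'
#' Mean Earth radius (IUGG), in kilometres. All geodesic computations —
#' cell areas, centroid step distances — use this single constant.
#' @export
EARTH_RADIUS_KM <- 6371.0088
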