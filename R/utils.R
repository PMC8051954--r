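#' @importFrom stats median quantile rbinom rhyper rmultinom rpois runif setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom rlang .data
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
# All seeded entry points funnel through here so a single integer reproduces
# any simulation or subsampling bit-identically.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# stopifnot() with a formatted message
check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# linear-interpolation quantile (type 7); stated because quantile
# conventions differ across ecosystems
q_interp <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

# median that treats an empty set as 0 (used for the negative fraction
# of a marker with no negative cells)
median0 <- function(x) if (length(x) == 0L) 0 else stats::median(x)
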