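# internal helpers shared across modules

torc_stop <- function(..., class = "torc_error") {
  stop(structure(
    class = c(class, "torc_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so package functions never clobber a user's random
#' stream.
#' @noRd
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
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic child seeds from one root seed; keeps values < 2^31 so they
# are representable as R integers.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= 1
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
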