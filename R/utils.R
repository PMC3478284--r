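# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
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
  force(code)
}

# Normal draws truncated at zero (rejection sampling; the truncated mass is
# tiny for the dispersions used here, cv < 0.5).
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal rejection sampling failed")
  }
  x
}

# scalar checks -------------------------------------------------------------

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_number <- function(x, name, positive = FALSE) {
  if (!is_number(x)) stop(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
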