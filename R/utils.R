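# internal helpers

#' @keywords internal
"_PACKAGE"

# Run code with a local RNG state: seeds the generator, restores the caller's
# .Random.seed on exit so library functions never disturb user-level RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Derive a deterministic sub-seed below 2^31 from a base seed and a stage tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

check_prob <- function(p, what) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop(sprintf("%s must lie in [0, 1]; offending value(s): %s",
                 what, paste(format(p[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
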