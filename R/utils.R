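#' @useDynLib graphburden, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic per-purpose seed derivation. A master seed plus a counter (and
# an optional text tag) yields distinct 31-bit seeds; the multiplier is odd so
# the map i -> seed is injective mod 2^31.
derive_seed <- function(master, counter = 0L, tag = "") {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  if (nzchar(tag)) {
    for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  }
  s <- (abs(master) + 1664525 * (counter + 1) + h) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
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
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rolling hash of a character vector, hex-encoded; used for manifests so a
# randomized ensemble can be traced back to its source network.
text_checksum <- function(x) {
  h <- 0
  for (s in x) {
    for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
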