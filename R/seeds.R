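#' Derive a reproducible sub-stream seed
#'
#' All randomness in the synthetic generators flows from one integer seed
#' through named sub-streams (e.g. "sequence", "coordinates", "counts"), so
#' that adding a generator does not perturb existing streams. The derived
#' seed is a deterministic 31-bit hash of `(seed, name)`.
#'
#' @param seed master integer seed
#' @param name sub-stream name
#' @return an integer in `[1, 2^31 - 2]`
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  M <- 2147483647 # 2^31 - 1 (prime)
  h <- 17
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% M
  s <- (h * 48271) %% M
  s <- (s + (abs(seed) %% M)) %% M
  s <- (s * 69621) %% M
  as.integer(s %% (M - 1L) + 1L)
}

# Run code under a named sub-stream without disturbing the caller's RNG.
with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(code)
}
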