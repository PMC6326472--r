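#' Derive a child seed from a parent seed and a key
#'
#' All randomness in the package flows from a single integer seed through
#' this counter-based splitting scheme: each stochastic sub-task derives its
#' own seed from the run seed plus a string/integer key, so stages can be
#' re-run independently and reproducibly.
#'
#' @param seed integer parent seed.
#' @param ... keys (strings or integers) identifying the sub-stream.
#' @return an integer in [0, 2^31 - 2], suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(as.character(seed), vapply(list(...), as.character, ""))
  h <- 5381
  m <- 2147483647  # 2^31 - 1, keeps every derived seed a valid R integer
  for (key in keys) {
    for (b in utf8ToInt(key)) {
      h <- (h * 33 + b) %% m
    }
    h <- (h * 33 + 7) %% m
  }
  as.integer(h)
}

# run code under a derived seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
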