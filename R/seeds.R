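#' Derive a stage seed from a run seed
#'
#' Stable integer hash of `(seed, stage)` so that each pipeline stage draws
#' from an independent stream while the whole run stays a pure function of
#' one top-level seed. The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer run seed.
#' @param stage character scalar naming the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 131 + c) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

# evaluate `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
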