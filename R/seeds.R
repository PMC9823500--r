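#' Derive a reproducible sub-seed from a base seed and a label path
#'
#' Experiments expand one user-facing seed into independent sub-seeds, one
#' per randomness consumer (identity draws, per-block jitter, negative
#' sampling, fold assignment, ...). The mapping is a stable polynomial hash
#' of the label path, so adding a new consumer never perturbs the streams of
#' existing ones, and the same `(seed, ...)` pair always yields the same
#' sub-seed on every platform.
#'
#' @param seed integer base seed.
#' @param ... labels (character or numeric scalars) identifying the consumer.
#' @return an integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "negatives", "user03")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double arithmetic
  h <- as.numeric(seed) %% m
  for (tok in list(...)) {
    for (b in utf8ToInt(paste0("/", as.character(tok)))) {
      h <- (h * 31 + b) %% m
    }
  }
  as.integer(h)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
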