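# Keyed RNG streams: every stochastic stage derives its own 31-bit seed from the
# root seed plus integer keys (stage, fold, repeat, size, replicate), so any
# replicate can be re-run in isolation and replicates are order-independent.

MODULUS <- 2147483647  # 2^31 - 1, Mersenne prime; products stay exact in doubles

.stage_ids <- c(
  pools = 1L, subset = 2L, null = 3L, split = 4L, data = 5L, labels = 6L,
  noise = 7L, loo = 8L, trial = 9L
)

#' Derive a child seed from a root seed and integer keys
#'
#' Mixes the root seed with a stage name and any number of integer keys through
#' a multiplicative-congruential hash, returning a seed in `[1, 2^31 - 2]`.
#' Used throughout the resampling engines so that every (fold, repeat, size,
#' replicate) combination owns an independent, reproducible RNG stream.
#'
#' @param root integer root seed.
#' @param stage character stage label (e.g. `"pools"`, `"subset"`, `"null"`).
#' @param ... additional integer keys, e.g. fold, repeat, size, replicate.
#' @return a single integer seed.
#' @export
child_seed <- function(root, stage, ...) {
  stage_id <- .stage_ids[[stage]]
  if (is.null(stage_id)) stage_id <- sum(utf8ToInt(stage)) %% MODULUS
  keys <- c(stage_id, as.numeric(c(...)))
  s <- (abs(as.numeric(root)) %% MODULUS)
  for (k in keys) {
    s <- (s * 48271) %% MODULUS
    s <- (s + (abs(k) %% MODULUS) + 1) %% MODULUS
  }
  as.integer(s %% (MODULUS - 1) + 1)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
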