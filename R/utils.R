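# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Stages of the pipeline draw their randomness from sub-seeds derived
#' deterministically from one master seed, so that a stage can be re-run in
#' isolation and still reproduce the full-pipeline result. The scheme is a
#' fixed affine hash modulo a prime below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. "simulate", "scan") or an integer.
#' @param index integer counter (e.g. participant number), default 0.
#' @return a single integer seed in [0, 2^31).
#' @export
derive_seed <- function(master, stage = 0L, index = 0L) {
  stage_id <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 7919
  } else as.integer(stage)
  as.integer((as.numeric(master) %% 2147483587 * 48271 +
                104729 * stage_id + 7919 * as.numeric(index)) %% 2147483587)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
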