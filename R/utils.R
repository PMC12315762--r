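# Seeding and small numeric helpers shared across modules.

#' Derive a reproducible integer seed from arbitrary labels
#'
#' Hashes the string representation of its arguments (polynomial rolling hash
#' mod 2^31 - 1) so that every cell, split, and permutation of a run draws
#' from its own deterministic stream. Results are therefore independent of
#' evaluation order and of how work is scheduled.
#'
#' @param ... labels (coerced to character) identifying the stream, e.g.
#'   master seed, subject id, ROI id, target, stage.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "sub01", 17, "rt")
derive_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "\x1f")
  h <- 7
  m <- 2147483647
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

# Clip correlations away from +/-1 so atanh stays finite.
clip_r <- function(r, eps = 1e-12) pmin(pmax(r, -1 + eps), 1 - eps)

# Pearson correlation returning NA (silently) when either side is constant.
safe_cor <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  sx <- sd(x); sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  cor(x, y)
}

`%||%` <- rlang::`%||%`
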