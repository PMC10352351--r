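## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Deterministic per-stage seed derivation: one user seed drives every
## stochastic stage through an independent substream keyed by a stage string,
## so adding a stage never perturbs the draws of earlier stages.
stage_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483647L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

## Evaluate expr with a local RNG state seeded at `seed`; the caller's
## .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Column variances with the n-1 denominator, without forming apply() loops.
col_vars <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

## Dense matrix from possibly sparse input.
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

fr_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
fr_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
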