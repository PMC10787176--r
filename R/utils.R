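`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific RNG seed from a global seed
#'
#' All randomness in the package flows through explicitly seeded generators.
#' One global seed fans out to per-stage seeds by hashing the stage label so
#' that stages are independently reproducible and no stage consumes
#' wall-clock entropy.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label, e.g. `"genome"`, `"bootstrap"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% (.Machine$integer.max - 1L))
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards
# so library functions never disturb user-level reproducibility.
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

# Nearest-rank empirical percentile: the k-th order statistic with
# k = ceiling(p * n). Used for bootstrap CI bounds so results are
# bit-reproducible across implementations.
nearest_rank <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  x[pmin(pmax(ceiling(p * n), 1L), n)]
}

xd_log <- function(...) message("[xdosage] ", ...)
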