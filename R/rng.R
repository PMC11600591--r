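#' Derive a reproducible sub-seed from a run seed and an operation name
#'
#' All stochastic stages fork one global seed per run by operation name, so
#' adding a new stage never perturbs the draws of earlier ones. The derived
#' seed is a deterministic 31-bit hash of `(seed, name)`.
#'
#' @param seed Integer run seed.
#' @param name Character scalar naming the operation (e.g. `"simulate_cne_set"`).
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name), length(name) == 1L)
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  s <- (abs(as.numeric(seed)) %% m)
  out <- (s * 48271 + h) %% m
  as.integer(max(1, out))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
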