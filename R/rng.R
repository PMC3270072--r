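#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All randomness in the package flows through R's global RNG, so a single
#' `set.seed()` makes any call reproducible. Experiment runners additionally
#' partition one master seed into independent named streams, so that adding an
#' experiment (or another network size) never perturbs the draws of an
#' existing one. The derivation hashes the label into `[0, 2^31 - 2]` and
#' offsets the master seed by it, modulo the same range.
#'
#' @param seed Integer master seed.
#' @param label Character scalar naming the stream, e.g. `"mating:n=15"`.
#' @return An integer seed suitable for `set.seed()`.
#' @examples
#' derive_seed(1, "viability:n=15")
#' @export
derive_seed <- function(seed, label) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    abort("`seed` must be a single integer.")
  if (!is.character(label) || length(label) != 1)
    abort("`label` must be a single string.")
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m + h) %% m)
}

with_stream <- function(seed, label, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, label))
  force(expr)
}
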