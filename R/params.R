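#' Developmental model parameters
#'
#' Bundles the constants of the developmental dynamics: the sigmoid curvature
#' `a`, the averaging window `tau` of the convergence statistic, the stability
#' threshold `sigma`, the step cutoff `l_max` after which a network is
#' considered unstable, and the minimum expression variance `min_var` a
#' converged state must show to count as viable.
#'
#' The defaults (`a = 1.5`, `tau = 10`, `sigma = 1e-4`, `l_max = 100`,
#' `min_var = 0.1`) define the continuous-output regime: with curvature
#' between 1 and 2 the stable expression levels spread over the whole (-1, 1)
#' interval. Curvature around 100 saturates the sigmoid so that expression
#' levels are effectively forced to -1 or +1, recovering a discrete-output
#' model; [dov_params()] is a shorthand for that regime.
#'
#' `min_var` guards against trivial stability: the origin is always a fixed
#' point of the dynamics (f(0) = 0), and small random networks collapse to it
#' very often, so bare convergence would call almost every small network
#' viable. Requiring the stable state's gene-product levels to have variance
#' of at least 0.1 restricts viability to individuals that actually express a
#' pattern; set `min_var = 0` to study bare convergence.
#'
#' @param a Positive sigmoid curvature. 1.5 gives continuous output (COV);
#'   values of roughly 100 and above give discrete output (DOV).
#' @param tau Positive integer averaging window: the convergence statistic is
#'   computed over the most recent `tau + 1` states.
#' @param sigma Positive stability threshold on the convergence statistic.
#' @param l_max Positive integer cutoff on the number of developmental steps.
#' @param min_var Non-negative minimum variance of the stable expression
#'   levels for viability (0 disables the requirement).
#'
#' @return An object of class `grn_params` (a named list with elements `a`,
#'   `tau`, `sigma`, `l_max`, `min_var`).
#' @examples
#' model_params()
#' dov_params() # discrete-output regime, a = 100
#' @export
model_params <- function(a = 1.5, tau = 10, sigma = 1e-4, l_max = 100,
                         min_var = 0.1) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    abort("`a` must be a single positive finite number.")
  if (!is.numeric(tau) || length(tau) != 1 || tau < 1 || tau != round(tau))
    abort("`tau` must be a positive integer.")
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    abort("`sigma` must be a single positive finite number.")
  if (!is.numeric(l_max) || length(l_max) != 1 || l_max < 1 || l_max != round(l_max))
    abort("`l_max` must be a positive integer.")
  if (l_max < tau)
    abort("`l_max` must be at least `tau`, otherwise no convergence window ever fills.")
  if (!is.numeric(min_var) || length(min_var) != 1 || !is.finite(min_var) ||
      min_var < 0)
    abort("`min_var` must be a single non-negative number.")
  structure(
    list(a = as.numeric(a), tau = as.integer(tau), sigma = as.numeric(sigma),
         l_max = as.integer(l_max), min_var = as.numeric(min_var)),
    class = "grn_params"
  )
}

#' @rdname model_params
#' @export
dov_params <- function(a = 100, tau = 10, sigma = 1e-4, l_max = 100,
                       min_var = 0.1) {
  model_params(a = a, tau = tau, sigma = sigma, l_max = l_max,
               min_var = min_var)
}

#' @export
print.grn_params <- function(x, ...) {
  regime <- if (x$a >= 100) "discrete-output (DOV)" else
    if (x$a <= 2) "continuous-output (COV)" else "intermediate"
  cat(sprintf("<grn_params> a = %g (%s), tau = %d, sigma = %g, l_max = %d, min_var = %g\n",
              x$a, regime, x$tau, x$sigma, x$l_max, x$min_var))
  invisible(x)
}

as_grn_params <- function(params) {
  if (inherits(params, "grn_params")) return(params)
  if (is.list(params)) return(do.call(model_params, params))
  abort("`params` must be a `grn_params` object (see `model_params()`).")
}
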