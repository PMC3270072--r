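check_network <- function(w) {
  if (!is.matrix(w) || !is.numeric(w))
    abort("A network must be a numeric matrix.")
  if (nrow(w) != ncol(w) || nrow(w) < 1)
    abort(sprintf("A network must be square with n >= 1 (got %d x %d).",
                  nrow(w), ncol(w)))
  if (any(!is.finite(w)))
    abort("Network entries must all be finite.")
  if (any(w < -1 | w > 1))
    abort("Network entries must lie in [-1, 1].")
  invisible(w)
}

check_state <- function(s, n = NULL) {
  if (!is.numeric(s) || length(s) < 1)
    abort("A state vector must be a non-empty numeric vector.")
  if (any(!is.finite(s)))
    abort("State elements must all be finite.")
  if (!is.null(n) && length(s) != n)
    abort(sprintf("State length %d does not match network size %d.",
                  length(s), n))
  invisible(s)
}

#' Sigmoidal expression scaling
#'
#' The bounding function of the developmental map,
#' `f(x) = 2 / (1 + exp(-a x)) - 1`, applied element-wise. It is odd, strictly
#' increasing, centred at 0, and maps the real line into (-1, 1); the
#' curvature `a` controls how sharply values saturate (a = 1.5 keeps stable
#' expression levels continuous, a = 100 pushes them to effectively +-1).
#'
#' @param x Numeric vector of unscaled regulatory inputs (finite).
#' @param a Positive sigmoid curvature.
#' @return Numeric vector of the same length with elements in (-1, 1).
#' @examples
#' sigmoid_scale(0, 1.5)      # exactly 0
#' sigmoid_scale(1, 1.5)      # 2 / (1 + exp(-1.5)) - 1
#' sigmoid_scale(5, 100)      # saturates at ~1
#' @export
sigmoid_scale <- function(x, a = 1.5) {
  if (!is.numeric(x) || any(!is.finite(x)))
    abort("`x` must be numeric and finite.")
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    abort("`a` must be a single positive number.")
  .sigmoid_scale_cpp(as.numeric(x), a)
}

#' One developmental step
#'
#' Applies the update S(t+1) = f(W S(t)): each gene's new expression level is
#' the sigmoid-scaled weighted sum of the current levels of all its
#' regulators, with weights taken from the gene's row of `w`.
#'
#' @param w Square numeric interaction matrix with entries in `[-1, 1]`; entry
#'   `w[i, j]` is the effect of gene `j` on gene `i`.
#' @param s Numeric expression state of length `nrow(w)`.
#' @param params A [model_params()] object (only `a` is used here).
#' @return The next state: numeric vector with elements in (-1, 1).
#' @examples
#' w <- matrix(0, 3, 3)
#' develop_step(w, c(1, -1, 0.5)) # zero matrix collapses to the origin
#' @export
develop_step <- function(w, s, params = model_params()) {
  params <- as_grn_params(params)
  check_network(w)
  check_state(s, nrow(w))
  .sigmoid_scale_cpp(as.numeric(w %*% s), params$a)
}

#' Distance between two expression states
#'
#' `D(X, Y) = sum((x_i - y_i)^2) / (4 n)`, normalised so that any two states
#' with elements in `[-1, 1]` are at most distance 1 apart (attained by the
#' all-ones versus all-minus-ones pair).
#'
#' @param x,y Numeric vectors of equal length with finite elements.
#' @return A single number in `[0, 1]` for states within `[-1, 1]`.
#' @examples
#' state_distance(c(1, 0, -1), c(0, 0, 0)) # 1/6
#' @export
state_distance <- function(x, y) {
  check_state(x)
  check_state(y)
  if (length(x) != length(y))
    abort(sprintf("State lengths differ (%d vs %d).", length(x), length(y)))
  sum((x - y)^2) / (4 * length(x))
}

#' Windowed convergence statistic
#'
#' The variance-like statistic that decides stability: given the `tau + 1`
#' most recent states S(t-tau), ..., S(t), it averages the distance
#' [state_distance()] of each state to the window's element-wise mean,
#' `phi = (1/tau) * sum_i D(S_i, S_bar)`. Development is declared stable when
#' phi falls below the threshold `sigma`.
#'
#' @param states A list of `tau + 1` numeric state vectors of equal length
#'   (chronological order is conventional but does not affect the value), or a
#'   matrix with one state per row.
#' @return A single non-negative number; 0 iff all states are identical.
#' @examples
#' v <- c(0.2, -0.5)
#' convergence_phi(rep(list(v), 11)) # 0: a flat window is stable
#' @export
convergence_phi <- function(states) {
  if (is.matrix(states)) states <- asplit(states, 1)
  if (!is.list(states) || length(states) < 2)
    abort("`states` must hold at least 2 state vectors (a window of tau + 1).")
  lens <- lengths(states)
  if (length(unique(lens)) != 1)
    abort("All states in the window must have the same length.")
  states <- lapply(states, function(s) { check_state(s); as.numeric(s) })
  tau <- length(states) - 1
  m <- Reduce(`+`, states) / (tau + 1)
  sum(vapply(states, state_distance, numeric(1), y = m)) / tau
}

#' Develop an individual to stability
#'
#' Iterates the developmental map S(t+1) = f(W S(t)) from the initial state
#' `s0`. After each step, once a full window of `tau + 1` states exists (i.e.
#' from step index `tau` onwards, counting `s0` as state 0), the convergence
#' statistic [convergence_phi()] is evaluated over the most recent window;
#' development *converges* if the statistic drops below `sigma` at some step
#' `t <= l_max`, in which case S(t) is the stable expression state and `t` the
#' developmental path length. If `l_max` steps pass without convergence the
#' individual is unstable (this is also how persistently cyclic networks,
#' e.g. those whose dominant eigenvalues are complex, are discarded).
#'
#' The individual is *viable* when development converges and the stable
#' state's expression levels have variance at least `min_var` — the latter
#' excludes trivial collapse to the ever-present fixed point at the origin
#' (see [model_params()]).
#'
#' The computation is deterministic: identical `(w, s0, params)` give
#' bit-identical results.
#'
#' @inheritParams develop_step
#' @param s0 Initial expression state (e.g. maternally inherited product
#'   levels), length `nrow(w)`, elements in `[-1, 1]`.
#' @param keep_phi If `TRUE`, record the convergence statistic at every step
#'   at which it was evaluated (diagnostics).
#' @return An object of class `grn_development`: a list with `viable` and
#'   `converged` (logicals), `final_state` (the stable state if converged,
#'   otherwise the last state reached), `path_length` (steps executed; equals
#'   `l_max` when non-converged), and optionally `phi_history`.
#' @examples
#' set.seed(1)
#' w <- random_network(5)
#' s0 <- random_state(5)
#' develop(w, s0)
#' @seealso [model_params()], [find_viable_individual()]
#' @export
develop <- function(w, s0, params = model_params(), keep_phi = FALSE) {
  params <- as_grn_params(params)
  check_network(w)
  check_state(s0, nrow(w))
  res <- .develop_cpp(w, as.numeric(s0), params$a, params$tau, params$sigma,
                      params$l_max, params$min_var, isTRUE(keep_phi))
  res$params <- params
  res$n <- nrow(w)
  structure(res, class = "grn_development")
}

#' @export
print.grn_development <- function(x, ...) {
  if (x$viable) {
    cat(sprintf("<grn_development> viable, n = %d, path length %d\n",
                x$n, x$path_length))
    cat("stable state:", format(round(x$final_state, 4)), "\n")
  } else if (x$converged) {
    cat(sprintf("<grn_development> converged in %d steps but NOT viable (stable-state variance %.3g < %g)\n",
                x$path_length, var(x$final_state), x$params$min_var))
  } else {
    cat(sprintf("<grn_development> no convergence after %d steps (n = %d)\n",
                x$path_length, x$n))
  }
  invisible(x)
}

#' Tidy a development result
#'
#' @param x A `grn_development` object from [develop()].
#' @param ... Unused.
#' @return For `tidy()`, a tibble with one row per gene (`gene`,
#'   `expression`); for `glance()`, a one-row tibble with `viable`,
#'   `path_length`, `n`, and the model parameters used.
#' @export
tidy.grn_development <- function(x, ...) {
  tibble(gene = seq_len(x$n), expression = as.numeric(x$final_state))
}

#' @rdname tidy.grn_development
#' @export
glance.grn_development <- function(x, ...) {
  tibble(viable = x$viable, converged = x$converged,
         path_length = x$path_length, n = x$n,
         a = x$params$a, tau = x$params$tau, sigma = x$params$sigma,
         l_max = x$params$l_max, min_var = x$params$min_var)
}
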