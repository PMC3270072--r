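#' Draw a random regulatory network
#'
#' All `n^2` interaction strengths are drawn i.i.d. Uniform on `[-1, 1]`; the
#' matrix is dense (every pair of genes interacts, however weakly). Entry
#' `[i, j]` is the effect of gene `j` on gene `i`.
#'
#' Randomness comes from R's global RNG: call `set.seed()` (or use the seeded
#' experiment runners) for reproducibility.
#'
#' @param n Positive integer number of genes.
#' @return An `n x n` numeric matrix with entries in `[-1, 1]`.
#' @examples
#' set.seed(42)
#' random_network(3)
#' @export
random_network <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    abort("`n` must be a positive integer.")
  matrix(runif(n * n, -1, 1), nrow = n, ncol = n)
}

#' Draw a random expression state
#'
#' Length-`n` vector of i.i.d. Uniform `[-1, 1]` expression levels; used both
#' as the maternally inherited initial state of a zygote and as replacement
#' vectors in the decomposition experiment.
#'
#' @inheritParams random_network
#' @return A numeric vector of length `n` with elements in `[-1, 1]`.
#' @export
random_state <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    abort("`n` must be a positive integer.")
  runif(n, -1, 1)
}

new_individual <- function(w, s0, dev, attempts = NA_integer_) {
  structure(
    list(network = w, initial_state = as.numeric(s0),
         stable_state = as.numeric(dev$final_state),
         path_length = dev$path_length, attempts = attempts),
    class = "grn_individual"
  )
}

#' @export
print.grn_individual <- function(x, ...) {
  cat(sprintf("<grn_individual> n = %d, path length %d%s\n",
              nrow(x$network), x$path_length,
              if (is.na(x$attempts)) "" else sprintf(", found in %d attempts", x$attempts)))
  invisible(x)
}

#' Find a viable individual by rejection sampling
#'
#' Repeatedly draws a random network and a random initial state and develops
#' the pair until development converges. This is the paper-and-pencil
#' definition of a random viable individual: no selection or enrichment, just
#' rejection sampling from the uniform ensemble.
#'
#' @param n Number of genes.
#' @param params A [model_params()] object.
#' @param max_attempts Failure budget; an error (class
#'   `grnevo_attempts_exhausted`, carrying the attempt count) is thrown if no
#'   viable pair is found within it. The default is effectively non-binding
#'   for viability rates down to well below 0.1%.
#' @return An object of class `grn_individual`: a list with `network`,
#'   `initial_state`, `stable_state`, `path_length`, and `attempts` (number of
#'   random pairs tried, including the successful one).
#' @examples
#' set.seed(7)
#' ind <- find_viable_individual(5)
#' develop(ind$network, ind$initial_state)$viable # TRUE by construction
#' @export
find_viable_individual <- function(n, params = model_params(),
                                   max_attempts = 1e6) {
  params <- as_grn_params(params)
  if (max_attempts < 1) abort("`max_attempts` must be >= 1.")
  for (attempt in seq_len(max_attempts)) {
    w <- random_network(n)
    s0 <- random_state(n)
    dev <- develop(w, s0, params)
    if (dev$viable) return(new_individual(w, s0, dev, attempt))
  }
  abort(
    sprintf("No viable individual found at n = %d within %d attempts.",
            n, as.integer(max_attempts)),
    class = "grnevo_attempts_exhausted",
    attempts = as.integer(max_attempts)
  )
}

#' Generate a population of viable individuals
#'
#' Independent calls to [find_viable_individual()]; the members are i.i.d.
#' draws from the viable subset of the uniform ensemble.
#'
#' @inheritParams find_viable_individual
#' @param size Number of viable individuals to generate.
#' @return A list of `grn_individual` objects of length `size`, of class
#'   `grn_population`, with attributes `n` and `attempts` (total random pairs
#'   tried). `tidy()` turns it into a tibble with list-columns.
#' @export
generate_population <- function(n, size, params = model_params(),
                                max_attempts = 1e6) {
  if (size < 1) abort("`size` must be >= 1.")
  params <- as_grn_params(params)
  pop <- vector("list", size)
  for (i in seq_len(size))
    pop[[i]] <- find_viable_individual(n, params, max_attempts)
  structure(pop, class = "grn_population", n = n,
            attempts = sum(vapply(pop, `[[`, integer(1), "attempts")))
}

#' @export
print.grn_population <- function(x, ...) {
  cat(sprintf("<grn_population> %d viable individuals, n = %d genes (%d attempts, raw viability %.3f)\n",
              length(x), attr(x, "n"), attr(x, "attempts"),
              length(x) / attr(x, "attempts")))
  invisible(x)
}

#' Tidy a population of viable individuals
#'
#' @param x A `grn_population` from [generate_population()].
#' @param ... Unused.
#' @return For `tidy()`, a tibble with one row per individual: `id`,
#'   `path_length`, `attempts`, and list-columns `network`, `initial_state`,
#'   `stable_state`. For `glance()`, a one-row summary with the raw viability
#'   rate implied by the rejection-sampling attempt counts.
#' @export
tidy.grn_population <- function(x, ...) {
  tibble(
    id = seq_along(x),
    path_length = map_int(x, "path_length"),
    attempts = map_int(x, "attempts"),
    network = map(x, "network"),
    initial_state = map(x, "initial_state"),
    stable_state = map(x, "stable_state")
  )
}

#' @rdname tidy.grn_population
#' @export
glance.grn_population <- function(x, ...) {
  att <- attr(x, "attempts")
  tibble(n = attr(x, "n"), size = length(x), attempts = att,
         raw_viability = length(x) / att,
         mean_path_length = mean(map_int(x, "path_length")))
}

as_individual <- function(x) {
  if (inherits(x, "grn_individual")) return(x)
  abort("Expected a `grn_individual` (see `find_viable_individual()`).")
}
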