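#' Intraclass correlation of stable expression states
#'
#' Measures whether the stable output vectors of a set of viable individuals
#' cluster: are the expression levels of a given gene similar across
#' individuals, relative to the spread between genes? Values near 0 mean the
#' stable states of independent viable individuals are uncorrelated; values
#' near 1 mean the population shares essentially one stable state.
#'
#' Two estimators are provided. `"anova"` (the default) is the classical
#' one-way ANOVA intraclass correlation with gene as the grouping factor and
#' individuals as replicates: `(MSB - MSW) / (MSB + (n - 1) MSW)` with `n`
#' individuals per gene. `"moment"` is the Fisher-style pairwise moment
#' estimator `(1/(n-1)) * ((n / (k s^2)) * sum_j (xbar_j - xbar)^2 - 1)`,
#' where `xbar_j` is gene j's mean over individuals, `xbar` the grand mean,
#' `k` the number of genes and `s^2` the population variance of all `n*k`
#' values. The two agree on the anchoring cases (a population of clones gives
#' 1; i.i.d. values give ~0) and differ only by small-sample factors.
#'
#' @param data Numeric matrix, individuals in rows, genes in columns (at least
#'   2 of each), values in `[-1, 1]`. A population's stable states can be
#'   stacked with [stable_state_matrix()].
#' @param method `"anova"` or `"moment"`.
#' @return A single number; by construction at most 1, and at least
#'   `-1/(n-1)`-ish for the degenerate designs. Zero (with a warning) if the
#'   data have no variance at all.
#' @examples
#' set.seed(2)
#' icc(matrix(runif(200, -1, 1), 20, 10))         # ~0: no clustering
#' icc(matrix(rep(runif(5, -1, 1), each = 20), 20, 5)) # 1: clones
#' @export
icc <- function(data, method = c("anova", "moment")) {
  method <- match.arg(method)
  if (!is.matrix(data) || !is.numeric(data))
    abort("`data` must be a numeric matrix (individuals x genes).")
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2)
    abort("Need at least 2 individuals and 2 genes.")
  if (any(!is.finite(data)))
    abort("`data` must be finite.")
  if (var(as.numeric(data)) == 0) {
    warn("Data have zero variance; ICC is undefined and reported as 0.")
    return(0)
  }
  gene_means <- colMeans(data)
  grand_mean <- mean(data)
  if (method == "moment") {
    s2 <- mean((data - grand_mean)^2) # population variance over all n*k values
    return((1 / (n - 1)) * ((n / (k * s2)) * sum((gene_means - grand_mean)^2) - 1))
  }
  # one-way ANOVA, gene as grouping factor, n replicates per gene
  ss_between <- n * sum((gene_means - grand_mean)^2)
  ss_within <- sum(sweep(data, 2, gene_means)^2)
  msb <- ss_between / (k - 1)
  msw <- ss_within / (k * (n - 1))
  (msb - msw) / (msb + (n - 1) * msw)
}

#' Stack a population's stable states into a matrix
#'
#' @param population A `grn_population` (or plain list of `grn_individual`s).
#' @return A numeric matrix, one row per individual, one column per gene.
#' @export
stable_state_matrix <- function(population) {
  do.call(rbind, lapply(population, `[[`, "stable_state"))
}

#' Viability rate with a binomial confidence interval
#'
#' Point estimate plus the 95% Wilson score interval (computed in closed form;
#' it never escapes `[0, 1]` and behaves well at the small success counts seen
#' for large random networks).
#'
#' @param outcomes Logical vector of per-trial viability outcomes, or an
#'   integer count of successes (then `trials` must be given).
#' @param trials Number of trials when `outcomes` is a count.
#' @param conf_level Confidence level of the interval.
#' @return A one-row tibble: `successes`, `trials`, `rate`, `ci_low`,
#'   `ci_high`.
#' @examples
#' viability_rate(c(rep(TRUE, 89), rep(FALSE, 911)))
#' @export
viability_rate <- function(outcomes, trials = NULL, conf_level = 0.95) {
  if (is.logical(outcomes)) {
    if (length(outcomes) < 1) abort("Need at least one outcome.")
    if (anyNA(outcomes)) abort("`outcomes` must not contain NA.")
    x <- sum(outcomes)
    n <- length(outcomes)
  } else {
    if (is.null(trials)) abort("Give `trials` when `outcomes` is a count.")
    x <- outcomes
    n <- trials
    if (n < 1 || x < 0 || x > n) abort("Need 0 <= successes <= trials, trials >= 1.")
  }
  p <- x / n
  z <- qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(successes = as.integer(x), trials = as.integer(n), rate = p,
         ci_low = max(0, centre - half), ci_high = min(1, centre + half))
}

#' Uniformity of pooled stable expression levels
#'
#' In the continuous regime the stable expression levels pooled across viable
#' individuals look uniform on (-1, 1); in the discrete regime they pile up at
#' the endpoints. This is a one-sample Kolmogorov-Smirnov test of the pooled
#' elements against Uniform(-1, 1).
#'
#' @param stable_vectors A list of stable-state vectors, a
#'   `grn_population`, or a numeric matrix (rows = individuals).
#' @param alpha Rejection level reported alongside the p-value.
#' @return A one-row tibble: `n_values`, `statistic`, `p_value`, `alpha`,
#'   `rejected`.
#' @export
output_uniformity <- function(stable_vectors, alpha = 0.01) {
  if (inherits(stable_vectors, "grn_population") ||
      (is.list(stable_vectors) && !is.data.frame(stable_vectors)))
    pooled <- unlist(lapply(stable_vectors, function(x)
      if (inherits(x, "grn_individual")) x$stable_state else x))
  else pooled <- as.numeric(stable_vectors)
  if (length(pooled) < 100)
    abort("Need at least 100 pooled expression values.")
  kt <- suppressWarnings(ks.test(pooled, "punif", min = -1, max = 1))
  tibble(n_values = length(pooled), statistic = unname(kt$statistic),
         p_value = kt$p.value, alpha = alpha, rejected = kt$p.value < alpha)
}

#' Minimum-variance population filter (discrete regime)
#'
#' Optional population-level acceptance filter for discrete-output runs: a
#' generated population passes if the variance of its pooled stable expression
#' levels is at least `min_var`. It is a property of a population, not of an
#' individual, and is disabled by default in all runners (and meaningless for
#' continuous-output runs, whose pooled variance is ~1/3).
#'
#' @param population A `grn_population` or list of individuals.
#' @param min_var Minimum pooled variance.
#' @return `TRUE` or `FALSE`.
#' @export
population_variance_ok <- function(population, min_var = 0.1) {
  pooled <- as.numeric(stable_state_matrix(population))
  var(pooled) >= min_var
}

#' Network-versus-initial-vector decomposition of viability
#'
#' For each viable individual, two shuffling arms disentangle what carries
#' viability. *retained_vector*: keep the individual's original initial state
#' and replace its network with a fresh random one, `n_shuffles` times.
#' *retained_network*: keep the network and redraw the initial state,
#' `n_shuffles` times. The per-arm viable fraction says how much information
#' the vector (respectively the network) holds: in the continuous regime the
#' retained-vector fraction stays near the unconditional random-viability
#' rate (the vector carries almost nothing), while in the discrete regime the
#' retained-network fraction is large (the matrix decides).
#'
#' @param population A `grn_population` of viable individuals.
#' @param n_shuffles Random replacements per individual per arm.
#' @param params A [model_params()] object (use the same regime the population
#'   was generated under).
#' @param arms Which arms to run.
#' @return A tibble with one row per individual per arm: `id`, `n`, `arm`,
#'   `successes`, `trials`, `rate`.
#' @export
decompose_stability <- function(population, n_shuffles = 200,
                                params = model_params(),
                                arms = c("retained_vector", "retained_network")) {
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1.")
  arms <- match.arg(arms, several.ok = TRUE)
  params <- as_grn_params(params)
  n <- attr(population, "n") %||% nrow(population[[1]]$network)
  rows <- list()
  for (i in seq_along(population)) {
    ind <- population[[i]]
    if ("retained_vector" %in% arms) {
      ok <- 0L
      for (s in seq_len(n_shuffles))
        if (develop(random_network(n), ind$initial_state, params)$viable)
          ok <- ok + 1L
      rows[[length(rows) + 1]] <- tibble(id = i, n = n, arm = "retained_vector",
                                         successes = ok, trials = n_shuffles,
                                         rate = ok / n_shuffles)
    }
    if ("retained_network" %in% arms) {
      ok <- 0L
      for (s in seq_len(n_shuffles))
        if (develop(ind$network, random_state(n), params)$viable)
          ok <- ok + 1L
      rows[[length(rows) + 1]] <- tibble(id = i, n = n, arm = "retained_network",
                                         successes = ok, trials = n_shuffles,
                                         rate = ok / n_shuffles)
    }
  }
  bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
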