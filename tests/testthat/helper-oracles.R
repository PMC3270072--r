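# Independent scalar-loop reference implementations of the developmental
# dynamics, written against the formulas directly (no vectorization, no reuse
# of package internals). Used to cross-check the compiled path.

oracle_sigmoid <- function(x, a) {
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- 2 / (1 + exp(-a * x[i])) - 1
  out
}

oracle_step <- function(w, s, a) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in 1:n) {
    acc <- 0
    for (j in 1:n) acc <- acc + w[i, j] * s[j]
    out[i] <- 2 / (1 + exp(-a * acc)) - 1
  }
  out
}

oracle_distance <- function(x, y) {
  n <- length(x)
  acc <- 0
  for (i in 1:n) acc <- acc + (x[i] - y[i])^2
  acc / (4 * n)
}

oracle_phi <- function(states) {
  m <- length(states) # tau + 1
  tau <- m - 1
  n <- length(states[[1]])
  mean_state <- numeric(n)
  for (k in 1:m) for (j in 1:n) mean_state[j] <- mean_state[j] + states[[k]][j] / m
  acc <- 0
  for (k in 1:m) acc <- acc + oracle_distance(states[[k]], mean_state)
  acc / tau
}

oracle_develop <- function(w, s0, params = model_params()) {
  window <- list(as.numeric(s0))
  s <- as.numeric(s0)
  converged <- FALSE
  path <- params$l_max
  for (t in seq_len(params$l_max)) {
    s <- oracle_step(w, s, params$a)
    window <- c(window, list(s))
    if (length(window) > params$tau + 1) window <- window[-1]
    if (t >= params$tau && oracle_phi(window) < params$sigma) {
      converged <- TRUE
      path <- t
      break
    }
  }
  viable <- converged &&
    (params$min_var <= 0 || stats::var(s) >= params$min_var)
  list(viable = viable, converged = converged, final_state = s,
       path_length = path)
}

# Small helpers for building fixtures in code.
rand_individual_fixture <- function(n, params = model_params()) {
  find_viable_individual(n, params)
}
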