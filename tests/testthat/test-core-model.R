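test_that("sigmoid scaling is centred, odd, increasing, and bounded", {
  expect_identical(sigmoid_scale(0, 1.5), 0)
  expect_equal(sigmoid_scale(1, 1.5), 0.6351489523872873, tolerance = 1e-12)

  set.seed(101)
  x <- runif(200, -10, 10)
  for (a in c(0.5, 1.5)) {
    y <- sigmoid_scale(x, a)
    expect_true(all(y > -1 & y < 1))
    expect_lt(max(abs(y + sigmoid_scale(-x, a))), 1e-12)
    ord <- order(x)
    expect_true(all(diff(y[ord]) > 0))
  }
  # at a = 100 the range saturates to +-1 within double precision
  y100 <- sigmoid_scale(x, 100)
  expect_true(all(y100 >= -1 & y100 <= 1))
  expect_true(all(diff(y100[order(x)]) >= 0))
  expect_equal(sigmoid_scale(x, 1.5), oracle_sigmoid(x, 1.5), tolerance = 1e-12)

  # saturation: the discrete-output regime
  expect_lt(abs(sigmoid_scale(5, 100) - 1), 1e-6)
  xm <- runif(500, 0.1, 1) * sample(c(-1, 1), 500, replace = TRUE)
  expect_true(all(abs(abs(sigmoid_scale(xm, 100)) - 1) < 1e-4))

  expect_error(sigmoid_scale(c(1, NA), 1.5), "finite")
  expect_error(sigmoid_scale(1, -2), "positive")
})

test_that("one developmental step matches the elementwise update", {
  expect_identical(develop_step(matrix(0, 3, 3), c(1, -1, 0.5)), rep(0, 3))

  s <- c(0.3, -0.7, 0.1)
  expect_equal(develop_step(diag(3), s), sigmoid_scale(s, 1.5), tolerance = 1e-15)

  set.seed(102)
  for (i in 1:20) {
    w <- matrix(runif(25, -1, 1), 5)
    s <- runif(5, -1, 1)
    expect_equal(develop_step(w, s), oracle_step(w, s, 1.5), tolerance = 1e-12)
  }

  expect_error(develop_step(matrix(0, 3, 3), c(1, 2)), "match")
  expect_error(develop_step(matrix(2, 2, 2), c(0, 0)), "\\[-1, 1\\]")
})

test_that("state distance is normalised, symmetric, and zero iff equal", {
  expect_identical(state_distance(c(1, 2, 3) / 3, c(1, 2, 3) / 3), 0)
  expect_equal(state_distance(c(1, 0, -1), c(0, 0, 0)), 1 / 6, tolerance = 1e-15)
  for (n in c(2, 5, 9)) {
    expect_equal(state_distance(rep(1, n), rep(-1, n)), 1, tolerance = 1e-15)
  }
  set.seed(103)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    x <- runif(n, -1, 1); y <- runif(n, -1, 1)
    d <- state_distance(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_identical(d, state_distance(y, x))
    expect_equal(d, oracle_distance(x, y), tolerance = 1e-14)
  }
  expect_error(state_distance(c(1, 2), c(1, 2, 3)), "differ")
})

test_that("the convergence statistic vanishes only on flat windows", {
  v <- c(0.2, -0.5, 0.9)
  expect_lt(convergence_phi(rep(list(v), 11)), 1e-28) # zero up to fp rounding
  expect_identical(convergence_phi(rep(list(c(0.5, -0.25)), 11)), 0)

  u <- c(0.4, -0.4)
  alternating <- rep(list(u, -u), length.out = 11)
  expect_gt(convergence_phi(alternating), 0)

  set.seed(104)
  win <- lapply(1:11, function(i) runif(4, -1, 1))
  expect_equal(convergence_phi(win), oracle_phi(win), tolerance = 1e-12)
  expect_equal(convergence_phi(do.call(rbind, win)), oracle_phi(win),
               tolerance = 1e-12)

  expect_error(convergence_phi(list(v)), "at least 2")
  expect_error(convergence_phi(list(c(1, 2), c(1, 2, 3))), "same length")
})

test_that("development separates convergence from viability", {
  # the zero network collapses to the origin in one step: converged, but the
  # expressed pattern has no variance, so it is not viable by default
  set.seed(105)
  dev <- develop(matrix(0, 4, 4), runif(4, -1, 1))
  expect_true(dev$converged)
  expect_false(dev$viable)
  expect_identical(dev$final_state, rep(0, 4))
  # tau steps fill the window with s0 still inside; one more step flattens it
  expect_identical(dev$path_length, 11L)

  # with the variance floor disabled, bare convergence is viability
  dev0 <- develop(matrix(0, 4, 4), runif(4, -1, 1), model_params(min_var = 0))
  expect_true(dev0$viable)
})

test_that("a sign-flip two-cycle in the discrete regime never stabilises", {
  # mutual activation started from opposite signs oscillates with period 2:
  # (1,-1) -> f((-1, 1)) -> f((1, -1)) -> ...
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  dev <- develop(w, c(1, -1), dov_params())
  expect_false(dev$converged)
  expect_false(dev$viable)
  expect_identical(dev$path_length, 100L)

  # mutual repression from the same start is a fixed point of the same map
  w_rep <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_true(develop(w_rep, c(1, -1), dov_params())$viable)
})

test_that("development is deterministic and matches the scalar-loop oracle", {
  set.seed(106)
  w <- random_network(8); s0 <- random_state(8)
  d1 <- develop(w, s0); d2 <- develop(w, s0)
  expect_identical(d1$final_state, d2$final_state)
  expect_identical(d1$path_length, d2$path_length)
  expect_identical(d1$viable, d2$viable)

  set.seed(107)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    p <- if (i %% 4 == 0) dov_params() else model_params()
    w <- random_network(n); s0 <- random_state(n)
    got <- develop(w, s0, p)
    want <- oracle_develop(w, s0, p)
    expect_identical(got$viable, want$viable)
    expect_identical(got$converged, want$converged)
    expect_identical(got$path_length, as.integer(want$path_length))
    expect_equal(got$final_state, want$final_state, tolerance = 1e-10)
  }
})

test_that("a stable state re-enters development and stays viable", {
  set.seed(108)
  found <- 0
  while (found < 20) {
    n <- sample(c(5, 8, 12), 1)
    w <- random_network(n); s0 <- random_state(n)
    d <- develop(w, s0)
    if (!d$viable) next
    found <- found + 1
    d2 <- develop(w, d$final_state)
    expect_true(d2$converged)
    expect_lte(d2$path_length, d$path_length)
    # the recorded stable state sits within the phi window's spread (~tau *
    # sigma in distance units) of the true fixed point, so re-entry can drift
    # by that much before settling
    expect_lt(state_distance(d2$final_state, d$final_state), 5e-3)
    # away from the variance floor, viability itself is re-entrant
    if (var(d$final_state) > 0.12) expect_true(d2$viable)
  }
})

test_that("development results tidy into per-gene and summary tables", {
  set.seed(109)
  d <- develop(random_network(5), random_state(5), keep_phi = TRUE)
  td <- tidy(d)
  expect_identical(nrow(td), 5L)
  expect_named(td, c("gene", "expression"))
  g <- glance(d)
  expect_identical(g$n, 5L)
  expect_identical(g$viable, d$viable)
  expect_true(length(d$phi_history) >= 1)
})
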