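pop_of <- function(n, size, seed = 1) {
  set.seed(seed)
  generate_population(n, size)
}

test_that("clone mating is the identity and always viable", {
  pop <- pop_of(5, 3, seed = 301)
  for (ind in pop) {
    h <- mate_haploid(ind, ind)
    d <- mate_diploid(ind, ind)
    expect_identical(h$offspring_network, ind$network)
    expect_identical(d$offspring_network, ind$network)
    expect_true(h$viable)
    expect_true(d$viable)
  }
})

test_that("haploid offspring rows are copied whole from one parent", {
  pop <- pop_of(6, 2, seed = 302)
  m <- pop[[1]]; f <- pop[[2]]

  all_maternal <- mate_haploid(m, f, rows = rep(1, 6))
  expect_identical(all_maternal$offspring_network, m$network)

  set.seed(303)
  for (i in 1:10) {
    off <- mate_haploid(m, f)$offspring_network
    for (r in 1:6) {
      expect_true(identical(off[r, ], m$network[r, ]) ||
                  identical(off[r, ], f$network[r, ]))
    }
  }
  # the initial state is a parent's stable state, verbatim
  set.seed(304)
  out <- mate_haploid(m, f)
  expect_true(identical(out$offspring_initial_state, m$stable_state) ||
              identical(out$offspring_initial_state, f$stable_state))
})

test_that("diploid mating averages entries, commutes, and stays bounded", {
  pop <- pop_of(5, 2, seed = 305)
  m <- pop[[1]]; f <- pop[[2]]
  off <- mate_diploid(m, f)$offspring_network
  expect_identical(off, (m$network + f$network) / 2)
  expect_identical(off, mate_diploid(f, m)$offspring_network)
  lo <- pmin(m$network, f$network); hi <- pmax(m$network, f$network)
  expect_true(all(off >= lo & off <= hi))
  expect_true(all(off >= -1 & off <= 1))
  expect_error(mate_diploid(m, pop_of(4, 1, seed = 306)[[1]]), "differ in size")
})

test_that("insertion grows the network by one untouched-elsewhere gene", {
  ind <- pop_of(4, 1, seed = 307)[[1]]
  set.seed(308)
  out <- insert_gene(ind)
  w2 <- out$offspring_network
  expect_identical(dim(w2), c(5L, 5L))
  k <- out$index
  old <- setdiff(1:5, k)
  expect_identical(w2[old, old], ind$network)
  expect_true(all(w2 >= -1 & w2 <= 1))
  # starting vector = parent's stable state with one new element spliced in
  expect_identical(out$offspring_initial_state[old], ind$stable_state)
  expect_true(abs(out$offspring_initial_state[k]) <= 1)
})

test_that("append duplication copies a row/column pair and is reversible", {
  ind <- pop_of(4, 1, seed = 309)[[1]]
  w <- ind$network
  set.seed(310)
  out <- duplicate_gene(ind, mode = "append")
  w2 <- out$offspring_network
  g <- out$index
  expect_identical(dim(w2), c(5L, 5L))
  expect_identical(w2[1:4, 1:4], w)
  expect_identical(w2[5, 1:4], w[g, ])
  expect_identical(w2[1:4, 5], w[, g])
  expect_identical(w2[5, 5], w[g, g])
  expect_identical(out$offspring_initial_state,
                   c(ind$stable_state, ind$stable_state[g]))
  # deleting the just-appended copy restores the parent matrix exactly
  expect_identical(w2[-5, -5], w)

  # zero-coupling variant: the copies do not regulate each other
  set.seed(310)
  outz <- duplicate_gene(ind, mode = "append", zero_coupling = TRUE)
  expect_identical(outz$offspring_network[5, outz$index], 0)
  expect_identical(outz$offspring_network[outz$index, 5], 0)
})

test_that("overwrite duplication keeps size and leaves two copies", {
  ind <- pop_of(6, 1, seed = 311)[[1]]
  set.seed(312)
  out <- duplicate_gene(ind) # overwrite is the default
  w2 <- out$offspring_network
  expect_identical(dim(w2), dim(ind$network))
  g <- out$index
  h <- setdiff(which(vapply(1:6, function(r)
    identical(w2[r, -c(r, g)], unname(ind$network[g, -c(r, g)])), logical(1))), g)
  expect_length(h, 1)
  expect_identical(w2[h, h], ind$network[g, g])
  expect_identical(w2[g, h], ind$network[g, g])
  expect_identical(w2[h, g], ind$network[g, g])
  expect_identical(out$offspring_initial_state[h], ind$stable_state[g])
  # all other genes untouched
  others <- setdiff(1:6, c(g, h))
  expect_identical(w2[others, others], ind$network[others, others])
})

test_that("deletion strikes one row, column, and vector entry", {
  ind <- pop_of(5, 1, seed = 313)[[1]]
  set.seed(314)
  out <- delete_gene(ind)
  g <- out$index
  expect_identical(out$offspring_network, ind$network[-g, -g])
  expect_identical(out$offspring_initial_state, ind$stable_state[-g])
  expect_identical(dim(out$offspring_network), c(4L, 4L))

  one_gene <- structure(
    list(network = matrix(0.5, 1, 1), initial_state = 0.2,
         stable_state = 0.3, path_length = 5L, attempts = 1L),
    class = "grn_individual")
  expect_error(delete_gene(one_gene), "last gene")
})

test_that("offspring outcomes tidy into one-row tables", {
  ind <- pop_of(4, 1, seed = 315)[[1]]
  set.seed(316)
  td <- tidy(insert_gene(ind))
  expect_identical(nrow(td), 1L)
  expect_identical(td$source, "insertion")
  expect_identical(td$n, 5L)
  expect_type(td$viable, "logical")
})
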