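tiny_cfg <- function(...) {
  experiment_config(gene_sizes = c(4, 6), population_size = 15,
                    trials_per_unit = 60, indel_trials = 5, seed = 7, ...)
}

test_that("configs resolve scaling with a floor and validate regime", {
  cfg <- experiment_config(scale_factor = 0.05)
  expect_identical(cfg$population_size, 50L)
  expect_identical(cfg$trials_per_unit, 50L)
  tiny <- experiment_config(scale_factor = 0.001)
  expect_identical(tiny$population_size, 10L) # floor
  expect_identical(cfg$indel_trials, 100L)    # protocol constant, not scaled
  expect_error(experiment_config(scale_factor = 0), "in \\(0, 1\\]")
  dov <- experiment_config(regime = "DOV")
  expect_identical(dov$params$a, 100)
})

test_that("configs round-trip through YAML files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gene_sizes: [5, 9]", "population_size: 40", "seed: 3",
               "regime: DOV", "params:", "  a: 100", "  min_var: 0"), path)
  cfg <- read_config(path)
  expect_identical(cfg$gene_sizes, c(5L, 9L))
  expect_identical(cfg$seed, 3L)
  expect_identical(cfg$params$min_var, 0)
  writeLines("not_a_field: 1", path)
  expect_error(read_config(path), "Unknown config fields")
})

test_that("the random-viability runner returns seeded, CI-bearing tables", {
  cfg <- tiny_cfg()
  tbl <- run_random_viability(cfg)
  expect_s3_class(tbl, "grn_rate_table")
  expect_identical(nrow(tbl), 2L)
  expect_true(all(c("n", "regime", "successes", "trials", "rate",
                    "ci_low", "ci_high") %in% names(tbl)))
  expect_true(all(tbl$ci_low <= tbl$rate & tbl$rate <= tbl$ci_high))

  # bit-identical rerun under the same master seed
  expect_identical(run_random_viability(cfg), tbl)

  # widening the replication narrows the interval
  cfg_big <- experiment_config(gene_sizes = 4, trials_per_unit = 1000, seed = 7)
  cfg_small <- experiment_config(gene_sizes = 4, trials_per_unit = 100, seed = 7)
  w_big <- with(run_random_viability(cfg_big), ci_high - ci_low)
  w_small <- with(run_random_viability(cfg_small), ci_high - ci_low)
  expect_lt(w_big, w_small)
})

test_that("mating, indel, icc and decomposition runners share populations", {
  cfg <- tiny_cfg()
  pops <- lapply(stats::setNames(cfg$gene_sizes, cfg$gene_sizes), function(n)
    grnevo:::population_for(cfg, n, sprintf("population:COV:n=%d", n)))

  hap <- run_mating(cfg, "haploid", populations = pops)
  expect_identical(nrow(hap), 2L)
  expect_true(all(hap$trials == 60L))
  expect_identical(run_mating(cfg, "haploid", populations = pops), hap)

  ins <- run_indels(cfg, "insertion", populations = pops)
  expect_true(all(ins$trials == 15L * 5L))
  expect_true(all(ins$parent_any_rate >= ins$rate))

  icc_tbl <- run_icc(cfg, populations = pops)
  expect_true(all(abs(icc_tbl$icc_anova) <= 1))
  expect_identical(icc_tbl$size, c(15L, 15L))

  dec <- run_decomposition(cfg, populations = pops, n_shuffles = 4)
  expect_identical(nrow(dec), 4L) # two sizes x two arms
  expect_true(all(dec$trials == 15L * 4L))
})

test_that("results directories carry a reproducible manifest", {
  cfg <- tiny_cfg()
  tbl <- run_random_viability(cfg)
  dir <- withr::local_tempdir()
  write_results(tbl, dir, cfg)
  expect_true(file.exists(file.path(dir, "results.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$seed, 7L)
  expect_identical(man$rows_written, 2L)
  cfg_plain <- unclass(cfg); cfg_plain$params <- unclass(cfg_plain$params)
  expect_identical(man$config_digest, grnevo:::config_digest(cfg_plain))
  got <- utils::read.csv(file.path(dir, "results.csv"))
  expect_equal(got$rate, tbl$rate)
})

test_that("seed derivation separates named streams deterministically", {
  expect_identical(derive_seed(1, "a"), derive_seed(1, "a"))
  expect_false(derive_seed(1, "mating:n=5") == derive_seed(1, "mating:n=6"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  expect_true(derive_seed(2^30, "x") < 2^31)
  expect_error(derive_seed("a", "b"), "integer")
})

test_that("rate tables and trajectories plot without error", {
  cfg <- tiny_cfg()
  p <- autoplot(run_random_viability(cfg))
  expect_s3_class(p, "ggplot")
  set.seed(7)
  d <- develop(random_network(6), random_state(6), keep_phi = TRUE)
  expect_s3_class(autoplot(d), "ggplot")
  d2 <- develop(random_network(6), random_state(6))
  expect_error(autoplot(d2), "keep_phi")
})
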