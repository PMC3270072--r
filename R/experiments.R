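#' Experiment configuration
#'
#' One object holds everything a runner needs: network sizes, replication
#' counts, the model regime and parameters, and the master seed. Full scale
#' (`scale_factor = 1`) mirrors the reference design — populations of 1000
#' viable individuals, 1000 matings, 100 insertion/deletion/duplication
#' attempts per population member. `scale_factor` shrinks `population_size`
#' and `trials_per_unit` multiplicatively (floor 10) for quick desk-scale
#' runs; the per-parent `indel_trials` count is part of the protocol and is
#' not scaled.
#'
#' @param gene_sizes Integer vector of network sizes to sweep.
#' @param population_size Viable individuals per size (before scaling).
#' @param trials_per_unit Matings or random draws per size (before scaling).
#' @param indel_trials Insertion/duplication/deletion attempts per parent.
#' @param regime `"COV"` (continuous output, a = 1.5) or `"DOV"` (discrete
#'   output, a = 100).
#' @param params Optional [model_params()] overriding the regime default.
#' @param seed Master seed; each runner derives an independent stream per
#'   (experiment, size) with [derive_seed()].
#' @param scale_factor In (0, 1]; multiplies `population_size` and
#'   `trials_per_unit`, with a floor of 10.
#' @param dov_variance_filter Apply the minimum pooled-variance population
#'   filter ([population_variance_ok()]) when generating DOV populations.
#' @param min_population_variance Threshold for that filter.
#' @param max_attempts Rejection-sampling budget per individual.
#' @return A list of class `grn_config` with scaled counts resolved.
#' @examples
#' experiment_config(gene_sizes = c(5, 10), scale_factor = 0.05, seed = 1)
#' @export
experiment_config <- function(gene_sizes = 3:15,
                              population_size = 1000,
                              trials_per_unit = 1000,
                              indel_trials = 100,
                              regime = c("COV", "DOV"),
                              params = NULL,
                              seed = 1,
                              scale_factor = 1,
                              dov_variance_filter = FALSE,
                              min_population_variance = 0.1,
                              max_attempts = 1e6) {
  regime <- match.arg(regime)
  if (!is.numeric(scale_factor) || scale_factor <= 0 || scale_factor > 1)
    abort("`scale_factor` must be in (0, 1].")
  if (is.null(params))
    params <- if (regime == "DOV") dov_params() else model_params()
  params <- as_grn_params(params)
  scaled <- function(x) max(10L, as.integer(floor(x * scale_factor)))
  structure(
    list(gene_sizes = as.integer(gene_sizes),
         population_size = scaled(population_size),
         trials_per_unit = scaled(trials_per_unit),
         indel_trials = as.integer(indel_trials),
         regime = regime, params = params, seed = seed,
         scale_factor = scale_factor,
         dov_variance_filter = isTRUE(dov_variance_filter),
         min_population_variance = min_population_variance,
         max_attempts = max_attempts),
    class = "grn_config"
  )
}

#' Read an experiment configuration from a YAML or JSON file
#'
#' Fields mirror the arguments of [experiment_config()]; missing fields take
#' the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `grn_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    abort(sprintf("Unknown config fields: %s", paste(bad, collapse = ", ")))
  if (!is.null(raw$params)) raw$params <- do.call(model_params, raw$params)
  do.call(experiment_config, raw)
}

#' @export
print.grn_config <- function(x, ...) {
  cat(sprintf("<grn_config> %s regime, sizes %s, population %d, trials %d, indel trials %d, seed %s\n",
              x$regime, paste(range(x$gene_sizes), collapse = "-"),
              x$population_size, x$trials_per_unit, x$indel_trials,
              format(x$seed)))
  invisible(x)
}

population_for <- function(cfg, n, stream) {
  with_stream(cfg$seed, stream, {
    pop <- generate_population(n, cfg$population_size, cfg$params,
                               cfg$max_attempts)
    if (cfg$regime == "DOV" && cfg$dov_variance_filter) {
      tries <- 1
      while (!population_variance_ok(pop, cfg$min_population_variance) &&
             tries < 20) {
        pop <- generate_population(n, cfg$population_size, cfg$params,
                                   cfg$max_attempts)
        tries <- tries + 1
      }
    }
    pop
  })
}

rate_table_class <- function(tbl, experiment) {
  attr(tbl, "experiment") <- experiment
  class(tbl) <- c("grn_rate_table", class(tbl))
  tbl
}

#' Random-genesis viability sweep
#'
#' For each network size, draws `trials_per_unit` random (network, initial
#' state) pairs from the uniform ensemble and estimates the probability that a
#' random individual is viable — the baseline every evolution operator is
#' compared against.
#'
#' @param cfg A [experiment_config()].
#' @return A tibble (class `grn_rate_table`), one row per size: `n`, `regime`,
#'   `successes`, `trials`, `rate`, `ci_low`, `ci_high`.
#' @examples
#' cfg <- experiment_config(gene_sizes = c(4, 6), trials_per_unit = 2000,
#'                          scale_factor = 0.1, seed = 1)
#' run_random_viability(cfg)
#' @export
run_random_viability <- function(cfg) {
  p <- cfg$params
  out <- map(cfg$gene_sizes, function(n) {
    ok <- with_stream(cfg$seed, sprintf("random_viability:%s:n=%d", cfg$regime, n),
                      .random_viability_cpp(n, cfg$trials_per_unit, p$a, p$tau,
                                            p$sigma, p$l_max, p$min_var))
    mutate(viability_rate(ok, cfg$trials_per_unit), n = n,
           regime = cfg$regime, .before = 1)
  })
  rate_table_class(bind_rows(out), "random_viability")
}

mate_once <- function(pop, mode, params) {
  idx <- sample.int(length(pop), 2, replace = FALSE) # distinct parents
  if (mode == "haploid") mate_haploid(pop[[idx[1]]], pop[[idx[2]]], params)
  else mate_diploid(pop[[idx[1]]], pop[[idx[2]]], params)
}

#' Mating viability sweep
#'
#' For each size, generates (or reuses) a population of viable individuals and
#' mates `trials_per_unit` random distinct pairs (drawn with replacement
#' across matings), recording the fraction of viable offspring.
#'
#' @param cfg A [experiment_config()].
#' @param mode `"haploid"` or `"diploid"`.
#' @param populations Optional named list of pre-built populations (names =
#'   network sizes as characters) to reuse across runners.
#' @return A `grn_rate_table` tibble, one row per size.
#' @export
run_mating <- function(cfg, mode = c("haploid", "diploid"),
                       populations = NULL) {
  mode <- match.arg(mode)
  out <- map(cfg$gene_sizes, function(n) {
    pop <- populations[[as.character(n)]] %||%
      population_for(cfg, n, sprintf("population:%s:n=%d", cfg$regime, n))
    oks <- with_stream(cfg$seed, sprintf("mating:%s:%s:n=%d", mode, cfg$regime, n),
                       vapply(seq_len(cfg$trials_per_unit), function(i)
                         mate_once(pop, mode, cfg$params)$viable, logical(1)))
    mutate(viability_rate(oks), n = n, regime = cfg$regime, mode = mode,
           .before = 1)
  })
  rate_table_class(bind_rows(out), paste0("mating_", mode))
}

#' Insertion / duplication / deletion viability sweep
#'
#' For each size, applies `indel_trials` independent operator draws to every
#' member of a viable population. Both success metrics are reported: the
#' per-trial viable fraction (primary) and the per-parent fraction with at
#' least one viable offspring among its trials.
#'
#' @param cfg A [experiment_config()].
#' @param op `"insertion"`, `"duplication"` or `"deletion"`.
#' @param populations Optional named list of pre-built populations, as in
#'   [run_mating()].
#' @return A `grn_rate_table` tibble, one row per size, with per-trial
#'   `successes`/`trials`/`rate`/CI plus `parent_any_rate`.
#' @export
run_indels <- function(cfg, op = c("insertion", "duplication", "deletion"),
                       populations = NULL) {
  op <- match.arg(op)
  fun <- switch(op, insertion = insert_gene, duplication = duplicate_gene,
                deletion = delete_gene)
  out <- map(cfg$gene_sizes, function(n) {
    pop <- populations[[as.character(n)]] %||%
      population_for(cfg, n, sprintf("population:%s:n=%d", cfg$regime, n))
    res <- with_stream(cfg$seed, sprintf("indel:%s:%s:n=%d", op, cfg$regime, n), {
      per_parent <- vapply(pop, function(ind)
        sum(vapply(seq_len(cfg$indel_trials), function(i)
          fun(ind, cfg$params)$viable, logical(1))), integer(1))
      per_parent
    })
    est <- viability_rate(sum(res), length(pop) * cfg$indel_trials)
    mutate(est, n = n, regime = cfg$regime, op = op, .before = 1) %>%
      mutate(parent_any_rate = mean(res > 0))
  })
  rate_table_class(bind_rows(out), paste0("indel_", op))
}

#' Intraclass-correlation sweep
#'
#' For each size, generates a viable population and computes the intraclass
#' correlation of its stacked stable states with both estimators, plus the
#' pooled-output uniformity test.
#'
#' @inheritParams run_mating
#' @return A tibble, one row per size: `n`, `regime`, `size`, `icc_anova`,
#'   `icc_moment`, `uniformity_p`.
#' @export
run_icc <- function(cfg, populations = NULL) {
  out <- map(cfg$gene_sizes, function(n) {
    pop <- populations[[as.character(n)]] %||%
      population_for(cfg, n, sprintf("population:%s:n=%d", cfg$regime, n))
    m <- stable_state_matrix(pop)
    unif_p <- if (length(m) >= 100) output_uniformity(pop)$p_value else NA_real_
    tibble(n = n, regime = cfg$regime, size = length(pop),
           icc_anova = icc(m, "anova"), icc_moment = icc(m, "moment"),
           uniformity_p = unif_p)
  })
  bind_rows(out)
}

#' Network-versus-vector decomposition sweep
#'
#' Runs [decompose_stability()] per size and aggregates: for each arm, the
#' pooled viable fraction over all individuals and shuffles.
#'
#' @inheritParams run_mating
#' @param n_shuffles Random replacements per individual per arm; defaults to
#'   `cfg$trials_per_unit`.
#' @return A `grn_rate_table` tibble, one row per size per arm.
#' @export
run_decomposition <- function(cfg, populations = NULL, n_shuffles = NULL) {
  n_shuffles <- n_shuffles %||% cfg$trials_per_unit
  out <- map(cfg$gene_sizes, function(n) {
    pop <- populations[[as.character(n)]] %||%
      population_for(cfg, n, sprintf("population:%s:n=%d", cfg$regime, n))
    per_ind <- with_stream(cfg$seed,
                           sprintf("decomposition:%s:n=%d", cfg$regime, n),
                           decompose_stability(pop, n_shuffles, cfg$params))
    per_ind %>%
      group_by(.data$n, .data$arm) %>%
      summarise(successes = sum(.data$successes), trials = sum(.data$trials),
                .groups = "drop") %>%
      mutate(regime = cfg$regime, rate = .data$successes / .data$trials)
  })
  rate_table_class(bind_rows(out), "decomposition")
}

#' Write an experiment result table with its manifest
#'
#' Writes `results.csv` plus a `manifest.json` recording the package version,
#' the configuration (including seed) and a digest of the written table, so
#' any results file can be regenerated bit-identically.
#'
#' @param tbl A result tibble from a runner.
#' @param dir Output directory (created if needed).
#' @param cfg The `grn_config` that produced it.
#' @return The directory, invisibly.
#' @export
write_results <- function(tbl, dir, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "results.csv")
  utils::write.csv(tbl, csv, row.names = FALSE)
  cfg_plain <- unclass(cfg)
  cfg_plain$params <- unclass(cfg_plain$params)
  manifest <- list(
    tool = "grnevo",
    tool_version = as.character(utils::packageVersion("grnevo")),
    experiment = attr(tbl, "experiment") %||% "table",
    config = cfg_plain,
    seed = cfg$seed,
    rows_written = nrow(tbl),
    config_digest = config_digest(cfg_plain),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

config_digest <- function(cfg_plain) {
  s <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(as.character(s))) h <- (h * 131 + code) %% m
  sprintf("%010d", h)
}
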