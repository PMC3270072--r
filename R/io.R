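fmt_float <- function(x) sprintf("%.17g", x)

#' Read and write networks
#'
#' Two interchange dialects. `tsv`: `n` lines of `n` tab-separated floats.
#' `json`: `{"n": <int>, "w": [[...], ...]}`. Both round-trip to full double
#' precision. The dialect is inferred from the file extension unless given.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"json"`; default infers from the extension.
#' @param w A square numeric matrix with entries in `[-1, 1]`.
#' @return `read_network()` returns the matrix; `write_network()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' set.seed(3)
#' w <- random_network(4)
#' write_network(w, f)
#' all.equal(read_network(f), w)
#' @export
read_network <- function(path, dialect = NULL) {
  dialect <- dialect %||% infer_dialect(path)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (dialect == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$w)) abort("JSON network must have a `w` field.")
    w <- obj$w
    if (is.list(w)) abort("JSON `w` rows have unequal lengths.")
    w <- as.matrix(w)
    if (!is.null(obj$n) && (nrow(w) != obj$n || ncol(w) != obj$n))
      abort(sprintf("JSON declares n = %d but `w` is %d x %d.",
                    obj$n, nrow(w), ncol(w)))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      toks <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals))
        abort(sprintf("Non-numeric token at line %d of %s: '%s'",
                      i, path, toks[which(is.na(vals))[1]]))
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1 || lens[1] != length(rows))
      abort(sprintf(
        "Not a square matrix in %s: %d rows, row lengths %s (first mismatch at line %d).",
        path, length(rows), paste(unique(lens), collapse = "/"),
        which(lens != lens[1])[1] %||% length(rows)))
    w <- do.call(rbind, rows)
  }
  storage.mode(w) <- "double"
  check_network(w)
  w
}

#' @rdname read_network
#' @export
write_network <- function(w, path, dialect = NULL) {
  check_network(w)
  dialect <- dialect %||% infer_dialect(path)
  if (dialect == "json") {
    jsonlite::write_json(list(n = nrow(w), w = w), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    writeLines(apply(w, 1, function(r) paste(fmt_float(r), collapse = "\t")),
               path)
  }
  invisible(path)
}

#' Read and write expression states
#'
#' A state is one TSV row of floats, or a JSON array.
#'
#' @param path File path.
#' @param s Numeric state vector.
#' @param dialect `"tsv"` or `"json"` (default: from extension).
#' @return `read_state()` returns the numeric vector.
#' @export
read_state <- function(path, dialect = NULL) {
  dialect <- dialect %||% infer_dialect(path)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  s <- if (dialect == "json") {
    unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    toks <- strsplit(trimws(readLines(path)[1]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) abort(sprintf("Non-numeric token in %s.", path))
    vals
  }
  check_state(s)
  as.numeric(s)
}

#' @rdname read_state
#' @export
write_state <- function(s, path, dialect = NULL) {
  check_state(s)
  dialect <- dialect %||% infer_dialect(path)
  if (dialect == "json")
    jsonlite::write_json(as.numeric(s), path, digits = NA)
  else
    writeLines(paste(fmt_float(s), collapse = "\t"), path)
  invisible(path)
}

infer_dialect <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
}

#' Read and write individuals
#'
#' An individual is a JSON bundle of its network, initial state, stable state,
#' developmental path length and the model parameters it was developed under.
#' On read, the stored stable state can be re-verified by redeveloping the
#' network from the stored initial state.
#'
#' @param ind A `grn_individual`.
#' @param path File path (JSON).
#' @param params The [model_params()] the individual was generated under
#'   (stored in the file).
#' @param verify Re-develop on read and error if the result is not viable or
#'   does not reproduce the stored stable state within the stability
#'   threshold (by [state_distance()]).
#' @return `read_individual()` returns a `grn_individual`.
#' @export
write_individual <- function(ind, path, params = model_params()) {
  ind <- as_individual(ind)
  params <- as_grn_params(params)
  jsonlite::write_json(
    list(n = nrow(ind$network), w = ind$network,
         initial_state = ind$initial_state, stable_state = ind$stable_state,
         path_length = ind$path_length, params = unclass(params)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_individual
#' @export
read_individual <- function(path, verify = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("w", "initial_state", "stable_state", "path_length")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    abort(sprintf("Individual file %s lacks fields: %s", path,
                  paste(missing, collapse = ", ")))
  w <- as.matrix(obj$w)
  storage.mode(w) <- "double"
  check_network(w)
  params <- if (!is.null(obj$params)) do.call(model_params, as.list(obj$params))
            else model_params()
  ind <- structure(
    list(network = w, initial_state = as.numeric(obj$initial_state),
         stable_state = as.numeric(obj$stable_state),
         path_length = as.integer(obj$path_length), attempts = NA_integer_),
    class = "grn_individual")
  check_state(ind$initial_state, nrow(w))
  check_state(ind$stable_state, nrow(w))
  if (isTRUE(verify)) {
    dev <- develop(w, ind$initial_state, params)
    if (!dev$viable)
      abort(sprintf("Re-verification failed: %s does not develop to stability.", path))
    if (state_distance(dev$final_state, ind$stable_state) >= params$sigma)
      abort(sprintf("Re-verification failed: stored stable state of %s is not reproduced.", path))
  }
  ind
}

#' Write and read populations as JSON lines
#'
#' One JSON individual per line; a sidecar `<path>.manifest.json` records the
#' size, gene count and parameters.
#'
#' @param population A `grn_population`.
#' @param path Output path (`.jsonl`).
#' @param params The generating [model_params()].
#' @return `read_population()` returns a `grn_population`.
#' @export
write_population <- function(population, path, params = model_params()) {
  params <- as_grn_params(params)
  lines <- vapply(population, function(ind)
    as.character(jsonlite::toJSON(
      list(n = nrow(ind$network), w = ind$network,
           initial_state = ind$initial_state,
           stable_state = ind$stable_state, path_length = ind$path_length),
      auto_unbox = TRUE, digits = NA)), character(1))
  writeLines(lines, path)
  jsonlite::write_json(
    list(size = length(population), n = attr(population, "n"),
         attempts = attr(population, "attempts"), params = unclass(params)),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  lines <- readLines(path)
  pop <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    w <- as.matrix(obj$w)
    storage.mode(w) <- "double"
    structure(list(network = w, initial_state = as.numeric(obj$initial_state),
                   stable_state = as.numeric(obj$stable_state),
                   path_length = as.integer(obj$path_length),
                   attempts = NA_integer_),
              class = "grn_individual")
  })
  structure(pop, class = "grn_population", n = nrow(pop[[1]]$network),
            attempts = NA_integer_)
}
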