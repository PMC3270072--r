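develop_offspring <- function(w, s0, source, index = NA_integer_,
                              params = model_params()) {
  dev <- develop(w, s0, params)
  structure(
    list(offspring_network = w, offspring_initial_state = as.numeric(s0),
         source = source, index = index, viable = dev$viable, result = dev),
    class = if (source %in% c("haploid", "diploid")) c("grn_mating", "grn_offspring")
            else c("grn_indel", "grn_offspring")
  )
}

#' @export
print.grn_offspring <- function(x, ...) {
  cat(sprintf("<%s offspring> n = %d, %s\n", x$source, nrow(x$offspring_network),
              if (x$viable) sprintf("viable (path length %d)", x$result$path_length)
              else "not viable"))
  invisible(x)
}

#' Tidy an offspring outcome
#'
#' @param x A `grn_mating` or `grn_indel` outcome from one of the evolution
#'   operators.
#' @param ... Unused.
#' @return A one-row tibble with `source`, `n`, `viable`, `path_length`, and
#'   (for insertions/duplications/deletions) the gene `index` acted on.
#' @export
tidy.grn_offspring <- function(x, ...) {
  tibble(source = x$source, n = nrow(x$offspring_network), viable = x$viable,
         path_length = x$result$path_length, index = x$index)
}

pick_parent_state <- function(mother, father) {
  if (runif(1) < 0.5) mother$stable_state else father$stable_state
}

#' Haploid mating: whole-row inheritance
#'
#' Each gene (row of the interaction matrix) of the offspring is copied
#' verbatim from the corresponding row of one parent, chosen independently
#' with probability 1/2 — genes pass between generations unmodified. The
#' offspring's initial expression state is the stable state of one parent
#' chosen uniformly, reflecting maternal provisioning of gene products; the
#' offspring is then developed and its viability recorded.
#'
#' @param mother,father `grn_individual` objects with networks of equal size.
#' @param params A [model_params()] object.
#' @param rows Optional integer vector (values 1 = mother, 2 = father) of
#'   length `n` forcing the row origins; mainly for deterministic tests.
#' @return A `grn_mating` outcome: list with `offspring_network`,
#'   `offspring_initial_state`, `source`, `viable` and the full `result` of
#'   [develop()]. Use [tidy()] for a one-row tibble.
#' @examples
#' set.seed(11)
#' pop <- generate_population(4, 2)
#' mate_haploid(pop[[1]], pop[[2]])
#' @export
mate_haploid <- function(mother, father, params = model_params(), rows = NULL) {
  mother <- as_individual(mother); father <- as_individual(father)
  n <- nrow(mother$network)
  if (nrow(father$network) != n)
    abort(sprintf("Parents differ in size (%d vs %d genes).",
                  n, nrow(father$network)))
  if (is.null(rows)) rows <- sample(1:2, n, replace = TRUE)
  if (length(rows) != n || !all(rows %in% 1:2))
    abort("`rows` must be a length-n vector of 1s (mother) and 2s (father).")
  w <- mother$network
  w[rows == 2, ] <- father$network[rows == 2, , drop = FALSE]
  develop_offspring(w, pick_parent_state(mother, father), "haploid",
                    params = params)
}

#' Diploid mating: additive gene action
#'
#' Every entry of the offspring's interaction matrix is the arithmetic mean of
#' the corresponding parental entries, modelling purely additive effects on
#' expression (dominance, parent-of-origin and epistatic effects are ignored).
#' Averaging tempers extreme parental interaction strengths, which is what
#' makes this mode markedly better than haploid mating at preserving viability
#' in large networks. The initial state convention is the same as in
#' [mate_haploid()]: the stable state of a uniformly chosen parent.
#'
#' @inheritParams mate_haploid
#' @return A `grn_mating` outcome, as in [mate_haploid()].
#' @export
mate_diploid <- function(mother, father, params = model_params()) {
  mother <- as_individual(mother); father <- as_individual(father)
  n <- nrow(mother$network)
  if (nrow(father$network) != n)
    abort(sprintf("Parents differ in size (%d vs %d genes).",
                  n, nrow(father$network)))
  w <- (mother$network + father$network) / 2
  develop_offspring(w, pick_parent_state(mother, father), "diploid",
                    params = params)
}

insert_at <- function(w, stable, k, new_row, new_col, self, new_s) {
  n <- nrow(w)
  w2 <- matrix(0, n + 1, n + 1)
  old_idx <- setdiff(seq_len(n + 1), k)
  w2[old_idx, old_idx] <- w
  w2[k, old_idx] <- new_row
  w2[old_idx, k] <- new_col
  w2[k, k] <- self
  s2 <- append(stable, new_s, after = k - 1)
  list(w = w2, s = s2)
}

#' Random gene insertion
#'
#' Adds a brand-new gene at a uniformly random position: its whole row
#' (effects of every gene on it) and whole column (its effects on every
#' pre-existing gene), including its self-interaction, are drawn i.i.d.
#' Uniform `[-1, 1]`; all pre-existing interactions are untouched. The
#' offspring develops from the parent's *stable* state extended with one new
#' Uniform `[-1, 1]` element — the initial concentration of the new gene's
#' product.
#'
#' @param parent A viable `grn_individual`.
#' @param params A [model_params()] object.
#' @return A `grn_indel` outcome with `index` the position of the new gene and
#'   an `(n+1) x (n+1)` offspring network.
#' @export
insert_gene <- function(parent, params = model_params()) {
  parent <- as_individual(parent)
  n <- nrow(parent$network)
  k <- sample.int(n + 1, 1)
  ins <- insert_at(parent$network, parent$stable_state, k,
                   new_row = runif(n, -1, 1), new_col = runif(n, -1, 1),
                   self = runif(1, -1, 1), new_s = runif(1, -1, 1))
  develop_offspring(ins$w, ins$s, "insertion", index = k, params = params)
}

#' Random gene duplication
#'
#' Duplication of a uniformly chosen gene `g`: a full copy of its row (inputs)
#' and column (outputs), with the copy's self-interaction and both
#' copy-original couplings equal to `w[g, g]`, and the starting expression
#' vector carrying a duplicate of gene `g`'s stable level.
#'
#' Two placements of the copy are provided. `"overwrite"` (the default, and
#' what the experiment runners use) writes the copy over a second, uniformly
#' chosen gene `h != g`, so the genome ends up with two copies of gene `g` and
#' the network size is unchanged — duplication-with-turnover. Its measured
#' viability signature is what distinguishes duplication from plain insertion:
#' the success rate is approximately constant in network size instead of
#' decaying. `"append"` grows the network to `n + 1` genes with the copy as
#' the last gene (its position is irrelevant to viability because the
#' dynamics are equivariant under gene relabelling); appending a literal copy
#' is considerably gentler than a random insertion and its success rate
#' decays with size like insertion's.
#'
#' @inheritParams insert_gene
#' @param mode `"overwrite"` (copy replaces a random other gene, size
#'   preserved) or `"append"` (size grows to `n + 1`).
#' @param zero_coupling Variant flag: set the two copy-original coupling
#'   entries to 0 instead of `w[g, g]` (the copy and the original do not
#'   regulate each other directly).
#' @return A `grn_indel` outcome with `index` the duplicated gene (and, for
#'   `"overwrite"`, attribute-free: the replaced slot is drawn internally).
#' @export
duplicate_gene <- function(parent, params = model_params(),
                           mode = c("overwrite", "append"),
                           zero_coupling = FALSE) {
  parent <- as_individual(parent)
  mode <- match.arg(mode)
  w <- parent$network
  n <- nrow(w)
  if (mode == "append") {
    g <- sample.int(n, 1)
    w2 <- rbind(cbind(w, w[, g]), c(w[g, ], w[g, g]))
    if (zero_coupling) {
      w2[n + 1, g] <- 0
      w2[g, n + 1] <- 0
    }
    s2 <- c(parent$stable_state, parent$stable_state[g])
  } else {
    if (n < 2) abort("Overwrite duplication needs at least 2 genes.")
    gh <- sample.int(n, 2)
    g <- gh[1]; h <- gh[2]
    w2 <- w
    w2[h, ] <- w[g, ]        # copy's inputs; also sets coupling w2[h, g] = w[g, g]
    w2[, h] <- w[, g]        # copy's outputs; also sets coupling w2[g, h] = w[g, g]
    w2[h, h] <- w[g, g]      # copy's self-interaction
    if (zero_coupling) {
      w2[h, g] <- 0
      w2[g, h] <- 0
    }
    s2 <- parent$stable_state
    s2[h] <- s2[g]
  }
  develop_offspring(w2, s2, "duplication", index = g, params = params)
}

#' Random gene deletion
#'
#' Removes a uniformly chosen gene: its row and column are struck from the
#' network and its entry from the expression vector. The reduced individual
#' develops from the parent's stable state with the deleted gene's level
#' removed.
#'
#' @inheritParams insert_gene
#' @return A `grn_indel` outcome with `index` the deleted gene and an
#'   `(n-1) x (n-1)` offspring network.
#' @export
delete_gene <- function(parent, params = model_params()) {
  parent <- as_individual(parent)
  n <- nrow(parent$network)
  if (n < 2) abort("Cannot delete the last gene of a 1-gene network.")
  g <- sample.int(n, 1)
  w2 <- parent$network[-g, -g, drop = FALSE]
  s2 <- parent$stable_state[-g]
  develop_offspring(w2, s2, "deletion", index = g, params = params)
}
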