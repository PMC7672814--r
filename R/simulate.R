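#' @noRd
core_symbols <- function(alphabet) {
  if (alphabet$kind == "dna") c("A", "C", "G", "T")
  else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

# per-site substitution with current RNG stream; each hit is replaced by a
# uniformly chosen *different* core symbol
mutate_chars <- function(chars, p, core) {
  n <- length(chars)
  hits <- which(stats::runif(n) < p)
  if (length(hits) > 0) {
    cur <- match(chars[hits], core)
    step <- sample(length(core) - 1L, length(hits), replace = TRUE)
    repl <- ifelse(is.na(cur),
                   core[sample(length(core), length(hits), replace = TRUE)],
                   core[(cur - 1L + step) %% length(core) + 1L])
    chars[hits] <- repl
  }
  chars
}

#' Uniform mutation model
#'
#' Per-site independent substitutions at a fixed probability; a substituted
#' site receives a uniformly chosen *different* symbol (a Jukes-Cantor-like
#' scheme).  Identical seeds reproduce identical outputs bit for bit.
#'
#' @param substitution_probability per-site probability in `[0, 1]`.
#' @param alphabet alphabet specification (default `"dna"`).
#' @param seed integer seed.
#' @return an object of class `acs_mutmodel`.
#' @export
mutation_model <- function(substitution_probability, alphabet = "dna", seed = 1L) {
  stopifnot(substitution_probability >= 0, substitution_probability <= 1)
  alphabet <- resolve_alphabet(alphabet)
  if (alphabet$kind == "auto")
    stop("simulate: mutation model needs a concrete alphabet", call. = FALSE)
  structure(list(substitution_probability = substitution_probability,
                 alphabet = alphabet, seed = as.integer(seed)),
            class = "acs_mutmodel")
}

#' Random i.i.d. sequence
#'
#' Uniform i.i.d. draws over the alphabet's core symbols (`A C G T` for DNA,
#' the 20 amino acids for protein; ambiguity codes are accepted on input but
#' never generated).  A pure function of its seed.
#'
#' @param length number of residues (`>= 1`).
#' @param alphabet alphabet specification (default `"dna"`).
#' @param seed integer seed.
#' @return an `acs_record`.
#' @examples
#' random_sequence(8, seed = 7)$residues
#' @export
random_sequence <- function(length, alphabet = "dna", seed = 1L) {
  if (length < 1) stop("simulate: length must be >= 1", call. = FALSE)
  alphabet <- resolve_alphabet(alphabet)
  if (alphabet$kind == "auto")
    stop("simulate: random_sequence needs a concrete alphabet", call. = FALSE)
  core <- core_symbols(alphabet)
  res <- withr::with_seed(seed,
    paste(sample(core, length, replace = TRUE), collapse = ""))
  sequence_record(sprintf("sim_l%d_s%d", length, seed), res, alphabet)
}

#' Mutate a record under a model
#'
#' @param record an `acs_record` (or residue string).
#' @param model an [mutation_model()]; alternatively a bare probability, in
#'   which case `seed` supplies the randomness.
#' @param seed seed used when `model` is a bare probability.
#' @return the mutated `acs_record` (same length, name suffixed `|mut`).
#' @examples
#' mutate_sequence(random_sequence(20, seed = 1), mutation_model(0.1, seed = 2))
#' @export
mutate_sequence <- function(record, model, seed = 1L) {
  record <- as_record(record)
  if (is.numeric(model)) model <- mutation_model(model, record$alphabet, seed)
  stopifnot(inherits(model, "acs_mutmodel"))
  core <- core_symbols(model$alphabet)
  chars <- strsplit(record$residues, "")[[1]]
  out <- withr::with_seed(model$seed,
    mutate_chars(chars, model$substitution_probability, core))
  sequence_record(paste0(record$name, "|mut"), paste(out, collapse = ""),
                  record$alphabet)
}

#' Simulate a clock tree and sequences evolved along it
#'
#' Draws a random bifurcating coalescent (clock) tree over `num_taxa` tips,
#' assigns the root an i.i.d. random sequence, and applies one round of
#' per-site substitution at probability `rate` along every branch.  The
#' per-branch rate is constant (branch lengths are topology bookkeeping
#' only), which keeps expected pairwise divergence proportional to path
#' edge counts -- an additive-enough regime for neighbor joining to recover
#' the generating topology at low rates.  Everything is a pure function of
#' `seed`.
#'
#' @param num_taxa number of tips (`>= 4`).
#' @param seq_length root sequence length.
#' @param rate per-branch substitution probability.
#' @param seed integer seed.
#' @param alphabet alphabet specification (default `"dna"`).
#' @return list with `tree` (the true [ape::phylo]) and `records` (leaf
#'   `acs_record`s in tip-label order).
#' @examples
#' sim <- simulate_tree_and_sequences(4, 200, 0.05, seed = 3)
#' sim$tree$tip.label
#' @export
simulate_tree_and_sequences <- function(num_taxa, seq_length, rate, seed = 1L,
                                        alphabet = "dna") {
  if (num_taxa < 4) stop("simulate: need at least 4 taxa", call. = FALSE)
  if (seq_length < 1) stop("simulate: seq_length must be >= 1", call. = FALSE)
  if (rate < 0 || rate > 1) stop("simulate: rate must be in [0, 1]", call. = FALSE)
  alphabet <- resolve_alphabet(alphabet)
  core <- core_symbols(alphabet)
  withr::with_seed(as.integer(seed), {
    tree <- ape::rcoal(num_taxa, tip.label = sprintf("t%02d", seq_len(num_taxa)))
    tree <- ape::reorder.phylo(tree, "cladewise")
    nnode <- num_taxa + tree$Nnode
    seqs <- vector("list", nnode)
    root <- num_taxa + 1L
    seqs[[root]] <- sample(core, seq_length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      seqs[[child]] <- mutate_chars(seqs[[parent]], rate, core)
    }
    records <- lapply(seq_len(num_taxa), function(i) {
      sequence_record(tree$tip.label[i], paste(seqs[[i]], collapse = ""), alphabet)
    })
    list(tree = tree, records = records)
  })
}
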