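#' Sequence alphabets
#'
#' Defines the residue alphabets over which sequences are validated.  The
#' `dna` alphabet is `A C G T N`; the `protein` alphabet is the twenty amino
#' acid letters plus the ambiguity/rare codes `X B Z U O`.  `auto` defers the
#' choice to file content: a record whose residues all fall in the DNA
#' alphabet is treated as DNA, anything else as protein.  Ambiguity codes
#' (`N`, `X`, ...) are ordinary symbols here: they match only themselves and
#' count as mismatches against everything else, since the k-mismatch
#' machinery has no wildcard semantics.
#'
#' @param kind one of `"dna"`, `"protein"`, `"auto"`.
#' @return an object of class `acs_alphabet` with fields `kind` and
#'   `symbols` (character vector; empty for `"auto"` until resolved).
#' @examples
#' acs_alphabet("dna")$symbols
#' @export
acs_alphabet <- function(kind = c("dna", "protein", "auto")) {
  kind <- match.arg(kind)
  symbols <- switch(kind,
    dna = c("A", "C", "G", "T", "N"),
    protein = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                c("X", "B", "Z", "U", "O")),
    auto = character(0))
  structure(list(kind = kind, symbols = symbols), class = "acs_alphabet")
}

resolve_alphabet <- function(alphabet, residues = NULL) {
  if (is.character(alphabet)) alphabet <- acs_alphabet(alphabet)
  if (!inherits(alphabet, "acs_alphabet")) {
    stop("`alphabet` must be an acs_alphabet or one of \"dna\", \"protein\", \"auto\"",
         call. = FALSE)
  }
  if (alphabet$kind == "auto") {
    if (is.null(residues)) return(alphabet)
    chars <- unique(strsplit(residues, "")[[1]])
    kind <- if (all(chars %in% acs_alphabet("dna")$symbols)) "dna" else "protein"
    alphabet <- acs_alphabet(kind)
  }
  alphabet
}

validate_residues <- function(residues, alphabet, name) {
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!(chars %in% alphabet$symbols))
  if (length(bad) > 0) {
    stop(sprintf("seqio: record '%s' has residue '%s' at position %d outside the %s alphabet",
                 name, chars[bad[1]], bad[1], alphabet$kind), call. = FALSE)
  }
  invisible(TRUE)
}

#' Create a sequence record
#'
#' A record couples a unique name with a residue string over a declared
#' alphabet.  Residues are folded to upper case before validation.
#'
#' @param name non-empty label.
#' @param residues character scalar of length >= 1.
#' @param alphabet an [acs_alphabet()] or one of `"dna"`, `"protein"`,
#'   `"auto"` (the default infers DNA vs protein from the residues).
#' @return an object of class `acs_record` with fields `name`, `residues`,
#'   `alphabet`.
#' @examples
#' sequence_record("x", "acgt")
#' @export
sequence_record <- function(name, residues, alphabet = "auto") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("seqio: record name must be a non-empty string", call. = FALSE)
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop(sprintf("seqio: record '%s' has no residues", name), call. = FALSE)
  residues <- toupper(residues)
  alphabet <- resolve_alphabet(alphabet, residues)
  validate_residues(residues, alphabet, name)
  structure(list(name = name, residues = residues, alphabet = alphabet),
            class = "acs_record")
}

#' @export
print.acs_record <- function(x, ...) {
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(sprintf("<acs_record> %s  (%s, %d residues)\n  %s\n",
              x$name, x$alphabet$kind, nchar(x$residues), res))
  invisible(x)
}

#' @export
length.acs_record <- function(x) nchar(x$residues)

as_record <- function(x, name = "seq") {
  if (inherits(x, "acs_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(sequence_record(name, x))
  stop("expected an acs_record or a single residue string", call. = FALSE)
}

#' Read a multi-FASTA file
#'
#' Records are returned in file order, residues upper-cased, wrapped lines
#' joined, and names taken as the header token up to the first whitespace.
#' Every record is validated against the requested alphabet; duplicate names
#' are an error because names key the distance matrix and PHYLIP output.
#'
#' @param path path to an existing FASTA file.
#' @param alphabet alphabet specification; see [sequence_record()].
#' @return list of `acs_record` objects.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "GG", "GG"), f)
#' recs <- read_fasta(f)
#' vapply(recs, function(r) r$residues, "")
#' @export
read_fasta <- function(path, alphabet = "auto") {
  if (!file.exists(path)) stop(sprintf("seqio: file '%s' not found", path), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("seqio: cannot parse '%s' as FASTA: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L)
    stop(sprintf("seqio: '%s' contains no FASTA records", path), call. = FALSE)
  headers <- names(set)
  names_tok <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1)
  if (anyDuplicated(names_tok)) {
    dup <- names_tok[duplicated(names_tok)][1]
    stop(sprintf("seqio: duplicate record name '%s' in '%s'", dup, path), call. = FALSE)
  }
  seqs <- unname(as.character(set))
  lapply(seq_along(set), function(i) {
    if (!nzchar(seqs[i]))
      stop(sprintf("seqio: record '%s' has no residues", names_tok[i]), call. = FALSE)
    sequence_record(names_tok[i], seqs[i], alphabet)
  })
}

#' Write records to a FASTA file
#'
#' @param records list of `acs_record` objects.
#' @param path output file path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "acs_record")) records <- list(records)
  stopifnot(length(records) >= 1L)
  seqs <- vapply(records, function(r) r$residues, "")
  names(seqs) <- vapply(records, function(r) r$name, "")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Reverse a record's residues
#'
#' Plain character-wise reversal (no complementation); used to pose backward
#' extension queries as forward queries on reversed strings.  The name gets a
#' `|rev` marker, which a second reversal removes, so the operation is an
#' involution.
#'
#' @param record an `acs_record`.
#' @return the reversed `acs_record`.
#' @examples
#' reverse_residues(sequence_record("s", "ACGT"))$residues
#' @export
reverse_residues <- function(record) {
  record <- as_record(record)
  rev_res <- paste(rev(strsplit(record$residues, "")[[1]]), collapse = "")
  marker <- "|rev"
  name <- if (endsWith(record$name, marker)) {
    substr(record$name, 1, nchar(record$name) - nchar(marker))
  } else {
    paste0(record$name, marker)
  }
  sequence_record(name, rev_res, record$alphabet)
}
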