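#' Build a generalized suffix-array index over a sequence pair
#'
#' Indexes the concatenation `X $1 Y $2`, where the two sentinels are
#' reserved characters that compare smaller than every residue and occur
#' exactly once each, so no common prefix between distinct suffixes ever
#' crosses a sequence boundary.  The index carries the suffix array, its
#' inverse (rank) array, the LCP array and a sparse-table range-minimum
#' structure, and therefore answers suffix-pair LCP queries in constant
#' time -- the role a generalized suffix tree plays in the textbook
#' formulation.  With `orientation = "reverse"` both sequences are reversed
#' first, which is how backward extensions are served.
#'
#' @param x,y `acs_record`s (or residue strings) over the same alphabet.
#' @param orientation `"forward"` or `"reverse"`.
#' @return an object of class `acs_index` with fields `text` (integer-coded,
#'   sentinels included), `boundary` (1-based position of the first
#'   sentinel), `suffix_array`, `inverse_array`, `lcp_array` (all 1-based),
#'   `rmq`, `orientation`, `x_length`, `y_length`.
#' @examples
#' ix <- build_index("ACGT", "ACGA")
#' ix$suffix_array
#' @export
build_index <- function(x, y, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  x <- as_record(x, "x"); y <- as_record(y, "y")
  if (nchar(x$residues) < 1L || nchar(y$residues) < 1L)
    stop("index: both sequences must be non-empty", call. = FALSE)
  if (orientation == "reverse") {
    x <- reverse_residues(x)
    y <- reverse_residues(y)
  }
  raw <- cpp_build_index(x$residues, y$residues)
  structure(list(
    text = raw$text,
    boundary = raw$boundary + 1L,
    suffix_array = raw$suffix_array + 1L,
    inverse_array = raw$inverse_array + 1L,
    lcp_array = raw$lcp_array,
    rmq = raw$rmq,
    orientation = orientation,
    x_length = nchar(x$residues),
    y_length = nchar(y$residues)
  ), class = "acs_index")
}

#' @export
print.acs_index <- function(x, ...) {
  cat(sprintf("<acs_index> %s text of %d positions (|X| = %d, |Y| = %d, 2 sentinels)\n",
              x$orientation, length(x$text), x$x_length, x$y_length))
  invisible(x)
}

#' Longest-common-prefix query between two suffixes of the indexed text
#'
#' Returns the exact LCP length of the suffixes starting at text positions
#' `a` and `b` (1-based over the sentinel-joined text).  Matches never
#' extend across a sentinel.  The `policy` flag chooses between walking the
#' text and a constant-time RMQ over the LCP array; it is a performance
#' knob only and never changes the returned value (`"auto"` walks and falls
#' back to RMQ past `threshold` characters).
#'
#' @param index an `acs_index`.
#' @param a,b distinct 1-based text positions.
#' @param policy `"walk"`, `"rmq"`, or `"auto"`.
#' @param threshold walk length at which `"auto"` switches to RMQ.
#' @return integer LCP length.
#' @export
lcp_query <- function(index, a, b, policy = c("auto", "walk", "rmq"),
                      threshold = 1024L) {
  stopifnot(inherits(index, "acs_index"))
  policy <- match.arg(policy)
  n <- length(index$text)
  if (a < 1 || a > n || b < 1 || b > n)
    stop("index: text position out of range", call. = FALSE)
  if (a == b) stop("index: positions must be distinct", call. = FALSE)
  pol <- c(walk = 0L, rmq = 1L, auto = 2L)[[policy]]
  cpp_lcp_query(index$text, index$inverse_array - 1L, index$lcp_array,
                index$rmq, as.integer(a) - 1L, as.integer(b) - 1L,
                pol, as.integer(threshold))
}

#' Exact matching statistics of X against Y
#'
#' For every position `i` of `X` computes `lambda(i)`, the length of the
#' longest exact common prefix between the suffix `X_i` and any suffix of
#' `Y`, together with *all* positions `j` in `Y` attaining it (ascending) --
#' the anchor set that every heuristic extends.  `mu(i)` is the smallest
#' attaining `j`, `NA` when `lambda(i) = 0`.
#'
#' @param x,y `acs_record`s or residue strings.
#' @param anchor_limit optional cap on the number of tie positions kept per
#'   `i` (applied in ascending-`j` order); `Inf` keeps all.
#' @return an object of class `acs_ms` with fields `lambda` (integer vector
#'   of length `|X|`), `mu` (1-based, `NA` where undefined),
#'   `match_positions` (list of 1-based integer vectors) and `z` (mean
#'   number of maximal matches over positions with `lambda > 0`).
#' @examples
#' ms <- matching_statistics("CATTGCATACGA", "ATGGATCCAATAG")
#' ms$lambda[4]; ms$mu[4]
#' @export
matching_statistics <- function(x, y, anchor_limit = Inf) {
  x <- as_record(x, "x"); y <- as_record(y, "y")
  lim <- if (is.finite(anchor_limit)) as.integer(anchor_limit) else 0L
  raw <- cpp_matching_statistics(x$residues, y$residues, lim)
  structure(list(
    lambda = raw$lambda,
    mu = ifelse(is.na(raw$mu), NA_integer_, raw$mu + 1L),
    match_positions = lapply(raw$match_positions, function(v) v + 1L),
    z = raw$z
  ), class = "acs_ms")
}

#' @export
print.acs_ms <- function(x, ...) {
  cat(sprintf("<acs_ms> matching statistics over %d positions; mean lambda %.2f, z = %.2f\n",
              length(x$lambda), mean(x$lambda), x$z))
  invisible(x)
}
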