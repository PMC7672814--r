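#' k-mismatch longest common prefix by direct walk
#'
#' Length of the maximal `L` such that `X[i..i+L-1]` and `Y[j..j+L-1]`
#' differ in at most `k` positions, stopping at either sequence end.  This
#' walk is the elementary oracle everything else is checked against: a
#' k-mismatch LCP is identical to a chain of `k + 1` exact LCPs separated by
#' skipped mismatches.
#'
#' @param x,y `acs_record`s or residue strings.
#' @param i,j 1-based start positions in `X` and `Y`.
#' @param k mismatch budget, `>= 0`.
#' @return integer match length.
#' @examples
#' lcp_k_walk("AATCGGT", "AACCGGT", 1, 1, k = 1)  # 7
#' @export
lcp_k_walk <- function(x, y, i, j, k) {
  x <- as_record(x, "x"); y <- as_record(y, "y")
  cpp_lcp_k_walk(x$residues, y$residues, as.integer(i) - 1L,
                 as.integer(j) - 1L, as.integer(k))
}

#' Exact lambda_k by brute force
#'
#' Computes `lambda_k(i) = max_j LCP_k(X_i, Y_j)` for every position of `X`
#' by trying all `j` -- the quadratic ground-truth oracle used to score the
#' heuristics.  Work is metered in character comparisons and aborts once
#' `cap` is exceeded, so short-`k` walks on moderately long pairs still run
#' while genome-scale requests are refused with a pointer to the heuristics.
#'
#' @param x,y `acs_record`s or residue strings.
#' @param k mismatch budget, `>= 0`.
#' @param cap maximum number of character comparisons (`Inf` to disable).
#' @return a [lambda_approx] object with `method = "exact"`; `witnesses`
#'   holds the smallest attaining `j` (1-based).
#' @examples
#' exact_lambda("CATTGCATACGA", "ATGGATCCAATAG", k = 2)$values[4]  # 7
#' @export
exact_lambda <- function(x, y, k, cap = 1e7) {
  x <- as_record(x, "x"); y <- as_record(y, "y")
  stopifnot(k >= 0)
  capv <- if (is.finite(cap)) as.numeric(cap) else 0
  raw <- cpp_exact_lambda(x$residues, y$residues, as.integer(k), capv)
  new_lambda_approx(
    method = "exact", k = as.integer(k), values = raw$values,
    witnesses = ifelse(is.na(raw$witness), NA_integer_, raw$witness + 1L),
    options = list(cap = cap),
    diagnostics = list(comparisons = raw$comparisons))
}
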