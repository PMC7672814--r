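#' Per-position lambda_k estimates
#'
#' Container for a per-position array of k-mismatch match-length values
#' produced by one method (`kmacs`, `alfredg`, `adyar`, or `exact`).  With
#' the LCP-0 fallback off, every value is the length of a genuine
#' `<= k`-mismatch common substring starting at that position of `X`
#' (witness-verifiable through [lcp_k_walk()]), hence a lower bound on the
#' exact `lambda_k(i)`.
#'
#' @param method method tag.
#' @param k mismatch budget.
#' @param values integer vector of length `|X|`.
#' @param witnesses 1-based start positions in `Y` (`NA` where no witnessed
#'   match exists, e.g. under the fallback).
#' @param options list of the options the method ran with.
#' @param diagnostics list of run diagnostics (e.g. `z`, the mean maximal
#'   match multiplicity).
#' @return object of class `acs_lambda`.
#' @name lambda_approx
NULL

new_lambda_approx <- function(method, k, values, witnesses = NULL,
                              options = list(), diagnostics = list()) {
  structure(list(method = method, k = k, values = as.integer(values),
                 witnesses = witnesses, options = options,
                 diagnostics = diagnostics),
            class = "acs_lambda")
}

#' @export
print.acs_lambda <- function(x, ...) {
  cat(sprintf("<acs_lambda> method %s, k = %d, %d positions, mean value %.3f\n",
              x$method, x$k, length(x$values), mean(x$values)))
  invisible(x)
}

chain_opts <- function(ties, fallback, anchor_limit) {
  list(tie_policy = ties, fallback = if (fallback) "on" else "off",
       anchor_limit = if (is.finite(anchor_limit)) anchor_limit else "unlimited")
}

#' Forward extension chain from an anchor
#'
#' `L_f[m + 1]` (1-based R indexing of the returned vector, budgets
#' `m = 0..k`) is the greedy `<= m`-mismatch extension length from the pair
#' of positions `(i, j)`: the exact LCP, then repeatedly one skipped
#' mismatch plus the next exact LCP, truncated at either sequence end (no
#' mismatch is consumed past an end).
#'
#' @param x,y `acs_record`s or residue strings.
#' @param i,j 1-based anchor positions in `X`, `Y`.
#' @param k mismatch budget.
#' @return integer vector of `k + 1` nondecreasing lengths.
#' @examples
#' forward_chain("CATTGCATACGA", "ATGGATCCAATAG", 4, 2, k = 2)  # 2 5 7
#' @export
forward_chain <- function(x, y, i, j, k) {
  x <- as_record(x, "x"); y <- as_record(y, "y")
  cpp_forward_chain(x$residues, y$residues, as.integer(i) - 1L,
                    as.integer(j) - 1L, as.integer(k))
}

#' Backward extension chain from an anchor
#'
#' Same chain semantics as [forward_chain()] applied leftwards to the
#' characters strictly before `(i, j)`; equivalently, a forward chain on the
#' reversed strings.  `L_r[m + 1] <= min(i - 1, j - 1)`.
#'
#' @inheritParams forward_chain
#' @return integer vector of `k + 1` nondecreasing lengths.
#' @examples
#' backward_chain("AATCGGT", "AATGGGAAACCGGT", 4, 11, k = 1)  # 0 3
#' @export
backward_chain <- function(x, y, i, j, k) {
  x <- as_record(x, "x"); y <- as_record(y, "y")
  cpp_backward_chain(x$residues, y$residues, as.integer(i) - 1L,
                     as.integer(j) - 1L, as.integer(k))
}

#' kmacs greedy lambda_k approximation
#'
#' For each position `i`, anchors at the maximal exact matches of `X_i` in
#' `Y` and extends forward through `k` skipped mismatches:
#' `lambda(i) + 1 + |LCP_(k-1)| after the first mismatch`, iterated.  With
#' `ties = "all"` every maximal anchor position is tried and the longest
#' extension kept; `ties = "first"` uses only the smallest `j` (the classic
#' single-anchor behavior).  At `k = 0` this is the exact matching
#' statistic.
#'
#' @param x,y `acs_record`s or residue strings.
#' @param k mismatch budget `>= 0`.
#' @param ties `"all"` or `"first"` anchor policy.
#' @param fallback copy the estimate of suffix `X_(i+1)` onto positions with
#'   no exact match anywhere in `Y` (`lambda(i) = 0`); such copied values
#'   are estimates, not witnessed matches.
#' @param anchor_limit cap on anchors tried per position (`Inf` = all).
#' @return a [lambda_approx] object.
#' @examples
#' kmacs_lambda("CATTGCATACGA", "ATGGATCCAATAG", k = 2)$values[4]  # 7
#' @export
kmacs_lambda <- function(x, y, k, ties = c("all", "first"), fallback = FALSE,
                         anchor_limit = Inf) {
  ties <- match.arg(ties)
  x <- as_record(x, "x"); y <- as_record(y, "y")
  stopifnot(k >= 0)
  lim <- if (is.finite(anchor_limit)) as.integer(anchor_limit) else 0L
  raw <- cpp_kmacs(x$residues, y$residues, as.integer(k), ties == "all",
                   lim, fallback)
  new_lambda_approx("kmacs", as.integer(k), raw$values,
                    ifelse(is.na(raw$witness), NA_integer_, raw$witness + 1L),
                    chain_opts(ties, fallback, anchor_limit),
                    list(z = raw$z))
}

#' ALFRED-G lambda_k approximation
#'
#' Anchors at the maximal 1-mismatch match (`lambda_1(i)` at `mu_1(i)`,
#' taken from the brute-force oracle) and extends forward with the remaining
#' `k - 2` budget after one more skipped mismatch.  Requires `k >= 2` and an
#' input small enough for the exact `lambda_1` oracle.
#'
#' @inheritParams kmacs_lambda
#' @param cap comparison cap forwarded to [exact_lambda()] for the
#'   1-mismatch anchor.
#' @return a [lambda_approx] object.
#' @export
alfredg_lambda <- function(x, y, k, cap = 1e7) {
  x <- as_record(x, "x"); y <- as_record(y, "y")
  if (k < 2) stop("heuristics: ALFRED-G requires k >= 2", call. = FALSE)
  capv <- if (is.finite(cap)) as.numeric(cap) else 0
  raw <- cpp_alfredg(x$residues, y$residues, as.integer(k), capv)
  new_lambda_approx("alfredg", as.integer(k), raw$values,
                    ifelse(is.na(raw$witness), NA_integer_, raw$witness + 1L),
                    list(cap = cap))
}

#' Two-phase forward/backward lambda_k approximation, phase 1
#'
#' Phase 1 of the forward/backward extension heuristic: every maximal exact
#' anchor `(i, j)` is extended forward and backward, splitting the mismatch
#' budget as `t` backward plus `k - t` forward for `t = 0..k`, and each
#' candidate of length `L_r[t] + L_f[k-t]` is credited to its true start
#' position `i - L_r[t]`.  Positions never reached stay 0 until phase 2.
#'
#' @inheritParams kmacs_lambda
#' @return a partial [lambda_approx] object (`method = "adyar"`).
#' @export
adyar_phase1 <- function(x, y, k, ties = c("all", "first"),
                         anchor_limit = Inf) {
  ties <- match.arg(ties)
  x <- as_record(x, "x"); y <- as_record(y, "y")
  stopifnot(k >= 0)
  lim <- if (is.finite(anchor_limit)) as.integer(anchor_limit) else 0L
  raw <- cpp_adyar(x$residues, y$residues, as.integer(k), ties == "all",
                   lim, FALSE, FALSE, FALSE)
  new_lambda_approx("adyar", as.integer(k), raw$values,
                    ifelse(is.na(raw$witness), NA_integer_, raw$witness + 1L),
                    c(chain_opts(ties, FALSE, anchor_limit), list(phase = 1L)),
                    list(z = raw$z))
}

#' Two-phase forward/backward lambda_k approximation, phase 2
#'
#' One left-to-right pass applying
#' `values[i] <- max(values[i], values[i-1] - 1)`: dropping the first
#' character of any genuine `<= k`-mismatch match yields a genuine match one
#' shorter, so the pass is applied unconditionally and preserves soundness.
#'
#' @param partial the phase-1 [lambda_approx].
#' @return the updated [lambda_approx].
#' @export
adyar_phase2 <- function(partial) {
  stopifnot(inherits(partial, "acs_lambda"))
  v <- partial$values
  w <- partial$witnesses
  if (length(v) > 1) {
    for (i in 2:length(v)) {
      if (v[i - 1] - 1L > v[i]) {
        v[i] <- v[i - 1] - 1L
        if (!is.null(w)) w[i] <- if (is.na(w[i - 1])) NA_integer_ else w[i - 1] + 1L
      }
    }
  }
  partial$values <- v
  partial$witnesses <- w
  partial$options$phase <- 2L
  partial
}

#' Two-phase forward/backward lambda_k approximation
#'
#' The full heuristic: phase 1 ([adyar_phase1()]), phase 2
#' ([adyar_phase2()]), and optionally the LCP-0 fallback -- a right-to-left
#' pass copying the estimate of `X_(i+1)` onto every position whose exact
#' anchor LCP is 0.  Because anchors may sit anywhere inside a k-mismatch
#' match, the backward extension can credit long matches to start positions
#' that forward-only greedy methods (kmacs) never see.
#'
#' @inheritParams kmacs_lambda
#' @param guard apply the phase-2 update only when the dropped character is
#'   not one of the preceding match's mismatch characters (fidelity variant;
#'   the default unguarded pass is never worse as a lower bound).
#' @return a [lambda_approx] object.
#' @examples
#' adyar_lambda("AATCGGT", "AATGGGAAACCGGT", k = 1)$values[1]  # 7 (kmacs: 6)
#' @export
adyar_lambda <- function(x, y, k, ties = c("all", "first"), fallback = FALSE,
                         anchor_limit = Inf, guard = FALSE) {
  ties <- match.arg(ties)
  x <- as_record(x, "x"); y <- as_record(y, "y")
  stopifnot(k >= 0)
  lim <- if (is.finite(anchor_limit)) as.integer(anchor_limit) else 0L
  raw <- cpp_adyar(x$residues, y$residues, as.integer(k), ties == "all",
                   lim, fallback, guard, TRUE)
  new_lambda_approx("adyar", as.integer(k), raw$values,
                    ifelse(is.na(raw$witness), NA_integer_, raw$witness + 1L),
                    c(chain_opts(ties, fallback, anchor_limit),
                      list(guard = guard)),
                    list(z = raw$z))
}

lambda_method <- function(x, y, k, method, ties = "all", fallback = TRUE,
                          anchor_limit = Inf, cap = 1e7) {
  switch(method,
    adyar = adyar_lambda(x, y, k, ties = ties, fallback = fallback,
                         anchor_limit = anchor_limit),
    kmacs = kmacs_lambda(x, y, k, ties = ties, fallback = fallback,
                         anchor_limit = anchor_limit),
    alfredg = alfredg_lambda(x, y, k, cap = cap),
    exact = exact_lambda(x, y, k, cap = cap),
    stop(sprintf("unknown method '%s'", method), call. = FALSE))
}

#' Write a per-position lambda dump as TSV
#'
#' Columns: `position` (1-based), `method`, `k`, `value`, `witness`
#' (1-based or `-`).
#'
#' @param lam a [lambda_approx] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lambda_tsv <- function(lam, path) {
  stopifnot(inherits(lam, "acs_lambda"))
  wit <- if (is.null(lam$witnesses)) rep(NA_integer_, length(lam$values)) else lam$witnesses
  df <- data.frame(position = seq_along(lam$values), method = lam$method,
                   k = lam$k, value = lam$values,
                   witness = ifelse(is.na(wit), "-", as.character(wit)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
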