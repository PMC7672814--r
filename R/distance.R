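#' Average common substring value from a lambda array
#'
#' `ACS_k(X, Y)` is the arithmetic mean of the per-position match lengths
#' `lambda_k(i)` over `i = 1..|X|`.  Note the measure is direction-dependent:
#' `ACS_k(X, Y) != ACS_k(Y, X)` in general.
#'
#' @param lam a [lambda_approx] object (or bare numeric vector of values).
#' @param x_length expected length of the array; defaults to its actual
#'   length and is checked when supplied.
#' @return the ACS value (numeric scalar).
#' @examples
#' acs_from_lambda(c(2, 1))  # 1.5
#' @export
acs_from_lambda <- function(lam, x_length = NULL) {
  values <- if (inherits(lam, "acs_lambda")) lam$values else lam
  if (length(values) == 0) stop("distance: empty lambda array", call. = FALSE)
  if (!is.null(x_length) && length(values) != x_length)
    stop(sprintf("distance: lambda array has %d entries, expected %d",
                 length(values), x_length), call. = FALSE)
  mean(values)
}

log_base_value <- function(log_base) {
  if (is.numeric(log_base)) return(as.numeric(log_base))
  switch(as.character(log_base),
         e = exp(1), "2" = 2, "10" = 10,
         stop("distance: log_base must be one of 'e', '2', '10'", call. = FALSE))
}

#' ACS-based pair distance
#'
#' Combines the two directed ACS values into a symmetric dissimilarity:
#' \deqn{d(X,Y) = \frac{1}{2}\left(\frac{\log|Y|}{ACS(X,Y)} +
#'   \frac{\log|X|}{ACS(Y,X)}\right) - \left(\frac{\log|X|}{|X|} +
#'   \frac{\log|Y|}{|Y|}\right)}
#' The subtracted term is the self-match baseline, so `d` is close to zero
#' (and slightly negative) for identical sequences.  The logarithm base is a
#' uniform rescaling that cannot change neighbor-joining topology; natural
#' log is the default.
#'
#' @param x_len,y_len sequence lengths (`>= 2`).
#' @param acs_xy,acs_yx directed ACS values.
#' @param log_base `"e"` (default), `"2"`, or `"10"`.
#' @return numeric distance; `+Inf` with a warning when either ACS is zero.
#' @examples
#' acs_distance(100, 100, 50.5, 50.5)  # self-distance, about -9.119e-4
#' @export
acs_distance <- function(x_len, y_len, acs_xy, acs_yx, log_base = "e") {
  stopifnot(x_len >= 2, y_len >= 2, acs_xy >= 0, acs_yx >= 0)
  b <- log_base_value(log_base)
  if (acs_xy == 0 || acs_yx == 0) {
    warning("distance: ACS value of 0; no finite distance exists, returning Inf",
            call. = FALSE)
    return(Inf)
  }
  0.5 * (log(y_len, b) / acs_xy + log(x_len, b) / acs_yx) -
    (log(x_len, b) / x_len + log(y_len, b) / y_len)
}

#' Pairwise ACS_k distance matrix over a sequence set
#'
#' For every unordered pair both directed lambda arrays are computed with
#' the requested method, averaged into `ACS_k` values and combined into the
#' symmetric distance.  The diagonal is 0 by construction.
#'
#' @param records list of `acs_record`s with unique names (>= 2).
#' @param k mismatch budget.
#' @param method `"adyar"` (default), `"kmacs"`, `"alfredg"`, or `"exact"`.
#' @param ties anchor tie policy for the heuristics.
#' @param fallback LCP-0 fallback (default on, the production setting).
#' @param log_base logarithm base for the distance.
#' @param clamp clamp small negative distances (near-identical pairs) to 0.
#' @param cap oracle comparison cap for `"exact"` / `"alfredg"`.
#' @param anchor_limit anchor cap per position.
#' @return an object of class `acs_dist`: `names`, `values` (symmetric
#'   matrix), `k`, `method`.
#' @export
acs_distance_matrix <- function(records, k, method = c("adyar", "kmacs", "alfredg", "exact"),
                                ties = "all", fallback = TRUE, log_base = "e",
                                clamp = FALSE, cap = 1e7, anchor_limit = Inf) {
  method <- match.arg(method)
  records <- lapply(records, as_record)
  nm <- vapply(records, function(r) r$name, "")
  if (length(records) < 2) stop("distance: need at least 2 records", call. = FALSE)
  if (anyDuplicated(nm))
    stop(sprintf("distance: duplicate record name '%s'", nm[duplicated(nm)][1]),
         call. = FALSE)
  n <- length(records)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      X <- records[[a]]; Y <- records[[b]]
      lam_xy <- lambda_method(X, Y, k, method, ties = ties, fallback = fallback,
                              anchor_limit = anchor_limit, cap = cap)
      lam_yx <- lambda_method(Y, X, k, method, ties = ties, fallback = fallback,
                              anchor_limit = anchor_limit, cap = cap)
      dv <- acs_distance(length(X), length(Y),
                         acs_from_lambda(lam_xy), acs_from_lambda(lam_yx),
                         log_base = log_base)
      if (clamp && is.finite(dv) && dv < 0) dv <- 0
      d[a, b] <- dv
      d[b, a] <- dv
    }
  }
  new_acs_dist(nm, d, as.integer(k), method)
}

new_acs_dist <- function(names, values, k = NA_integer_, method = NA_character_) {
  stopifnot(nrow(values) == length(names), ncol(values) == length(names))
  dimnames(values) <- list(names, names)
  structure(list(names = names, values = values, k = k, method = method),
            class = "acs_dist")
}

#' @export
print.acs_dist <- function(x, ...) {
  cat(sprintf("<acs_dist> %d x %d distance matrix (method %s, k = %s)\n",
              nrow(x$values), ncol(x$values), x$method, x$k))
  print(round(x$values, 6))
  invisible(x)
}

#' Mean error percentage of approximate ACS values against exact ones
#'
#' Mean over ordered entries of `|approx - exact| / exact * 100`; the
#' accuracy score used to compare the heuristics against the brute-force
#' oracle.
#'
#' @param approx,exact equal-length numeric vectors; `exact` entries must be
#'   positive.
#' @return mean percentage error.
#' @examples
#' mean_error_percent(1, 2)  # 50
#' @export
mean_error_percent <- function(approx, exact) {
  if (length(approx) != length(exact) || length(exact) == 0)
    stop("distance: approx and exact must be equal-length nonempty vectors",
         call. = FALSE)
  if (any(exact <= 0))
    stop("distance: exact ACS entries must be positive", call. = FALSE)
  mean(abs(approx - exact) / exact) * 100
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line is the taxon count; each row is the taxon name followed by
#' whitespace-separated distances to 6 decimals.  The strict dialect pads or
#' truncates names to 10 characters (erroring when truncation makes two
#' names collide); the relaxed dialect writes full names.
#'
#' @param matrix an `acs_dist`.
#' @param path output path.
#' @param dialect `"strict"` (10-character names) or `"relaxed"`.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(matrix, path, dialect = c("strict", "relaxed")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(matrix, "acs_dist"))
  nm <- matrix$names
  if (dialect == "strict") {
    short <- substr(nm, 1, 10)
    if (anyDuplicated(short)) {
      clash <- short[duplicated(short)][1]
      stop(sprintf("distance: names collide at 10 characters ('%s'); use the relaxed dialect",
                   clash), call. = FALSE)
    }
    nm <- formatC(short, width = 10, flag = "-")
  }
  rows <- vapply(seq_along(nm), function(i) {
    paste(nm[i], paste(sprintf("%.6f", matrix$values[i, ]), collapse = " "))
  }, "")
  writeLines(c(as.character(length(nm)), rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Accepts both the strict 10-character and relaxed dialects (the name is
#' the first whitespace-delimited token of each row).
#'
#' @param path input path.
#' @return an `acs_dist`.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("distance: malformed PHYLIP matrix", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 2 || length(lines) != n + 1)
    stop("distance: malformed PHYLIP matrix header", call. = FALSE)
  nm <- character(n)
  vals <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1]), "[ \t]+")[[1]]
    if (length(tok) != n + 1)
      stop(sprintf("distance: row %d has %d fields, expected %d (matrix not square?)",
                   i, length(tok), n + 1), call. = FALSE)
    nm[i] <- tok[1]
    vals[i, ] <- as.numeric(tok[-1])
  }
  if (anyNA(vals)) stop("distance: non-numeric entries in PHYLIP matrix", call. = FALSE)
  nm <- trimws(nm)
  new_acs_dist(nm, vals)
}

#' Write a distance matrix as TSV
#'
#' @param matrix an `acs_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "acs_dist"))
  df <- data.frame(name = matrix$names,
                   matrix$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
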