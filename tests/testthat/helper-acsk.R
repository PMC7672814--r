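# Independent R oracles used to check the C++ paths, plus fixture helpers.
# The oracles deliberately share no code with the package internals: plain
# character vectors and explicit loops.

oracle_chars <- function(s) strsplit(s, "")[[1]]

# k-mismatch greedy walk from 1-based (i, j); the defining semantics of LCP_k
oracle_walk <- function(x, y, i, j, k) {
  xc <- oracle_chars(x); yc <- oracle_chars(y)
  l <- 0L; mis <- 0L
  while (i + l <= length(xc) && j + l <= length(yc)) {
    if (xc[i + l] != yc[j + l]) {
      if (mis == k) break
      mis <- mis + 1L
    }
    l <- l + 1L
  }
  l
}

# lambda_k(i) for all i by trying every j
oracle_lambda <- function(x, y, k) {
  vapply(seq_len(nchar(x)), function(i) {
    max(0L, vapply(seq_len(nchar(y)), function(j) oracle_walk(x, y, i, j, k), 0L))
  }, 0L)
}

# all j attaining lambda_0(i)
oracle_ties <- function(x, y, i) {
  lam <- max(0L, vapply(seq_len(nchar(y)), function(j) oracle_walk(x, y, i, j, 0L), 0L))
  if (lam == 0L) return(integer(0))
  which(vapply(seq_len(nchar(y)), function(j) oracle_walk(x, y, i, j, 0L), 0L) == lam)
}

# naive LCP of two suffixes of an integer-coded text (sentinels are unique
# codes, so equality testing stops at them automatically)
oracle_text_lcp <- function(text, a, b) {
  n <- length(text)
  l <- 0L
  while (a + l <= n && b + l <= n && text[a + l] == text[b + l]) l <- l + 1L
  l
}

# seeded mutated DNA pair at a given per-site substitution rate
fixture_pair <- function(n, rate, seed) {
  x <- random_sequence(n, seed = seed)
  y <- mutate_sequence(x, mutation_model(rate, seed = seed + 10000L))
  y$name <- paste0(x$name, "_m")
  list(x = x, y = y)
}

# all strings of the given lengths over a small alphabet
all_strings <- function(lengths, alphabet = c("A", "C")) {
  unlist(lapply(lengths, function(L) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    apply(grid, 1, paste, collapse = "")
  }), use.names = FALSE)
}
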