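test_that("suffix array is a permutation and the LCP array matches naive comparison", {
  for (seed in 1:5) {
    p <- fixture_pair(sample(20:30, 1), 0.3, seed)
    ix <- build_index(p$x, p$y)
    n <- length(ix$text)
    expect_setequal(ix$suffix_array, seq_len(n))
    # suffixes in sorted order agree on exactly lcp_array[r] characters
    for (r in 2:n) {
      a <- ix$suffix_array[r - 1]; b <- ix$suffix_array[r]
      expect_identical(ix$lcp_array[r], oracle_text_lcp(ix$text, a, b))
    }
  }
})

test_that("sentinels are distinct, unique, smaller than residues, and block LCPs", {
  ix <- build_index("ACGT", "ACGT")
  sent <- sort(ix$text)[1:2]
  expect_true(sent[1] < sent[2])
  expect_equal(sum(ix$text == sent[1]), 1)
  expect_equal(sum(ix$text == sent[2]), 1)
  expect_true(all(ix$text[-c(ix$boundary, length(ix$text))] > sent[2]))
  # identical halves: LCP stops at the sentinel, never crossing it
  expect_equal(lcp_query(ix, 1, ix$boundary + 1), 4)
})

test_that("lcp_query equals a direct character walk for every suffix pair", {
  p <- fixture_pair(14, 0.2, 7)
  ix <- build_index(p$x, p$y)
  n <- length(ix$text)
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      expect_identical(lcp_query(ix, a, b), oracle_text_lcp(ix$text, a, b))
    }
  }
  expect_error(lcp_query(ix, 0, 3), "out of range")
  expect_error(lcp_query(ix, 1, n + 1), "out of range")
})

test_that("walk, rmq and auto LCP policies return identical values", {
  p <- fixture_pair(60, 0.1, 3)
  ix <- build_index(p$x, p$y)
  n <- length(ix$text)
  set.seed(42)
  for (rep in 1:200) {
    ab <- sample(n, 2)
    w <- lcp_query(ix, ab[1], ab[2], policy = "walk")
    expect_identical(lcp_query(ix, ab[1], ab[2], policy = "rmq"), w)
    expect_identical(lcp_query(ix, ab[1], ab[2], policy = "auto", threshold = 2L), w)
  }
})

test_that("matching statistics reproduce the worked DNA pair", {
  ms <- matching_statistics("CATTGCATACGA", "ATGGATCCAATAG")
  expect_equal(ms$lambda[4], 2)
  expect_equal(ms$mu[4], 2)
  expect_equal(ms$lambda[1], 2)
  expect_equal(ms$mu[1], 8)
})

test_that("matching statistics on X = Y are the suffix lengths with mu(i) = i", {
  x <- random_sequence(40, seed = 5)
  ms <- matching_statistics(x, x)
  n <- length(x)
  expect_equal(ms$lambda, n:1)
  expect_true(all(vapply(seq_len(n), function(i) i %in% ms$match_positions[[i]], NA)))
})

test_that("matching statistics agree with the brute-force oracle, ties included", {
  for (seed in c(2, 21)) {
    p <- fixture_pair(90, 0.4, seed)
    ms <- matching_statistics(p$x, p$y)
    for (i in seq_len(length(p$x))) {
      expect_identical(ms$lambda[i],
                       max(0L, vapply(seq_len(length(p$y)),
                                      function(j) oracle_walk(p$x$residues, p$y$residues, i, j, 0L), 0L)))
    }
    # spot-check full tie sets at a handful of positions
    for (i in c(1, 10, 45, 90)) {
      expect_identical(ms$match_positions[[i]], oracle_ties(p$x$residues, p$y$residues, i))
    }
  }
})

test_that("no reported match length exceeds the sequence bounds", {
  p <- fixture_pair(70, 0.15, 13)
  ms <- matching_statistics(p$x, p$y)
  n <- length(p$x)
  expect_true(all(ms$lambda <= pmin(n - seq_len(n) + 1L, length(p$y))))
  expect_true(all(ms$lambda >= 0))
})

test_that("the anchor limit truncates tie sets in ascending-j order", {
  x <- "AAAA"; y <- "AAAAAA"
  full <- matching_statistics(x, y)
  lim <- matching_statistics(x, y, anchor_limit = 2)
  expect_identical(lim$match_positions[[1]], head(full$match_positions[[1]], 2))
  expect_identical(lim$lambda, full$lambda)
})

test_that("reverse-orientation index is the forward index of the reversed pair", {
  p <- fixture_pair(25, 0.2, 31)
  ixr <- build_index(p$x, p$y, orientation = "reverse")
  ixf <- build_index(reverse_residues(p$x), reverse_residues(p$y))
  expect_identical(ixr$suffix_array, ixf$suffix_array)
  expect_identical(ixr$lcp_array, ixf$lcp_array)
})

test_that("empty sequences are rejected", {
  expect_error(build_index("", "ACGT"), "no residues|non-empty")
})
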