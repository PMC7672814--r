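X1 <- "CATTGCATACGA"; Y1 <- "ATGGATCCAATAG"
X2 <- "AATCGGT";      Y2 <- "AATGGGAAACCGGT"

test_that("forward chains follow the greedy skip-one-mismatch semantics", {
  expect_equal(forward_chain(X1, Y1, 4, 2, k = 2), c(2, 5, 7))
  # X = Y from the same position: nothing to skip, all budgets saturate
  x <- random_sequence(20, seed = 1)
  expect_equal(forward_chain(x, x, 5, 5, k = 3), rep(16, 4))
  # a mismatch at the last character consumes the end without extension
  expect_equal(forward_chain("TTA", "CCG", 3, 3, k = 1), c(0, 1))
  # chains are nondecreasing and step by at most 1 + remaining text
  p <- fixture_pair(50, 0.2, 8)
  L <- forward_chain(p$x, p$y, 3, 3, k = 5)
  expect_true(all(diff(L) >= 0))
  # every entry is a genuine <=m-mismatch match length
  for (m in 0:5) expect_equal(L[m + 1], lcp_k_walk(p$x, p$y, 3, 3, m))
})

test_that("backward chains measure characters strictly before the anchor", {
  expect_equal(backward_chain(X2, Y2, 4, 11, k = 1), c(0, 3))
  expect_equal(backward_chain(X2, Y2, 1, 5, k = 2), c(0, 0, 0))
  x <- random_sequence(15, seed = 3)
  expect_equal(backward_chain(x, x, 7, 7, k = 2), rep(6, 3))
  # backward chain equals a forward chain on the reversed strings
  p <- fixture_pair(40, 0.25, 12)
  xr <- reverse_residues(p$x)$residues; yr <- reverse_residues(p$y)$residues
  i <- 17; j <- 23; k <- 3
  nx <- length(p$x); ny <- length(p$y)
  expect_equal(backward_chain(p$x, p$y, i, j, k),
               forward_chain(xr, yr, nx - i + 2, ny - j + 2, k))
})

test_that("kmacs reproduces the worked examples and reduces to lambda at k = 0", {
  expect_equal(kmacs_lambda(X1, Y1, k = 2)$values[4], 7)
  expect_equal(kmacs_lambda(X2, Y2, k = 1)$values[1], 6)
  p <- fixture_pair(150, 0.3, 5)
  expect_identical(kmacs_lambda(p$x, p$y, 0)$values,
                   matching_statistics(p$x, p$y)$lambda)
})

test_that("ALFRED-G handles the degenerate and self cases and rejects k < 2", {
  x <- random_sequence(30, seed = 6)
  n <- length(x)
  expect_equal(alfredg_lambda(x, x, k = 2)$values, n:1)
  expect_equal(alfredg_lambda(x, x, k = 4)$values, n:1)
  expect_error(alfredg_lambda(x, x, k = 1), "k >= 2")
})

test_that("ALFRED-G never exceeds the exact lambda_k", {
  for (seed in c(1, 9)) {
    p <- fixture_pair(80, 0.25, seed)
    for (k in 2:4) {
      expect_true(all(alfredg_lambda(p$x, p$y, k)$values <=
                      exact_lambda(p$x, p$y, k)$values))
    }
  }
})

test_that("phase 1 relocates backward-extended candidates to their start", {
  p1 <- adyar_phase1(X2, Y2, k = 1)
  expect_gte(p1$values[1], 7)
  expect_equal(lcp_k_walk(X2, Y2, 1, 8, 1), 7)
  # full-length self anchor
  x <- random_sequence(25, seed = 2)
  expect_equal(adyar_phase1(x, x, 3)$values[1], 25)
})

test_that("phase 2 is the left-to-right decrement propagation", {
  mk <- function(v) acsk:::new_lambda_approx("adyar", 1L, v,
                                             rep(NA_integer_, length(v)))
  expect_equal(adyar_phase2(mk(c(7, 0, 0, 4, 0)))$values, c(7, 6, 5, 4, 3))
  fix <- c(5, 4, 4, 6, 5)
  expect_equal(adyar_phase2(mk(fix))$values, fix)
  set.seed(10)
  v <- sample(0:9, 30, replace = TRUE)
  out <- adyar_phase2(mk(v))$values
  expect_true(all(out[-1] >= out[-30] - 1))
  expect_true(all(out >= v))
})

test_that("the full two-phase heuristic beats forward-only greedy on the worked pair", {
  expect_equal(adyar_lambda(X2, Y2, k = 1)$values[1], 7)
  expect_equal(exact_lambda(X2, Y2, k = 1)$values[1], 7)
  expect_equal(kmacs_lambda(X2, Y2, k = 1)$values[1], 6)
})

test_that("the heuristic is exact at k = 0 and on identical sequences", {
  for (seed in c(3, 33)) {
    p <- fixture_pair(150, 0.3, seed)
    expect_identical(adyar_lambda(p$x, p$y, 0)$values,
                     matching_statistics(p$x, p$y)$lambda)
  }
  x <- random_sequence(30, seed = 7)
  expect_equal(adyar_lambda(x, x, 2)$values, 30:1)
})

test_that("soundness and dominance hold on exhaustive tiny instances", {
  strs <- all_strings(3:4)  # every binary-alphabet string of lengths 3 and 4
  for (k in 1:2) {
    for (x in strs) {
      for (y in strs) {
        ex <- exact_lambda(x, y, k)$values
        km <- kmacs_lambda(x, y, k)$values
        ad <- adyar_lambda(x, y, k)$values
        expect_true(all(km <= ad), info = sprintf("kmacs<=adyar x=%s y=%s k=%d", x, y, k))
        expect_true(all(ad <= ex), info = sprintf("adyar<=exact x=%s y=%s k=%d", x, y, k))
      }
    }
  }
})

test_that("soundness, dominance and witness validity hold on seeded pairs", {
  for (seed in 1:6) {
    p <- fixture_pair(200, c(0.1, 0.2, 0.3)[seed %% 3 + 1], seed)
    for (k in c(1, 3, 5)) {
      ex <- exact_lambda(p$x, p$y, k, cap = Inf)$values
      km <- kmacs_lambda(p$x, p$y, k)
      ad <- adyar_lambda(p$x, p$y, k)
      expect_true(all(km$values <= ad$values))
      expect_true(all(ad$values <= ex))
      for (lam in list(km, ad)) {
        has <- which(!is.na(lam$witnesses) & lam$values > 0)
        ok <- vapply(has, function(i) {
          lcp_k_walk(p$x, p$y, i, lam$witnesses[i], k) >= lam$values[i]
        }, NA)
        expect_true(all(ok))
      }
    }
  }
})

test_that("anchor tie policy: trying all maximal anchors never hurts", {
  for (seed in c(11, 12)) {
    p <- fixture_pair(120, 0.35, seed)
    for (k in c(1, 3)) {
      first <- adyar_lambda(p$x, p$y, k, ties = "first")$values
      all_ <- adyar_lambda(p$x, p$y, k, ties = "all")$values
      expect_true(all(all_ >= first))
    }
  }
})

test_that("the LCP-0 fallback copies the next suffix's estimate", {
  # X has a character absent from Y at position 2
  x <- "GTTAC"; y <- "TTACTTAC"
  ms <- matching_statistics(x, y)
  expect_equal(ms$lambda[1], 0)
  off <- adyar_lambda(x, y, 1, fallback = FALSE)
  on <- adyar_lambda(x, y, 1, fallback = TRUE)
  expect_equal(on$values[1], on$values[2])
  expect_true(is.na(on$witnesses[1]))
  expect_identical(on$values[-1], off$values[-1])
})

test_that("the guarded phase-2 variant never exceeds the unguarded pass", {
  for (seed in c(14, 15)) {
    p <- fixture_pair(100, 0.3, seed)
    g <- adyar_lambda(p$x, p$y, 2, guard = TRUE)$values
    u <- adyar_lambda(p$x, p$y, 2, guard = FALSE)$values
    expect_true(all(g <= u))
    expect_true(all(g <= exact_lambda(p$x, p$y, 2)$values))
  }
})

test_that("per-position TSV dumps carry position, method, k, value, witness", {
  lam <- adyar_lambda(X2, Y2, 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lambda_tsv(lam, f)
  df <- read.delim(f)
  expect_equal(names(df), c("position", "method", "k", "value", "witness"))
  expect_equal(df$value, lam$values)
  expect_equal(nrow(df), nchar(X2))
})
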