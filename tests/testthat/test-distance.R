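test_that("ACS is the arithmetic mean of the lambda array", {
  expect_equal(acs_from_lambda(c(2, 1)), 1.5)
  expect_equal(acs_from_lambda(rep(0, 5)), 0)
  # self-comparison closed form: mean of n..1 = (n+1)/2
  x <- random_sequence(40, seed = 1)
  expect_equal(acs_from_lambda(exact_lambda(x, x, 0)), 41 / 2)
  expect_error(acs_from_lambda(numeric(0)), "empty")
  expect_error(acs_from_lambda(c(1, 2), x_length = 3), "expected 3")
})

test_that("the self-distance closed form holds to 1e-12", {
  for (n in c(10, 100, 1000)) {
    x <- random_sequence(n, seed = n)
    acs <- acs_from_lambda(matching_statistics(x, x)$lambda)
    expect_equal(acs, (n + 1) / 2)
    d <- acs_distance(n, n, acs, acs)
    expect_equal(d, -2 * log(n) / (n * (n + 1)), tolerance = 1e-12)
  }
})

test_that("the pair distance is symmetric in its arguments and warns at ACS 0", {
  d1 <- acs_distance(120, 80, 3.2, 4.1)
  d2 <- acs_distance(80, 120, 4.1, 3.2)
  expect_equal(d1, d2)
  expect_warning(dinf <- acs_distance(10, 10, 0, 2), "Inf")
  expect_identical(dinf, Inf)
})

test_that("log-base choice rescales distances without reordering them", {
  de <- acs_distance(100, 200, 5, 6, log_base = "e")
  d2 <- acs_distance(100, 200, 5, 6, log_base = "2")
  expect_equal(d2, de / log(2))
})

test_that("distance matrices are symmetric with zero diagonal", {
  sim <- simulate_tree_and_sequences(5, 300, 0.1, seed = 4)
  m <- acs_distance_matrix(sim$records, k = 2, method = "adyar")
  expect_equal(m$values, t(m$values))
  expect_equal(diag(m$values), setNames(rep(0, 5), m$names))
  expect_error(acs_distance_matrix(sim$records[1], 2), "at least 2")
})

test_that("identical sequences give the self-distance off-diagonal (clamped to 0 on request)", {
  x <- random_sequence(100, seed = 8)
  recs <- lapply(c("a", "b", "c"), function(nm) sequence_record(nm, x$residues))
  m <- acs_distance_matrix(recs, k = 0, method = "exact")
  expect_equal(m$values[1, 2], -2 * log(100) / (100 * 101), tolerance = 1e-12)
  mc <- acs_distance_matrix(recs, k = 0, method = "exact", clamp = TRUE)
  expect_true(all(mc$values == 0))
})

test_that("heuristic and exact matrices coincide at k = 0", {
  sim <- simulate_tree_and_sequences(4, 150, 0.15, seed = 6)
  ma <- acs_distance_matrix(sim$records, k = 0, method = "adyar", fallback = FALSE)
  me <- acs_distance_matrix(sim$records, k = 0, method = "exact")
  expect_equal(ma$values, me$values, tolerance = 1e-12)
})

test_that("mean error percentage follows its definition", {
  expect_equal(mean_error_percent(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_error_percent(1, 2), 50)
  expect_equal(mean_error_percent(c(1, 3), c(2, 2)), 50)
  expect_error(mean_error_percent(1, 0), "positive")
  expect_error(mean_error_percent(c(1, 2), 1), "equal-length")
  # for a sound (lower-bound) heuristic the error is mean(1 - approx/exact)
  approx <- c(3, 4, 5); exact <- c(4, 4, 8)
  expect_equal(mean_error_percent(approx, exact),
               mean(1 - approx / exact) * 100)
})

test_that("PHYLIP matrices round-trip in both dialects", {
  sim <- simulate_tree_and_sequences(4, 200, 0.1, seed = 9)
  m <- acs_distance_matrix(sim$records, k = 1, method = "kmacs")
  for (dialect in c("strict", "relaxed")) {
    f <- withr::local_tempfile(fileext = ".phylip")
    write_phylip(m, f, dialect = dialect)
    back <- read_phylip(f)
    expect_equal(back$names, m$names)
    expect_equal(back$values, m$values, tolerance = 5e-7, ignore_attr = TRUE)
  }
})

test_that("strict PHYLIP names collide at 10 characters; relaxed keeps full names", {
  vals <- matrix(c(0, 1, 1, 0), 2, 2)
  m <- acsk:::new_acs_dist(c("Escherichia_coli_K12", "Escherichia_coli_O157"), vals)
  f <- withr::local_tempfile(fileext = ".phylip")
  expect_error(write_phylip(m, f, "strict"), "collide")
  write_phylip(m, f, "relaxed")
  expect_equal(read_phylip(f)$names, m$names)
})

test_that("malformed PHYLIP files are rejected", {
  f <- withr::local_tempfile(fileext = ".phylip")
  writeLines(c("3", "a 0.0 1.0", "b 1.0 0.0"), f)
  expect_error(read_phylip(f), "malformed|square")
  writeLines(c("2", "a 0.0 1.0 2.0", "b 1.0 0.0 3.0"), f)
  expect_error(read_phylip(f), "expected 3")
})
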