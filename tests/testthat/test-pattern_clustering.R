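test_that("comparison encoding maps significance and direction to digits", {
  a <- c(1.0, 1.1, 0.9, 1.05)
  b <- c(4.0, 4.2, 3.9, 4.1)
  expect_identical(encode_comparison(a, a), 1L)
  expect_identical(encode_comparison(a, b), 2L)
  expect_identical(encode_comparison(b, a), 0L)
})

test_that("encoding antisymmetry: digit(a,b) + digit(b,a) = 2 off the null", {
  set.seed(3)
  for (i in 1:25) {
    a <- rnorm(4); b <- rnorm(4, sample(c(0, 2), 1))
    d1 <- encode_comparison(a, b); d2 <- encode_comparison(b, a)
    if (d1 != 1L || d2 != 1L) expect_equal(d1 + d2, 2L)
    else expect_equal(c(d1, d2), c(1L, 1L))
  }
})

test_that("pattern assignment reproduces the canonical worked codes", {
  flat <- make_groups()
  expect_equal(assign_pattern(flat)$pattern, "111")
  # CDDO-unique: V ~ D300 << C10
  expect_equal(assign_pattern(make_groups(v = 8, d = 8, c = 12))$pattern,
               "122")
  # common response: V << D300 ~ C10
  expect_equal(assign_pattern(make_groups(v = 8, d = 12, c = 12))$pattern,
               "221")
  # opposite: D300 up, C10 down
  expect_equal(assign_pattern(make_groups(v = 8, d = 12, c = 4))$pattern,
               "200")
  expect_error(assign_pattern(list(V = 1:4, D300 = 1:4)), "missing group")
})

test_that("meta clustering implements the published pattern collapse", {
  expect_equal(meta_cluster(c("222", "001")), c("1", "1"))
  expect_equal(meta_cluster(c("210", "012")), c("2", "2"))
  expect_equal(meta_cluster(c("122", "100")), c("3", "3"))
  expect_equal(meta_cluster("200"), "opposite")
  expect_equal(meta_cluster("111"), "concordant_only")
  expect_error(meta_cluster("3x1"), "invalid pattern")
})

test_that("27-code exhaustive input partitions as 6/6/6/6/3", {
  digits <- c("0", "1", "2")
  codes <- as.vector(outer(outer(digits, digits, paste0), digits, paste0))
  ct <- tabulate_patterns(codes)
  expect_equal(unname(ct$meta_counts),
               c(6, 6, 6, 6, 3))
  expect_equal(sum(ct$meta_counts), 27)
})

test_that("tabulation conserves counts and handles empty input", {
  ct <- tabulate_patterns(character(0))
  expect_equal(sum(ct$counts$n), 0)
  expect_equal(sum(ct$meta_counts), 0)

  ct2 <- tabulate_patterns(c("221", "221", "111"))
  expect_equal(sum(ct2$counts$n), 3)
  expect_equal(sum(ct2$meta_counts), 3)
})

test_that("redundant probe resolution follows wins, then KW p, then id", {
  expect_equal(resolve_redundant("probeA", matrix(0.5, 1, 3)), "probeA")

  # A wins VD and VC, B wins DC: A retained (2 of 3)
  p <- rbind(A = c(0.01, 0.02, 0.50), B = c(0.03, 0.04, 0.40))
  expect_equal(resolve_redundant(c("A", "B"), p), "A")

  # exact three-way split with equal KW p: lexicographically smallest wins
  p3 <- rbind(c(0.01, 0.5, 0.5), c(0.5, 0.01, 0.5), c(0.5, 0.5, 0.01))
  expect_equal(resolve_redundant(c("c", "a", "b"), p3, kw_p = rep(0.2, 3)),
               "a")

  # KW p tie-break engages before the lexicographic one
  expect_equal(resolve_redundant(c("z", "a"), rbind(c(0.01, 0.5, 0.5),
                                                    c(0.5, 0.01, 0.5)),
                                 kw_p = c(0.001, 0.2)), "z")

  # alternative reading: smallest sum of p-values
  psum <- rbind(A = c(0.04, 0.04, 0.04), B = c(0.01, 0.02, 0.30))
  expect_equal(resolve_redundant(c("A", "B"), psum), "B")  # B wins 2 of 3
  expect_equal(resolve_redundant(c("A", "B"), psum, rule = "min_sum"), "A")
})

test_that("null-data pattern rate matches the enumeration oracle", {
  # Monte-Carlo oracle (enumerated exact 4v4 tests on 100k continuous null
  # draws) gives P(pattern != "111") = 0.0742; the independence
  # approximation 1-(1-2/70)^3 = 0.0833 overstates it because the three
  # comparisons share groups.
  set.seed(123)
  n <- 4000
  hits <- logical(n)
  for (i in seq_len(n)) {
    g <- list(V = rnorm(4), D300 = rnorm(4), C10 = rnorm(4))
    hits[i] <- assign_pattern(g)$pattern != "111"
  }
  rate <- mean(hits)
  se <- sqrt(0.0742 * (1 - 0.0742) / n)
  expect_lt(abs(rate - 0.0742), 3 * se + 0.0008)  # + oracle's own MC error
})
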