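test_that("exact Wilcoxon reproduces hand-enumerated cases", {
  r <- wilcoxon_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(r$p_two_sided, 2 / 70)
  expect_equal(r$direction, "second_greater")

  r2 <- wilcoxon_exact(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(r2$p_two_sided, 2 / 70)
  expect_equal(r2$direction, "first_greater")

  tied <- wilcoxon_exact(rep(3, 4), rep(3, 4))
  expect_equal(tied$p_two_sided, 1)
  expect_equal(tied$direction, "none")
})

test_that("exact Wilcoxon agrees with base R on tie-free data", {
  set.seed(10)
  for (i in 1:50) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(wilcoxon_exact(x, y)$p_two_sided,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("4v4 two-sided p can never fall below 2/70", {
  set.seed(20)
  for (i in 1:300) {
    x <- sample(1:5, 4, replace = TRUE)  # heavy ties on purpose
    y <- sample(1:5, 4, replace = TRUE)
    expect_gte(wilcoxon_exact(x, y)$p_two_sided, 2 / 70)
  }
})

test_that("input validation of the exact test", {
  expect_error(wilcoxon_exact(1, c(1, 2)), "at least 2")
  expect_error(wilcoxon_exact(c(1, NA), c(1, 2)), "finite")
})

test_that("Kruskal-Wallis statistic matches the reference implementation", {
  expect_equal(kruskal_wallis_stat(list(c(1, 2), c(3, 4), c(5, 6))), 32 / 7)
  # degenerate all-tie case is defined as 0
  expect_equal(kruskal_wallis_stat(rep(list(rep(4.2, 4)), 5)), 0)
  expect_error(kruskal_wallis_stat(list(1:3)), "at least 2 groups")

  set.seed(30)
  for (i in 1:25) {
    g <- lapply(sample(2:5, 3, replace = TRUE), function(n)
      sample(1:6, n, replace = TRUE))  # includes ties
    expect_equal(kruskal_wallis_stat(g),
                 unname(kruskal.test(g)$statistic), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis is invariant to location shifts", {
  g <- list(c(1.2, 3.4), c(2.2, 5.5, 6.1), c(0.3, 0.4))
  expect_equal(kruskal_wallis_stat(g),
               kruskal_wallis_stat(lapply(g, `+`, 100)))
})

test_that("permutation p-value: enumeration, Monte Carlo, and floor", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  p_en <- perm_pvalue(g, B = 10)
  expect_equal(attr(p_en, "method"), "enumeration")
  expect_equal(as.numeric(p_en), 6 / 90)

  p_mc1 <- as.numeric(perm_pvalue(g, B = 20000, seed = 1,
                                  method = "monte_carlo"))
  p_mc2 <- as.numeric(perm_pvalue(g, B = 20000, seed = 2,
                                  method = "monte_carlo"))
  tol <- 3 * sqrt((6 / 90) * (1 - 6 / 90) / 20000)
  expect_lt(abs(p_mc1 - 6 / 90), tol)
  expect_lt(abs(p_mc2 - 6 / 90), tol)

  # all identical constants: p = 1 on both routes
  const <- rep(list(rep(2, 3)), 3)
  expect_equal(as.numeric(perm_pvalue(const, B = 10)), 1)
  expect_equal(as.numeric(perm_pvalue(const, B = 500, seed = 3,
                                      method = "monte_carlo")), 1)

  # Monte-Carlo p never returns 0: add-one correction floor
  g2 <- list(c(1, 2, 3, 4), c(10, 11, 12, 13), c(20, 21, 22, 23),
             c(30, 31, 32, 33), c(40, 41, 42, 43))
  p <- as.numeric(perm_pvalue(g2, B = 200, seed = 4,
                              method = "monte_carlo"))
  expect_gte(p, 1 / 201)
})

test_that("Monte-Carlo permutation stream is reproducible under a seed", {
  g <- list(rnorm(4), rnorm(4), rnorm(4), rnorm(4), rnorm(4))
  p1 <- perm_pvalue(g, B = 5000, seed = 42, method = "monte_carlo")
  p2 <- perm_pvalue(g, B = 5000, seed = 42, method = "monte_carlo")
  expect_identical(as.numeric(p1), as.numeric(p2))
})

test_that("BH step-up matches a hand-rolled oracle and its properties", {
  bh_oracle <- function(p) {  # literal step-up definition
    m <- length(p); o <- order(p)
    adj <- numeric(m)
    running <- 1
    for (i in m:1) {
      running <- min(running, m * p[o[i]] / i)
      adj[o[i]] <- running
    }
    adj
  }
  expect_equal(sum(bh_fdr(c(0.01, 0.02, 0.03, 0.5), 0.05)$reject), 3)
  expect_equal(sum(bh_fdr(rep(1, 3), 0.5)$reject), 0)
  expect_identical(bh_fdr(numeric(0), 0.05),
                   list(adjusted = numeric(0), reject = logical(0)))

  set.seed(40)
  p <- runif(50)
  expect_equal(bh_fdr(p, 0.1)$adjusted, bh_oracle(p), tolerance = 1e-12)

  # monotone rejection sets in q; q near 1 rejects everything when p < 1
  r1 <- bh_fdr(p, 0.05)$reject
  r2 <- bh_fdr(p, 0.20)$reject
  expect_true(all(r2[r1]))
  expect_true(all(bh_fdr(p, 0.9999)$reject))
})
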