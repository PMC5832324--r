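test_that("dependence classification applies the two-criterion rule", {
  wt <- c(10, 10.1, 9.9, 10.05)
  # fc shift alone: rho = 2 >= 1.3 while the raw values are identical
  call <- classify_dependence(wt, wt, fc_wt = 2, fc_ko = 1)
  expect_false(call$by_significance)
  expect_true(call$by_fc_shift)
  expect_true(call$dependent)

  # neither criterion: rho ~ 1.09 and p large
  set.seed(1)
  a <- rnorm(4, 8, 1); b <- rnorm(4, 8, 1)
  call2 <- classify_dependence(a, b, fc_wt = 1.2, fc_ko = 1.1)
  expect_false(call2$by_fc_shift)

  # identical everything: not dependent
  call3 <- classify_dependence(wt, wt, fc_wt = 1.5, fc_ko = 1.5)
  expect_false(call3$dependent)
  expect_equal(call3$p_wt_vs_ko, 1)

  # significance alone
  call4 <- classify_dependence(c(10, 10.1, 9.9, 10.2), c(8, 8.1, 7.9, 8.2),
                               fc_wt = 1.1, fc_ko = 1.05)
  expect_true(call4$by_significance)
  expect_true(call4$dependent)
  expect_false(call4$by_fc_shift)

  expect_error(classify_dependence(wt, wt, 2, 1, delta = 1.3), "delta")
})

test_that("fc-shift criterion handles the signed convention on both sides", {
  wt <- c(8, 8.1, 7.9, 8)
  # Wt down 2-fold, KO flat: rho = 2^(-1 - 0) = 0.5 <= 1/1.3
  call <- classify_dependence(wt, wt, fc_wt = -2, fc_ko = 1)
  expect_true(call$by_fc_shift)
  # symmetric swap flips rho to its reciprocal, same verdict
  call_sw <- classify_dependence(wt, wt, fc_wt = 1, fc_ko = -2)
  expect_identical(call$by_fc_shift, call_sw$by_fc_shift)
})

test_that("increasing delta never creates a dependent call", {
  set.seed(2)
  wt <- rnorm(4, 9, 0.3); ko <- rnorm(4, 9, 0.3)
  fcs <- expand.grid(w = c(1.1, 1.4, 2, -1.6), k = c(1.05, 1.3, -1.2))
  for (i in seq_len(nrow(fcs))) {
    d1 <- classify_dependence(wt, ko, fcs$w[i], fcs$k[i],
                              delta = 0.2)$by_fc_shift
    d2 <- classify_dependence(wt, ko, fcs$w[i], fcs$k[i],
                              delta = 0.5)$by_fc_shift
    expect_true(d1 || !d2)  # d2 implies d1
  }
})

test_that("absolute-difference variant of the shift criterion", {
  wt <- c(8, 8.1, 7.9, 8)
  # |2.0 - 1.3| = 0.7 >= 0.3 * 2.0 = 0.6
  expect_true(classify_dependence(wt, wt, 2, 1.3,
                                  fc_rule = "absolute")$by_fc_shift)
  # |2.0 - 1.5| = 0.5 < 0.6
  expect_false(classify_dependence(wt, wt, 2, 1.5,
                                   fc_rule = "absolute")$by_fc_shift)
})

test_that("dependence rate rounds half away from zero", {
  expect_equal(dependence_rate(98, 197), 50L)
  expect_equal(dependence_rate(649, 745), 87L)
  expect_equal(dependence_rate(0, 10), 0L)
  expect_equal(dependence_rate(1, 200), 1L)   # 0.5 rounds up
  expect_equal(dependence_rate(3, 200), 2L)   # 1.5 rounds up (away from 0)
  expect_error(dependence_rate(1, 0), "positive")
  expect_error(dependence_rate(5, 4), "n_total")
})

test_that("planted dependence is recovered; false-call rate at its ceiling", {
  # With a planted 4-fold effect and sigma = 0.25, a dependent gene has
  # rho = 4 and clear Wt/KO separation: call rate should be ~1.
  set.seed(7)
  n <- 300
  dep_called <- logical(n)
  for (i in seq_len(n)) {
    wv <- rnorm(4, 8, 0.25); wt <- rnorm(4, 10, 0.25)
    kv <- rnorm(4, 8, 0.25); kt <- rnorm(4, 8, 0.25)
    dep_called[i] <- classify_dependence(
      wt, kt, signed_fold_change(wt, wv), signed_fold_change(kt, kv)
    )$dependent
  }
  expect_gte(mean(dep_called), 0.90)

  # With no genotype difference the false-call rate sits near the analytic
  # ceiling: P(|N(0, 0.25)| >= log2(1.3)) + exact Wilcoxon size 2/70,
  # about 0.13 + 0.029 minus overlap (Monte-Carlo oracle: 0.144).
  false_called <- logical(n)
  for (i in seq_len(n)) {
    wv <- rnorm(4, 8, 0.25); wt <- rnorm(4, 10, 0.25)
    kv <- rnorm(4, 8, 0.25); kt <- rnorm(4, 10, 0.25)
    false_called[i] <- classify_dependence(
      wt, kt, signed_fold_change(wt, wv), signed_fold_change(kt, kv)
    )$dependent
  }
  se <- sqrt(0.144 * (1 - 0.144) / n)
  expect_lt(abs(mean(false_called) - 0.144), 4 * se)
})
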