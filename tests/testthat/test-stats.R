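test_that("ICC(A,1) matches hand-computed and degenerate cases", {
  expect_equal(icc_a1(rbind(c(1, 1), c(2, 2), c(3, 3)))$icc, 1)
  # MSR = 2, MSC = 1.5, MSE = 0 -> ICC = 2/3
  res <- icc_a1(rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(res$icc, 2 / 3, tolerance = 1e-14)
  expect_lt(res$p, 0.05)  # F = Inf under MSE = 0
  # all-identical data: defined as 1 with the degenerate flag
  deg <- icc_a1(matrix(5, 4, 2))
  expect_equal(deg$icc, 1)
  expect_true(deg$degenerate)
  expect_error(icc_a1(rbind(c(1, 2), c(2, 3))), "at least 3")
  # incomplete rows are dropped listwise and counted
  x <- rbind(c(1, 2), c(2, 3), c(3, 4), c(NA, 1))
  expect_identical(icc_a1(x)$n_dropped, 1L)
  expect_identical(icc_a1(x)$n, 3L)
})

test_that("ICC agrees with a brute-force ANOVA oracle to 1e-10", {
  set.seed(101)
  for (i in 1:100) {
    x <- matrix(rnorm(40, mean = runif(1, -5, 5), sd = runif(1, 0.1, 3)),
                20, 2)
    expect_equal(icc_a1(x)$icc, icc_a1_bruteforce(x), tolerance = 1e-10)
  }
})

test_that("ICC is invariant to common shifts and 1 on duplicated columns", {
  set.seed(7)
  x <- matrix(rnorm(30), 15, 2)
  expect_equal(icc_a1(x)$icc, icc_a1(x + 100)$icc, tolerance = 1e-9)
  dup <- cbind(x[, 1], x[, 1])
  expect_equal(icc_a1(dup)$icc, 1, tolerance = 1e-12)
})

test_that("ICC bands follow the conventional thresholds", {
  expect_identical(icc_band(c(0.83, 0.19, 0.95, 0.6, 0.75, 0.90)),
                   c("good", "poor", "excellent", "moderate", "moderate",
                     "good"))
  expect_true(is.na(icc_band(NA_real_)))
})

test_that("correlation type is gated on Shapiro-Wilk normality", {
  x <- 1:10
  expect_equal(gated_correlation(x, x)$estimate, 1, tolerance = 1e-12)
  set.seed(33)
  xn <- rnorm(30); yn <- 0.8 * xn + rnorm(30, 0, 0.5)
  expect_identical(gated_correlation(xn, yn)$type, "pearson")
  # one extreme outlier fails the gate -> Spearman
  xo <- c(rnorm(29), 50)
  res <- gated_correlation(xo, c(rnorm(29), 40))
  expect_identical(res$type, "spearman")
  # constant input is flagged, not an error
  cc <- gated_correlation(rep(1, 10), rnorm(10))
  expect_true(is.na(cc$estimate))
  expect_identical(cc$flag, "constant_input")
  expect_error(gated_correlation(1:2, 2:3), "at least 3")
})

test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06),
               tolerance = 1e-12)
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(55)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_stepdown(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("group comparisons gate on normality and flag degenerate pairs", {
  x <- c(1.2, 3.4, 2.2, 4.1, 2.8)
  res <- compare_groups(x, x, paired = TRUE)
  expect_identical(res$test, "degenerate")
  expect_equal(res$p, 1)
  set.seed(42)
  a <- rnorm(21); b <- rnorm(21, 1)
  expect_identical(compare_groups(a, b)$test, "t")
  skew <- exp(rnorm(21, 0, 1.5)); skew2 <- exp(rnorm(21, 0.5, 1.5))
  expect_identical(compare_groups(skew, skew2)$test, "wilcoxon")
  # paired gate uses the differences
  d_normal <- rnorm(15, 0.5)
  expect_identical(compare_groups(a[1:15] + d_normal, a[1:15],
                                  paired = TRUE)$test, "t")
})

test_that("a 1-sd shift is detected by the gated procedure near nominal power", {
  # closed-form power of the two-sample t-test at n = 21, d = 1 is 0.885;
  # the gate occasionally diverts to Wilcoxon with slightly less power
  set.seed(99)
  hits <- 0L
  for (i in 1:200) {
    a <- rnorm(21); b <- rnorm(21, 1)
    res <- compare_groups(a, b)
    if (res$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 200, 0.8)
})

test_that("SRM is mean change over sd of change", {
  expect_equal(srm(c(0, 0, 0), c(1, 2, 3)), 2)
  s <- srm(c(1, 2, 3), c(1, 2, 3))
  expect_true(is.na(s))
  expect_identical(attr(s, "flag"), "zero_variance_change")
  # antisymmetry and scale invariance
  b <- c(1, 2, 4, 8); f <- c(2, 4, 5, 10)
  expect_equal(srm(f, b), -srm(b, f), tolerance = 1e-12)
  expect_equal(srm(b, b + 3 * (f - b)), srm(b, f), tolerance = 1e-12)
  expect_true(sign(srm(b, f)) == sign(mean(f - b)))
})

test_that("reliability report assembles ICC, gated correlation and Holm per family", {
  set.seed(12)
  truth <- rnorm(12, 3, 0.5)
  tabs <- lapply(c("m1", "m2", "m3"), function(m)
    two_session_table(truth + rnorm(12, 0, 0.1), truth + rnorm(12, 0, 0.1),
                      muscle = m))
  tab <- measurement_table(do.call(rbind, tabs))
  rep <- reliability_report(tab)
  expect_identical(nrow(rep), 3L)
  expect_true(all(rep$icc > 0.8))
  expect_true(all(rep$holm_adjusted_p >= rep$correlation_p))
  expect_true(all(rep$icc_band %in% c("good", "excellent")))
  # uncorrelated sessions give low ICC
  bad <- two_session_table(rnorm(12), rnorm(12))
  expect_lt(reliability_report(bad)$icc, 0.6)
})

test_that("longitudinal report computes change statistics, SRM and Holm", {
  set.seed(21)
  n <- 10
  rows <- list()
  for (m in c("m1", "m2")) {
    base <- rnorm(n, 3, 0.4)
    for (sess in c("baseline", "month9", "month18")) {
      shift <- switch(sess, baseline = 0, month9 = 0.2, month18 = 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("P%02d", 1:n), group = "patient",
        session = sess, muscle = m, side = "left",
        metric = "stiffness_kPa",
        value = base + shift + rnorm(n, 0, 0.1))
    }
  }
  tab <- measurement_table(do.call(rbind, rows))
  rep <- longitudinal_report(tab)
  expect_identical(nrow(rep), 4L)  # 2 muscles x 2 intervals
  m18 <- rep[rep$interval == "month18", ]
  expect_true(all(m18$change_mean > 0.2))
  expect_true(all(m18$srm > 1))
  expect_true(all(rep$holm_adjusted_p >= rep$p))
  expect_true(all(rep$n == n))
})
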