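test_that("mean and SEM follow the sample-SD definition", {
  m <- mean_sem(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$sem, 1 / sqrt(3))  # sd([1,2,3]) = 1
  expect_equal(m$sem, 0.577, tolerance = 1e-3)
  m2 <- mean_sem(c(5, 5, 5, 5))
  expect_equal(m2$sem, 0)
  m3 <- mean_sem(7)
  expect_true(is.na(m3$sem))
  expect_error(mean_sem(numeric(0)), "no finite values")
})

test_that("the test-selection rule follows the normality/variance gates", {
  set.seed(1)
  # strongly non-normal sample -> Mann-Whitney
  a <- rexp(40); b <- rnorm(40)
  expect_identical(choose_test(a, b)$test_name, "mann_whitney")
  # clear variance inequality between normal samples -> Welch
  set.seed(2)
  a2 <- rnorm(40, 0, 1); b2 <- rnorm(40, 0, 3)
  expect_identical(choose_test(a2, b2)$test_name, "welch_t")
  # well-behaved normal samples -> Student
  set.seed(3)
  a3 <- rnorm(40); b3 <- rnorm(40)
  expect_identical(choose_test(a3, b3)$test_name, "student_t")
  # tiny groups fall back to Mann-Whitney with a note
  ch <- choose_test(c(1, 2), c(3, 4))
  expect_identical(ch$test_name, "mann_whitney")
  expect_match(ch$note, "too small")
})

test_that("branch rates over many seeds match the gatekeeper levels", {
  picks <- function(gen_a, gen_b, n_rep = 40) {
    out <- character(n_rep)
    for (i in seq_len(n_rep)) {
      set.seed(1000 + i)
      out[i] <- choose_test(gen_a(), gen_b())$test_name
    }
    out
  }
  p1 <- picks(function() rnorm(40), function() rnorm(40))
  expect_gte(mean(p1 == "student_t"), 0.75)   # ~ 0.95^2 * 0.95
  p2 <- picks(function() rnorm(40, 0, 1), function() rnorm(40, 0, 3))
  expect_gte(mean(p2 == "welch_t"), 0.8)
  p3 <- picks(function() rexp(40), function() rnorm(40))
  expect_gte(mean(p3 == "mann_whitney"), 0.9)
})

test_that("comparisons detect shifts and stay quiet on identical samples", {
  set.seed(5)
  a <- rnorm(40)
  r <- compare_groups(a, a)
  expect_gt(r$p_value, 0.9)
  expect_false(r$significant)
  r2 <- compare_groups(a, a + 5)
  expect_true(r2$significant)
  expect_lt(r2$p_value, 1e-6)
})

test_that("the Mann-Whitney statistic equals the exhaustive enumeration oracle", {
  set.seed(11)
  for (i in 1:8) {
    a <- round(rnorm(4), 2); b <- round(rnorm(4), 2)
    u <- suppressWarnings(stats::wilcox.test(a, b))$statistic
    expect_equal(unname(u), mw_u_oracle(a, b))
  }
  # exact p-value agrees with full enumeration for small untied samples
  for (i in 1:4) {
    a <- rnorm(5); b <- rnorm(4)
    p_pkg <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(p_pkg, mw_p_oracle(a, b), tolerance = 1e-12)
  }
  # n = 6 per group as well
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(unname(stats::wilcox.test(a, b)$statistic), mw_u_oracle(a, b))
})

test_that("every test result is consistent with the decision tree", {
  set.seed(13)
  gens <- list(function() rnorm(30), function() rexp(25),
               function() rnorm(35, 0, 4), function() runif(20))
  for (i in 1:30) {
    a <- gens[[sample(4, 1)]](); b <- gens[[sample(4, 1)]]()
    r <- compare_groups(a, b)
    expected <- if (min(r$shapiro_p_a, r$shapiro_p_b) < 0.05) "mann_whitney"
    else if (is.finite(r$f_p) && r$f_p < 0.05) "welch_t"
    else "student_t"
    expect_identical(r$test_name, expected)
    expect_identical(r$significant, r$p_value < 0.05)
  }
})

test_that("percent changes reproduce half-up rounding and the exchange identity", {
  expect_equal(percent_change(29.0, 38.1)$rounded, 31)
  expect_equal(percent_change(263, 181)$rounded, -31)
  expect_equal(percent_change(5, 5)$rounded, 0)
  expect_error(percent_change(0, 5), "nonzero")
  expect_equal(round_half_up(14.5), 15)
  expect_equal(round_half_up(-14.5), -15)
  expect_equal(round_half_up(c(2.4, 2.5, -2.4)), c(2, 3, -2))
  # algebraic identity: pc(a,b) = -pc(b,a) * b/a
  set.seed(17)
  for (i in 1:10) {
    ab <- runif(2, 1, 50)
    expect_equal(percent_change(ab[1], ab[2])$percent,
                 -percent_change(ab[2], ab[1])$percent * ab[2] / ab[1])
  }
})

test_that("summary tables carry group means, markers and giant-event restriction", {
  set.seed(19)
  mk <- function(n, amp, qc) data.frame(
    fiber_id = paste0("f", seq_len(n)), rmp = runif(n, -75, -65),
    mean_epp = qc * amp + rnorm(n, 0, 1),
    mean_epp_nor = qc * amp + rnorm(n, 0, 1),
    quantal_content = qc + rnorm(n), mean_mepp = amp + rnorm(n, 0, 0.02),
    mepp_rise = 1.2 + rnorm(n, 0, 0.1), mepp_decay = 4 + rnorm(n, 0, 0.2),
    mepp_freq = 0.6 + rnorm(n, 0, 0.05),
    gmepp_freq = c(rep(0, 3), runif(n - 3, 0.1, 0.5)),
    gmepp_mepp_ratio = c(rep(NA, 3), runif(n - 3, 0.5, 2)),
    has_gmepps = c(rep(FALSE, 3), rep(TRUE, n - 3)))
  g1 <- mk(12, 0.55, 29); g2 <- mk(12, 0.75, 45)
  st <- build_summary_table(list(WT = g1, TG = g2))
  expect_s3_class(st, "nmj_summary")
  expect_identical(nrow(st$summary), 2L * 10L)
  # giant-event rows are restricted to fibers exhibiting giants
  gm <- st$summary[st$summary$measure == "gmepp_mepp_ratio", ]
  expect_true(all(gm$n == 9))
  # a large shift in mean MEPP amplitude is flagged significant
  cm <- st$comparisons
  expect_true(cm$significant[cm$measure == "mean_mepp"])
  expect_true(all(cm$marker[cm$significant] %in% c("#", "*", "+")))
  expect_error(build_summary_table(list(WT = g1)), "at least two")
})

test_that("identical cohorts produce few significant rows", {
  set.seed(23)
  mk <- function(n) data.frame(
    fiber_id = paste0("f", seq_len(n)), rmp = runif(n, -78, -62),
    mean_epp = rnorm(n, 17, 4), mean_epp_nor = rnorm(n, 18, 4),
    quantal_content = rnorm(n, 30, 8), mean_mepp = rnorm(n, 0.55, 0.1),
    mepp_rise = rnorm(n, 1.3, 0.3), mepp_decay = rnorm(n, 4, 0.8),
    mepp_freq = rnorm(n, 0.6, 0.2), gmepp_freq = runif(n, 0, 0.5),
    gmepp_mepp_ratio = runif(n, 0.2, 2), has_gmepps = TRUE)
  st <- build_summary_table(list(a = mk(40), b = mk(40)))
  expect_lte(sum(st$comparisons$significant, na.rm = TRUE), 2L)
})
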