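test_that("histograms conserve counts and send edge values to the upper bin", {
  h <- build_histogram(rep(0.55, 10), bin_width = 0.05)
  expect_identical(sum(h$counts), 10L)
  expect_identical(h$n_total, 10L)
  expect_identical(sum(h$counts > 0), 1L)
  expect_length(h$counts, 16L)

  # a value exactly on an edge belongs to the bin above it
  h2 <- build_histogram(c(0.25, 0.26), bin_width = 0.05)
  expect_identical(h2$counts[1], 0L)          # [0.20, 0.25)
  expect_identical(h2$counts[2], 2L)          # [0.25, 0.30)

  set.seed(10)
  a <- runif(2785, 0.2, 0.999)
  expect_identical(build_histogram(a)$n_total, 2785L)

  expect_error(build_histogram(numeric(0)), "no amplitudes")
  expect_error(build_histogram(c(0.5, 1.2)), "within")
  expect_error(build_histogram(0.5, bin_width = 0), "positive")
})

test_that("R-squared matches long-hand arithmetic", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  # 3-bin case, by hand: ss_tot = 8, ss_res = (1-2)^2 + (5-4)^2 = 2
  expect_equal(r_squared(c(1, 5, 3), c(2, 4, 3)), 1 - 2 / 8)
  expect_error(r_squared(1:3, 1:4), "equal length")
  expect_warning(r2 <- r_squared(rep(2, 4), c(1, 2, 3, 2)), "zero total")
  expect_true(is.na(r2))
})

test_that("an exact Gaussian histogram is recovered to numerical precision", {
  x <- seq(0.225, 0.975, by = 0.05)
  counts <- 120 * exp(-(x - 0.55)^2 / (2 * 0.09^2))
  h <- structure(list(edges = seq(0.2, 1, by = 0.05), mids = x,
                      counts = counts, n_total = round(sum(counts)),
                      bin_width = 0.05), class = "amp_histogram")
  fit <- fit_gaussian(h)
  expect_true(fit$converged)
  expect_equal(fit$mean, 0.55, tolerance = 1e-6)
  expect_equal(fit$sd, 0.09, tolerance = 1e-6)
  expect_equal(fit$height, 120, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("two-Gaussian fits recover mixture peaks from sampled data", {
  # oracle: the generative component means
  set.seed(42)
  a <- c(rnorm(1500, 0.32, 0.09), rnorm(1500, 0.64, 0.09))
  a <- a[a >= 0.2 & a < 1]
  fit <- fit_two_gaussians(build_histogram(a))
  expect_true(fit$converged)
  expect_lt(abs(fit$mean[1] - 0.32), 0.03)
  expect_lt(abs(fit$mean[2] - 0.64), 0.03)
  expect_lt(fit$mean[1], fit$mean[2])
  expect_gt(fit$r_squared, 0.95)
})

test_that("model selection separates unimodal from bimodal distributions", {
  set.seed(7)
  uni <- rnorm(2500, 0.55, 0.12); uni <- uni[uni >= 0.2 & uni < 1]
  h_uni <- build_histogram(uni)
  s_uni <- fit_gaussian(h_uni); d_uni <- fit_two_gaussians(h_uni)
  expect_identical(select_model(s_uni, d_uni)$decision, "unimodal")

  bi <- c(rnorm(1500, 0.32, 0.09), rnorm(1500, 0.64, 0.09))
  bi <- bi[bi >= 0.2 & bi < 1]
  h_bi <- build_histogram(bi)
  s_bi <- fit_gaussian(h_bi); d_bi <- fit_two_gaussians(h_bi)
  expect_identical(select_model(s_bi, d_bi)$decision, "bimodal")

  # identical fits never clear the improvement threshold
  expect_identical(select_model(s_uni, list(converged = TRUE,
                                            mean = c(s_uni$mean, s_uni$mean + 0.3),
                                            height = c(s_uni$height, s_uni$height),
                                            r_squared = s_uni$r_squared))$decision,
                   "unimodal")
  expect_identical(select_model(list(converged = FALSE),
                                list(converged = FALSE))$decision,
                   "undetermined")
})

test_that("fitted peaks are stable under sub-bin histogram shifts", {
  set.seed(9)
  a <- rnorm(3000, 0.55, 0.1); a <- a[a >= 0.22 & a < 0.98]
  f1 <- fit_gaussian(build_histogram(a))
  f2 <- fit_gaussian(build_histogram(a, range = c(0.18, 1.02)))
  expect_lt(abs(f1$mean - f2$mean), 0.02)
})

test_that("fiber classification applies the cutoff with ties going to B", {
  tab <- data.frame(fiber_id = c("f1", "f2", "f3", "f4"),
                    mean_mepp = c(0.32, 0.64, 0.49, NA))
  cl <- classify_fibers(tab, cutoff = 0.49)
  expect_identical(cl$label, c("A", "B", "B", NA))
  # default cutoff: pooled mean of the per-fiber means
  cl2 <- classify_fibers(tab[1:2, ])
  expect_equal(attr(cl2, "cutoff"), 0.48)
  expect_identical(cl2$label, c("A", "B"))
  # idempotence: reclassifying with the same cutoff changes nothing
  cl3 <- classify_fibers(tab, cutoff = attr(cl, "cutoff"))
  expect_identical(cl3$label, cl$label)
  expect_error(classify_fibers(tab, cutoff = -1), "positive")
  expect_error(classify_fibers(data.frame(x = 1)), "needs columns")
})

test_that("peak matching validates a grouping within tolerance", {
  g <- function(m) list(converged = TRUE, mean = m)
  pooled <- list(converged = TRUE, mean = c(0.31, 0.63))
  expect_identical(as.character(validate_grouping(g(0.30), g(0.65), pooled)),
                   "pass")
  expect_identical(as.character(validate_grouping(g(0.31), g(0.63), pooled)),
                   "pass")
  expect_identical(as.character(validate_grouping(g(0.51), g(0.63), pooled)),
                   "fail")
  expect_identical(validate_grouping(list(converged = FALSE), g(0.63),
                                     pooled), "undetermined")
})

test_that("single-population cohorts are rarely called bimodal", {
  # unimodal null at the pre-symptomatic cohort size; with few fibers the
  # pooled histogram is lumpier (fiber heterogeneity), so the full 40-fiber
  # cohort is the right null condition
  calls <- character(5)
  for (s in seq_len(5)) {
    ens <- simulate_ensemble(c("WT-young" = 40), seed = 500 + s,
                             sampling_rate = 5000, duration = 100,
                             evoked = FALSE)
    tab <- analyze_ensemble(ens)
    pooled <- attr(tab, "pooled_events")
    amps <- pooled$amplitude[pooled$event_class == "MEPP"]
    h <- build_histogram(amps)
    calls[s] <- select_model(fit_gaussian(h), fit_two_gaussians(h))$decision
  }
  expect_lte(sum(calls == "bimodal"), 1L)
})
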