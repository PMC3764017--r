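test_that("amplitude normalization follows the -75 mV reference formula", {
  expect_equal(normalize_amplitude(20, -60), 25)
  expect_equal(normalize_amplitude(16, -80), 15)
  # identity at the reference potential, for any amplitude
  x <- runif(20, 0.1, 30)
  expect_equal(normalize_amplitude(x, -75), x)
  # monotone decreasing in |rmp|
  expect_gt(normalize_amplitude(10, -65), normalize_amplitude(10, -70))
  expect_error(normalize_amplitude(10, 75), "negative")
  expect_error(normalize_amplitude(10, 0), "negative")
  expect_error(normalize_amplitude(-1, -70), "non-negative")
})

test_that("the RMP acceptance window is inclusive at both bounds", {
  expect_true(check_rmp(-69))
  expect_true(check_rmp(-80))
  expect_true(check_rmp(-60))
  expect_false(check_rmp(-59))
  expect_false(check_rmp(-80.5))
  expect_identical(check_rmp(c(-70, -59, NA)), c(TRUE, FALSE, FALSE))
})

test_that("mean EPP averages 60 consecutive normalized sweeps", {
  m <- mean_epp(rep(20, 60), rmp = -75)
  expect_equal(m$mean_raw, 20)
  expect_equal(m$mean_nor, 20)
  expect_equal(m$sem_nor, 0)
  expect_false(m$short_record)
  # per-sweep RMP normalization
  m2 <- mean_epp(c(20, 20), rmp = c(-60, -75), n_use = 2)
  expect_equal(m2$mean_nor, (25 + 20) / 2)
  # short records use all sweeps and are flagged
  m3 <- mean_epp(rep(20, 59), rmp = -75)
  expect_true(m3$short_record)
  expect_identical(m3$n_used, 59L)
  # only the first 60 of longer records are used
  m4 <- mean_epp(c(rep(10, 60), rep(99, 5)), rmp = -75)
  expect_equal(m4$mean_raw, 10)
  expect_error(mean_epp(numeric(0), -75), "no EPP")
})

test_that("mean MEPP averages the first 100 events and rejects giants", {
  ev <- data.frame(amplitude = rep(0.55, 100), rise_time = rep(1.3, 100),
                   decay_time = rep(4, 100),
                   event_class = rep("MEPP", 100))
  m <- mean_mepp(ev, rmp = -75)
  expect_equal(m$mean_amp, 0.55)
  expect_equal(m$sem_amp, 0)
  expect_equal(m$mean_rise, 1.3)
  expect_false(m$short_record)
  ev$event_class[5] <- "GMEPP"
  expect_error(mean_mepp(ev, -75), "MEPP-class")
  m2 <- mean_mepp(ev[1:4, ][ev$event_class[1:4] == "MEPP", ], -75)
  expect_true(m2$short_record)
  expect_error(mean_mepp(ev[0, ], -75), "no MEPPs")
})

test_that("quantal content is the ratio of normalized means", {
  expect_equal(quantal_content(18, 0.6), 30)
  expect_equal(quantal_content(5, 5), 1)
  expect_true(is.na(quantal_content(18, 0)))
  expect_true(is.na(quantal_content(18, NA)))
})

test_that("the GMEPP/MEPP ratio is defined only for fibers with giants", {
  expect_equal(gmepp_mepp_ratio(0.2, 0.1), 2)
  expect_equal(gmepp_mepp_ratio(0.44, 0.44), 1)
  expect_true(is.na(gmepp_mepp_ratio(0, 0.5)))
})

test_that("scaling amplitudes scales means and cancels in quantal content", {
  ev <- data.frame(amplitude = runif(50, 0.3, 0.8),
                   rise_time = 1, decay_time = 4,
                   event_class = "MEPP")
  c_ <- 3
  ev2 <- ev; ev2$amplitude <- ev2$amplitude * c_
  m1 <- mean_mepp(ev, -70); m2 <- mean_mepp(ev2, -70)
  expect_equal(m2$mean_amp, c_ * m1$mean_amp)
  expect_equal(m2$mean_amp_nor, c_ * m1$mean_amp_nor)
  e1 <- mean_epp(rep(18, 10), -70); e2 <- mean_epp(rep(18 * c_, 10), -70)
  expect_equal(quantal_content(e2$mean_nor, m2$mean_amp_nor),
               quantal_content(e1$mean_nor, m1$mean_amp_nor))
  expect_equal(quantal_content(e2$mean_nor, m1$mean_amp_nor),
               c_ * quantal_content(e1$mean_nor, m1$mean_amp_nor))
})

test_that("the mean of per-fiber quantal contents differs from the ratio of group means", {
  # heterogeneous fibers: the two estimators disagree by construction
  epp_nor <- c(12, 20)
  mepp_nor <- c(0.3, 0.8)
  per_fiber <- mean(epp_nor / mepp_nor)      # (40 + 25) / 2 = 32.5
  of_means <- mean(epp_nor) / mean(mepp_nor) # 16 / 0.55 = 29.09
  expect_gt(abs(per_fiber - of_means), 1)
})

test_that("fiber records assemble all quantities and propagate flags", {
  ev <- structure(
    data.frame(onset_time = seq(0.5, 15, length.out = 30),
               peak_time = seq(0.5, 15, length.out = 30) + 0.002,
               amplitude = c(rep(0.5, 28), 1.5, 1.8),
               rise_time = 1.2, decay_time = 3.9,
               event_class = c(rep("MEPP", 28), "GMEPP", "GMEPP"),
               merged = FALSE),
    duration = 20)
  epp <- data.frame(epp_amplitude = rep(15, 10), rmp_at_sweep = -75)
  rec <- summarize_fiber("f1", rmp = -75, events = ev, epp = epp)
  expect_true(rec$accepted)
  expect_equal(rec$mepp_freq, 28 / 20)
  expect_equal(rec$gmepp_freq, 2 / 20)
  expect_true(rec$has_gmepps)
  expect_equal(rec$gmepp_mepp_ratio, 2 / 28)
  expect_equal(rec$mean_mepp, 0.5)
  expect_equal(rec$quantal_content, 15 / 0.5)
  expect_true(rec$short_mepp_record)

  # no giants: ratio undefined
  ev2 <- ev[ev$event_class == "MEPP", ]; attr(ev2, "duration") <- 20
  rec2 <- summarize_fiber("f2", rmp = -70, events = ev2, epp = epp)
  expect_false(rec2$has_gmepps)
  expect_true(is.na(rec2$gmepp_mepp_ratio))

  # rejected RMP: no downstream fields
  rec3 <- summarize_fiber("f3", rmp = -55, events = ev, epp = epp)
  expect_false(rec3$accepted)
  expect_true(is.na(rec3$quantal_content))
  expect_true(is.na(rec3$mean_mepp))

  # missing evoked data: partial record
  rec4 <- summarize_fiber("f4", rmp = -70, events = ev)
  expect_true(is.na(rec4$mean_epp))
  expect_false(is.na(rec4$mepp_freq))
})

test_that("the ratio-of-means estimator recovers the generative quantal content", {
  # oracle: the generative parameter itself (quantal_mean)
  qc <- numeric(40)
  for (s in seq_len(40)) {
    p <- sim_params(sampling_rate = 2000, duration = 30, mepp_rate = 1.2,
                    quantal_mean = 30, n_sweeps = 30, seed = 100 + s)
    rec <- simulate_gapfree(p)
    sw <- simulate_evoked(p)
    ev <- detect_spontaneous(rec$trace)
    mep <- ev[ev$event_class == "MEPP", ]
    mm <- mean_mepp(mep, p$rmp)
    me <- mean_epp(measure_sweeps(sw)$epp_amplitude, p$rmp)
    qc[s] <- quantal_content(me$mean_nor, mm$mean_amp_nor)
  }
  expect_lt(abs(mean(qc) - 30) / 30, 0.1)
})
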