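test_that("amplitude bands partition events with the stated boundaries", {
  expect_identical(classify_event_amplitude(0.5), "MEPP")
  expect_identical(classify_event_amplitude(1.0), "GMEPP")
  expect_identical(classify_event_amplitude(0.15), "rejected")
  expect_identical(classify_event_amplitude(c(0.19999, 0.2, 0.999, 3)),
                   c("rejected", "MEPP", "MEPP", "GMEPP"))
  expect_error(classify_event_amplitude(-0.1), "negative")
  expect_error(classify_event_amplitude(NaN), "finite")
})

test_that("noise-free events are recovered with exact count and 1% amplitudes", {
  tr <- make_clean_trace(times = c(1, 3.5, 7), amps = c(0.5, 0.5, 0.5))
  ev <- detect_spontaneous(tr)
  expect_identical(nrow(ev), 3L)
  expect_true(all(ev$event_class == "MEPP"))
  expect_true(all(abs(ev$amplitude - 0.5) / 0.5 < 0.01))
  expect_true(all(ev$onset_time < ev$peak_time))
  expect_true(all(diff(ev$onset_time) > 0))

  tr2 <- make_clean_trace(times = c(2, 6), amps = c(1.5, 0.5))
  ev2 <- detect_spontaneous(tr2)
  expect_identical(ev2$event_class, c("GMEPP", "MEPP"))
  expect_true(all(abs(ev2$amplitude - c(1.5, 0.5)) / c(1.5, 0.5) < 0.01))
})

test_that("a baseline-only trace yields no events", {
  tr <- nmj_trace(rep(-70, 20000) + rnorm(20000, 0, 0.05), 10000,
                  rmp = -70)
  set.seed(8)
  ev <- detect_spontaneous(tr)
  expect_identical(nrow(ev), 0L)
})

test_that("detection warns below 2 kHz and errors on sub-second traces", {
  tr <- nmj_trace(rep(-70, 3000), 1500, rmp = -70)
  expect_warning(detect_spontaneous(tr), "sampling rate")
  tr2 <- nmj_trace(rep(-70, 1000), 10000, rmp = -70)
  expect_error(detect_spontaneous(tr2), "at least 1 s")
})

test_that("detection is invariant to a constant baseline shift", {
  set.seed(21)
  p <- quick_params(sampling_rate = 5000, duration = 20, mepp_rate = 0.8,
                    seed = 21)
  rec <- simulate_gapfree(p)
  ev1 <- detect_spontaneous(rec$trace)
  tr2 <- nmj_trace(rec$trace$voltage - 5, 5000, rmp = rec$trace$rmp - 5)
  ev2 <- detect_spontaneous(tr2)
  expect_equal(ev1$amplitude, ev2$amplitude, tolerance = 1e-12)
  expect_equal(ev1$rise_time, ev2$rise_time, tolerance = 1e-12)
  expect_equal(ev1$decay_time, ev2$decay_time, tolerance = 1e-12)
})

test_that("oracle equivalence: detection matches ground truth on clean traces", {
  # noise-free simulated trace with well-separated events
  p <- sim_params(sampling_rate = 5000, duration = 60, mepp_rate = 0.4,
                  noise_sd = 0, seed = 31)
  rec <- simulate_gapfree(p)
  truth <- rec$truth[rec$truth$amplitude >= 0.2, ]
  gaps_ok <- all(diff(rec$truth$time) > 0.02)
  ev <- detect_spontaneous(rec$trace)
  if (gaps_ok) expect_identical(nrow(ev), nrow(truth))
  m <- match_events(ev, truth)
  expect_gte(m$recall, 0.99)
  ord <- order(truth$time)
  if (nrow(ev) == nrow(truth))
    expect_true(all(abs(ev$amplitude - truth$amplitude[ord]) /
                      truth$amplitude[ord] < 0.01))
})

test_that("recall and precision reach 0.95 at the stated noise floor", {
  p <- sim_params(sampling_rate = 5000, duration = 100, mepp_rate = 0.7,
                  mepp_amp_mean = 0.55, noise_sd = 0.05, gmepp_rate = 0.2,
                  seed = 17)
  rec <- simulate_gapfree(p)
  truth <- rec$truth[rec$truth$amplitude >= 0.2, ]
  ev <- detect_spontaneous(rec$trace)
  m <- match_events(ev, truth)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("nearby candidate peaks are merged into one event", {
  tr <- make_clean_trace(times = c(2, 2.003), amps = c(0.6, 0.5))
  ev <- detect_spontaneous(tr)
  expect_identical(nrow(ev), 1L)
  # the same two events well separated are resolved
  tr2 <- make_clean_trace(times = c(2, 2.05), amps = c(0.6, 0.5))
  expect_identical(nrow(detect_spontaneous(tr2)), 2L)
  # candidate clusters closer than the merge window keep the strongest
  # member and carry the merged flag
  m <- nmjquant:::merge_candidates(pos = c(100L, 104L, 300L),
                                   score = c(1, 0.8, 0.5),
                                   min_sep = 10L, decim = 2L)
  expect_identical(m$index, c(199L, 599L))
  expect_identical(m$merged, c(TRUE, FALSE))
})

test_that("the derivative detector finds clean events", {
  tr <- make_clean_trace(times = c(2, 6), amps = c(0.6, 0.8))
  ev <- detect_spontaneous(tr, detect_config(detector = "derivative"))
  expect_identical(nrow(ev), 2L)
  expect_true(all(abs(ev$amplitude - c(0.6, 0.8)) < 0.05))
})

test_that("rise-time measurement follows the 10-90% convention", {
  # linear ramp: 10-90% of a 1 ms ramp is 0.8 ms
  dt <- 0.001
  w <- c(seq(0, 1, by = dt), rep(1, 100))
  expect_equal(measure_rise_time(w, dt_ms = dt), 0.8, tolerance = 1e-6)
  # instantaneous step: rise below one sample interval
  w2 <- c(rep(0, 50), rep(1, 50))
  expect_lte(measure_rise_time(w2, dt_ms = 0.1), 0.1)
  # 20-80% convention via frac
  expect_equal(measure_rise_time(w, dt_ms = dt, frac = c(0.2, 0.8)), 0.6,
               tolerance = 1e-6)
  # peak never rises above baseline -> failure flag
  expect_true(is.na(measure_rise_time(rep(0, 100), dt_ms = 0.1)))
})

test_that("decay measurement recovers a pure exponential exactly and flags truncation", {
  t <- seq(0, 30, by = 0.01)
  w <- exp(-t / 3)
  expect_equal(measure_decay_time(w, dt_ms = 0.01), 3, tolerance = 1e-9)
  # truncated falling phase: never reaches 10% of peak
  w2 <- w[t <= 3]
  expect_true(is.na(measure_decay_time(w2, dt_ms = 0.01)))
  # half-decay convention: t_half = 3 * log(2)
  expect_equal(measure_decay_time(w, dt_ms = 0.01, convention = "half"),
               3 * log(2), tolerance = 1e-3)
})

test_that("EPP measurement is accurate, baseline-invariant and window-checked", {
  fs <- 10000
  n <- fs * 0.2
  v <- rep(-70, n)
  onset <- floor(0.052 * fs) + 1
  tk <- (seq_len(2000) - 1) / fs * 1000
  kern <- event_waveform(tk, 20, 2.95, 3.56)
  v[onset:(onset + 1999)] <- v[onset:(onset + 1999)] + kern
  m <- measure_epp(v, fs, stim_time = 0.05)
  expect_equal(m$epp_amplitude, 20, tolerance = 0.005 * 20)
  m2 <- measure_epp(v - 5, fs, stim_time = 0.05)
  expect_equal(m$epp_amplitude, m2$epp_amplitude, tolerance = 1e-12)
  # no-response sweep stays near zero
  set.seed(3)
  v0 <- rep(-70, n) + rnorm(n, 0, 0.05)
  expect_lt(abs(measure_epp(v0, fs, stim_time = 0.05)$epp_amplitude),
            3 * 0.05)
  expect_error(measure_epp(v, fs, stim_time = 0.05, window_ms = 500),
               "exceeds sweep extent")
})

test_that("event frequencies are counts over duration, per class", {
  ev <- data.frame(event_class = c(rep("MEPP", 64), rep("GMEPP", 33)))
  f <- event_frequency(ev, duration = 100)
  expect_equal(f[["MEPP"]], 0.64)
  expect_equal(f[["GMEPP"]], 0.33)
  f0 <- event_frequency(data.frame(event_class = character(0)),
                        duration = 100)
  expect_identical(unname(f0), c(0, 0))
  expect_error(event_frequency(ev, duration = 0), "positive")
})
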