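# Shared fixtures: all synthetic, generated in code.

# short, cheap trace parameters for unit tests
quick_params <- function(...) {
  defaults <- list(sampling_rate = 2000, duration = 20, mepp_rate = 0.5,
                   noise_sd = 0.05, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# a noise-free trace with events injected at chosen times/amplitudes
make_clean_trace <- function(times, amps, fs = 10000, duration = 10,
                             rmp = -70, tau_rise = 2.95, tau_decay = 3.56) {
  n <- round(fs * duration)
  v <- rep(0, n)
  klen <- ceiling(fs * 8 * tau_decay / 1000)
  tk <- (seq_len(klen) - 1) / fs * 1000
  kern <- event_waveform(tk, 1, tau_rise, tau_decay)
  for (i in seq_along(times)) {
    i0 <- floor(times[i] * fs) + 1
    idx <- i0:min(n, i0 + klen - 1)
    v[idx] <- v[idx] + amps[i] * kern[seq_along(idx)]
  }
  nmj_trace(v + rmp, fs, rmp = rmp)
}

# match detected events to ground-truth events by onset time (tolerance s)
match_events <- function(detected, truth, tol = 0.003) {
  hits <- vapply(truth$time, function(t)
    any(abs(detected$onset_time - t) < tol), TRUE)
  fp <- vapply(detected$onset_time, function(t)
    !any(abs(truth$time - t) < tol), TRUE)
  list(recall = mean(hits), precision = 1 - mean(fp), hits = hits)
}

# exhaustive Mann-Whitney U oracle: U = #(a_i > b_j) + 0.5 #(a_i == b_j)
mw_u_oracle <- function(a, b) {
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  sum(cmp)
}

# exact two-sided permutation p-value for the MW statistic, n small
mw_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- mw_u_oracle(a, b)
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(i) mw_u_oracle(pooled[i], pooled[-i]))
  mu <- na * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
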