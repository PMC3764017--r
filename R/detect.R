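#' Detection settings
#'
#' Configuration for [detect_spontaneous()] and [measure_epp()]. The default
#' detector is a matched filter: the trace is correlated with a unit-peak
#' event kernel and local maxima of the least-squares amplitude estimate
#' above `candidate_threshold` become candidates, which are then re-measured
#' at full resolution against a local pre-onset baseline. A simple
#' derivative-threshold detector is available as an alternative; it is less
#' robust near the 0.2 mV detection floor.
#'
#' @param detector `"template"` (matched filter, default) or
#'   `"derivative"`.
#' @param mepp_min lower amplitude bound of the MEPP band (mV); candidates
#'   measuring below it are discarded.
#' @param gmepp_min minimum GMEPP amplitude (mV); events at or above it are
#'   classified as giants.
#' @param candidate_threshold matched-filter amplitude (mV) above which a
#'   local maximum becomes a candidate; set below `mepp_min` so borderline
#'   events are measured precisely before the band is applied.
#' @param template_tau_rise,template_tau_decay time constants (ms) of the
#'   detection template. Template mismatch affects sensitivity only, not
#'   amplitude measurement.
#' @param min_separation_ms candidates closer than this are merged into one
#'   event (the maximal peak), flagged `merged`.
#' @param baseline_window_ms pre-onset window whose median defines the local
#'   baseline.
#' @param peak_search_ms window after the candidate onset searched for the
#'   peak.
#' @param decay_window_ms falling-phase window used for the decay fit.
#' @param search_rate_hz internal decimation target for the candidate
#'   search; features are always measured at full resolution.
#' @param rise_frac fractional amplitudes defining the rise time
#'   (default `c(0.1, 0.9)`, i.e. 10--90\%; use `c(0.2, 0.8)` for 20--80\%).
#' @param decay_convention `"tau"` (fitted exponential time constant,
#'   default) or `"half"` (time from peak to 50\% decay).
#' @return a list of class `detect_config`.
#' @export
detect_config <- function(detector = c("template", "derivative"),
                          mepp_min = 0.2, gmepp_min = 1.0,
                          candidate_threshold = 0.15,
                          template_tau_rise = 2.9,
                          template_tau_decay = 3.6,
                          min_separation_ms = 5, baseline_window_ms = 10,
                          peak_search_ms = 8, decay_window_ms = 30,
                          search_rate_hz = 2000,
                          rise_frac = c(0.1, 0.9),
                          decay_convention = c("tau", "half")) {
  detector <- match.arg(detector)
  decay_convention <- match.arg(decay_convention)
  if (mepp_min <= 0 || gmepp_min <= mepp_min)
    stop("need 0 < mepp_min < gmepp_min", call. = FALSE)
  if (candidate_threshold <= 0 || candidate_threshold > mepp_min)
    stop("'candidate_threshold' must lie in (0, mepp_min]", call. = FALSE)
  check_taus(template_tau_rise, template_tau_decay)
  if (length(rise_frac) != 2L || rise_frac[1] <= 0 || rise_frac[2] >= 1 ||
      rise_frac[1] >= rise_frac[2])
    stop("'rise_frac' must be increasing fractions in (0, 1)", call. = FALSE)
  structure(list(detector = detector, mepp_min = mepp_min,
                 gmepp_min = gmepp_min,
                 candidate_threshold = candidate_threshold,
                 template_tau_rise = template_tau_rise,
                 template_tau_decay = template_tau_decay,
                 min_separation_ms = min_separation_ms,
                 baseline_window_ms = baseline_window_ms,
                 peak_search_ms = peak_search_ms,
                 decay_window_ms = decay_window_ms,
                 search_rate_hz = search_rate_hz,
                 rise_frac = rise_frac,
                 decay_convention = decay_convention),
            class = "detect_config")
}

#' Classify a spontaneous event by amplitude band
#'
#' Events below 0.2 mV are rejected as sub-threshold; amplitudes in
#' \[0.2, 1.0) mV are MEPPs; amplitudes of 1 mV and above are giant MEPPs.
#' The 1 mV boundary belongs to the giant band.
#'
#' @param amp numeric vector of event amplitudes (mV), non-negative.
#' @param mepp_min,gmepp_min band boundaries (mV).
#' @return character vector: `"rejected"`, `"MEPP"` or `"GMEPP"`.
#' @examples
#' classify_event_amplitude(c(0.15, 0.5, 1.0))
#' @export
classify_event_amplitude <- function(amp, mepp_min = 0.2, gmepp_min = 1.0) {
  if (!is.numeric(amp) || any(!is.finite(amp)))
    stop("'amp' must be finite numeric", call. = FALSE)
  if (any(amp < 0))
    stop("negative amplitudes are invalid", call. = FALSE)
  ifelse(amp >= gmepp_min, "GMEPP",
         ifelse(amp >= mepp_min, "MEPP", "rejected"))
}

# Savitzky-Golay quadratic smoother, window 5 (endpoints passed through).
smooth_sg5 <- function(x) {
  n <- length(x)
  if (n < 5L) return(x)
  y <- as.numeric(stats::filter(x, c(-3, 12, 17, 12, -3) / 35, sides = 2))
  y[c(1L, 2L, n - 1L, n)] <- x[c(1L, 2L, n - 1L, n)]
  y
}

# Peak value by quadratic-vertex refinement around the argmax of a smoothed
# segment; avoids the upward bias of taking a running max over noise.
peak_refine <- function(w, half_width = 5L) {
  ip <- which.max(w)
  a0 <- max(1L, ip - half_width)
  a1 <- min(length(w), ip + half_width)
  if (a1 - a0 < 4L) return(list(value = w[ip], index = ip))
  t <- seq(a0, a1) - ip
  fit <- stats::lm.fit(cbind(1, t, t * t), w[a0:a1])
  cf <- fit$coefficients
  if (!is.finite(cf[3]) || cf[3] >= 0) return(list(value = w[ip], index = ip))
  tv <- -cf[2] / (2 * cf[3])
  tv <- max(min(tv, half_width), -half_width)
  list(value = cf[1] + cf[2] * tv + cf[3] * tv * tv,
       index = ip, vertex_offset = tv)
}

#' Detect spontaneous events in a gap-free trace
#'
#' Locates spontaneous depolarizations, measures each against a local
#' pre-onset baseline (median of a 10 ms window), extracts kinetic features
#' and classifies survivors into MEPPs and GMEPPs by amplitude band.
#' Candidates below the 0.2 mV floor are discarded; candidate peaks closer
#' than the merge window are collapsed into a single event and flagged.
#'
#' @param trace an [nmj_trace()] (or an `nmj_recording`, whose trace is
#'   used).
#' @param config a [detect_config()].
#' @return a data.frame of class `nmj_events`, one row per detected event,
#'   sorted by onset time, with columns `onset_time` and `peak_time` (s),
#'   `amplitude` (mV), `rise_time` and `decay_time` (ms, `NA` when a
#'   measurement fails), `event_class` and `merged`. Attributes record the
#'   trace duration and the measurement conventions.
#' @export
detect_spontaneous <- function(trace, config = detect_config()) {
  if (inherits(trace, "nmj_recording")) trace <- trace$trace
  stopifnot(inherits(trace, "nmj_trace"))
  fs <- trace$sampling_rate
  v <- trace$voltage
  n <- length(v)
  if (n < fs) stop("trace must be at least 1 s long", call. = FALSE)
  if (fs < 2000)
    warning("sampling rate below 2 kHz: rise times may be unresolved",
            call. = FALSE)

  starts <- if (config$detector == "template")
    candidates_template(v, fs, config)
  else candidates_derivative(v, fs, config)

  empty <- data.frame(onset_time = numeric(0), peak_time = numeric(0),
                      amplitude = numeric(0), rise_time = numeric(0),
                      decay_time = numeric(0), event_class = character(0),
                      merged = logical(0), stringsAsFactors = FALSE)
  if (!nrow(starts)) return(events_frame(empty, trace, config))

  bw <- round(config$baseline_window_ms / 1000 * fs)
  pre <- round(0.002 * fs)
  ps <- round(config$peak_search_ms / 1000 * fs)
  dw <- round(config$decay_window_ms / 1000 * fs)

  nc <- nrow(starts)
  o_onset <- o_peak <- o_amp <- o_rise <- o_decay <- rep(NA_real_, nc)
  o_merged <- rep(NA, nc)
  for (i in seq_len(nc)) {
    i0 <- starts$index[i]
    if (i0 <= 2L) next
    # baseline window ends slightly before the aligned onset so that small
    # alignment errors do not leak the rising foot into the baseline
    bm <- round(0.0015 * fs)
    b_idx <- max(1L, i0 - bw - bm):max(1L, i0 - bm)
    baseline <- stats::median(v[b_idx])
    a0 <- max(1L, i0 - pre)
    next_start <- if (i < nrow(starts)) starts$index[i + 1L] else n + dw
    a1 <- min(n, i0 + ps + dw, next_start - round(0.001 * fs))
    if (a1 - a0 < 5L) next
    ws <- smooth_sg5(v[a0:a1])
    search_hi <- min(length(ws), i0 + ps - a0 + 1L)
    pk <- peak_refine(ws[seq_len(search_hi)])
    amp <- pk$value - baseline
    if (!is.finite(amp) || amp < config$mepp_min) next
    ip <- pk$index  # relative to a0 segment
    # onset: last sample before the peak at or below 5% of the amplitude
    below <- which(ws[seq_len(ip)] - baseline <= 0.05 * amp)
    onset_rel <- if (length(below)) max(below) else 1L
    if (onset_rel >= ip) onset_rel <- max(1L, ip - 1L)
    # rise measured from the onset onwards so that pre-onset noise cannot
    # masquerade as an early threshold crossing
    rise <- measure_rise_time(ws[onset_rel:(ip + min(2L, length(ws) - ip))],
                              dt_ms = 1000 / fs, baseline = baseline,
                              frac = config$rise_frac)
    decay <- measure_decay_time(ws[ip:length(ws)], dt_ms = 1000 / fs,
                                baseline = baseline,
                                convention = config$decay_convention)
    o_onset[i] <- trace$start_time + (a0 + onset_rel - 2L) / fs
    o_peak[i] <- trace$start_time + (a0 + ip - 2L) / fs
    o_amp[i] <- amp
    o_rise[i] <- rise
    o_decay[i] <- decay
    o_merged[i] <- starts$merged[i]
  }
  keep <- which(is.finite(o_amp))
  ev <- if (length(keep))
    data.frame(onset_time = o_onset[keep], peak_time = o_peak[keep],
               amplitude = o_amp[keep], rise_time = o_rise[keep],
               decay_time = o_decay[keep],
               event_class = classify_event_amplitude(o_amp[keep],
                                                      config$mepp_min,
                                                      config$gmepp_min),
               merged = o_merged[keep], stringsAsFactors = FALSE)
  else empty
  ev <- ev[order(ev$onset_time), , drop = FALSE]
  rownames(ev) <- NULL
  events_frame(ev, trace, config)
}

events_frame <- function(ev, trace, config) {
  attr(ev, "duration") <- trace_duration(trace)
  attr(ev, "rise_convention") <-
    sprintf("%d-%d%% rise time, linear interpolation",
            round(100 * config$rise_frac[1]),
            round(100 * config$rise_frac[2]))
  attr(ev, "decay_convention") <- if (config$decay_convention == "tau")
    "log-linear fitted time constant between 90% and 10% of peak"
  else "time from peak to 50% of peak"
  attr(ev, "amplitude_bands") <-
    sprintf("MEPP [%.3g, %.3g) mV; GMEPP >= %.3g mV",
            config$mepp_min, config$gmepp_min, config$gmepp_min)
  class(ev) <- c("nmj_events", "data.frame")
  ev
}

# Matched-filter candidate search on a decimated copy of the trace.
candidates_template <- function(v, fs, config) {
  decim <- max(1L, floor(fs / config$search_rate_hz))
  nd <- floor(length(v) / decim)
  vd <- if (decim > 1L)
    colMeans(matrix(v[seq_len(nd * decim)], nrow = decim))
  else v
  vd <- vd - stats::median(vd)
  dt_ms <- 1000 * decim / fs
  tk <- seq(0, 6 * config$template_tau_decay, by = dt_ms)
  kd <- event_waveform(tk, 1, config$template_tau_rise,
                       config$template_tau_decay)
  p <- length(kd)
  den <- sum(kd * kd)
  # FFT cross-correlation; a_hat[s] is the least-squares amplitude of a
  # template starting at decimated sample s
  n2 <- stats::nextn(nd + p)
  xf <- stats::fft(c(vd, rep(0, n2 - nd)))
  kf <- stats::fft(c(kd, rep(0, n2 - p)))
  cc <- Re(stats::fft(xf * Conj(kf), inverse = TRUE)) / n2
  a_hat <- cc[seq_len(nd - p + 1L)] / den
  cands <- local_maxima_above(a_hat, config$candidate_threshold)
  merge_candidates(cands, a_hat[cands],
                   round(config$min_separation_ms / dt_ms), decim)
}

# Derivative-threshold candidate search (alternative detector).
candidates_derivative <- function(v, fs, config) {
  decim <- max(1L, floor(fs / config$search_rate_hz))
  nd <- floor(length(v) / decim)
  vd <- if (decim > 1L)
    colMeans(matrix(v[seq_len(nd * decim)], nrow = decim))
  else v
  vd <- as.numeric(stats::filter(vd, rep(1 / 3, 3), sides = 2))
  dt_ms <- 1000 * decim / fs
  d <- c(NA, diff(vd)) / dt_ms
  d[!is.finite(d)] <- 0
  thr <- 0.6 * config$candidate_threshold / config$template_tau_rise
  cands <- local_maxima_above(d, thr)
  # derivative maxima sit mid-rise; step back ~1 ms to the onset side
  cands <- pmax(1L, cands - max(1L, round(1 / dt_ms)))
  merge_candidates(cands, d[pmin(length(d), cands + 1L)],
                   round(config$min_separation_ms / dt_ms), decim)
}

local_maxima_above <- function(x, thr) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  ok <- which(x[2:(n - 1L)] >= thr &
              x[2:(n - 1L)] >= x[1:(n - 2L)] &
              x[2:(n - 1L)] > x[3:n]) + 1L
  ok
}

# Greedy clustering of candidate positions closer than min_sep (in
# decimated samples); keeps the strongest member, flags merged clusters,
# and maps back to full-resolution sample indices.
merge_candidates <- function(pos, score, min_sep, decim) {
  if (!length(pos))
    return(data.frame(index = integer(0), merged = logical(0)))
  o <- order(pos)
  pos <- pos[o]; score <- score[o]
  keep_idx <- integer(0); merged <- logical(0)
  cl_start <- 1L
  for (i in seq_along(pos)) {
    last <- i == length(pos)
    if (!last && pos[i + 1L] - pos[i] < min_sep) next
    cl <- cl_start:i
    best <- cl[which.max(score[cl])]
    keep_idx <- c(keep_idx, pos[best])
    merged <- c(merged, length(cl) > 1L)
    cl_start <- i + 1L
  }
  data.frame(index = (keep_idx - 1L) * decim + 1L, merged = merged)
}

#' Measure the rise time of an event waveform
#'
#' Time from the lower to the upper fractional amplitude (default 10\% to
#' 90\%) on the rising phase, with linear interpolation between samples.
#'
#' @param w numeric waveform containing a single peak above `baseline`.
#' @param dt_ms sample interval (ms).
#' @param baseline baseline level subtracted before thresholding.
#' @param frac lower and upper fractions of the peak amplitude.
#' @return rise time in ms, or `NA` if the crossings cannot be located
#'   (measurement-failure flag).
#' @export
measure_rise_time <- function(w, dt_ms, baseline = 0, frac = c(0.1, 0.9)) {
  rel <- w - baseline
  ip <- which.max(rel)
  pk <- rel[ip]
  if (!is.finite(pk) || pk <= 0 || ip < 2L) return(NA_real_)
  t_lo <- cross_time_rising(rel, ip, frac[1] * pk, dt_ms)
  t_hi <- cross_time_rising(rel, ip, frac[2] * pk, dt_ms)
  if (is.na(t_lo) || is.na(t_hi)) return(NA_real_)
  t_hi - t_lo
}

# Crossing time of `level` on the rising phase. On a noisy waveform the
# last sample below the level is biased late and the first sample above it
# biased early (strongly so where the slope is shallow, e.g. near a rounded
# peak); their average is approximately unbiased and reduces exactly to the
# interpolated crossing on a monotone noise-free rise.
cross_time_rising <- function(rel, ip, level, dt_ms) {
  pre <- rel[seq_len(ip)]
  below <- which(pre[-ip] <= level)
  if (!length(below)) return(NA_real_)
  interp <- function(j) {
    if (pre[j + 1L] == pre[j]) return((j - 1) * dt_ms)
    frac <- (level - pre[j]) / (pre[j + 1L] - pre[j])
    ((j - 1) + max(0, min(1, frac))) * dt_ms
  }
  t_last_below <- interp(max(below))
  above <- which(pre >= level)
  above <- above[above > 1L]
  t_first_above <- if (length(above)) interp(min(above) - 1L) else
    t_last_below
  (t_last_below + t_first_above) / 2
}

#' Measure the decay of an event waveform
#'
#' With `convention = "tau"` (default), fits a single exponential by
#' least squares on the logarithm of the falling phase between the 90\% and
#' 10\% crossings of the peak amplitude and returns the time constant. With
#' `convention = "half"`, returns the time from the peak to the 50\%
#' crossing. The falling phase must be sampled down to the lower crossing;
#' a truncated falling phase yields `NA` (measurement-failure flag).
#'
#' @inheritParams measure_rise_time
#' @param convention `"tau"` or `"half"`.
#' @return decay time in ms, or `NA` on failure.
#' @export
measure_decay_time <- function(w, dt_ms, baseline = 0,
                               convention = c("tau", "half")) {
  convention <- match.arg(convention)
  rel <- w - baseline
  ip <- which.max(rel)
  pk <- rel[ip]
  if (!is.finite(pk) || pk <= 0 || ip >= length(rel) - 1L) return(NA_real_)
  post <- rel[ip:length(rel)]
  if (convention == "half") {
    j <- which(post <= 0.5 * pk)
    if (!length(j)) return(NA_real_)
    j <- j[1L]
    if (j < 2L) return(NA_real_)
    frac <- (0.5 * pk - post[j - 1L]) / (post[j] - post[j - 1L])
    return(((j - 2L) + frac) * dt_ms)
  }
  j90 <- which(post <= 0.9 * pk)
  j10 <- which(post <= 0.1 * pk)
  if (!length(j10) || !length(j90)) return(NA_real_)  # truncated fall
  idx <- j90[1L]:j10[1L]
  y <- post[idx]
  keep <- y > 0
  if (sum(keep) < 3L) return(NA_real_)
  tt <- (idx[keep] - 1) * dt_ms
  slope <- ls_slope(tt, log(y[keep]))
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  -1 / slope
}

#' Measure an evoked EPP amplitude in one sweep
#'
#' The amplitude is the peak depolarization inside the post-stimulus window
#' minus the pre-stimulus baseline (mean of a pre-stimulus segment). The
#' peak is measured on a lightly smoothed copy of the sweep with
#' quadratic-vertex refinement, so a constant baseline shift leaves the
#' amplitude unchanged.
#'
#' @param sweep numeric vector of one sweep's voltage samples (mV).
#' @param sampling_rate sampling rate (Hz).
#' @param stim_time stimulus time within the sweep (s).
#' @param window_ms post-stimulus search window (ms).
#' @param baseline_ms pre-stimulus segment length (ms).
#' @return a one-row data.frame: `stimulus_time`, `baseline`,
#'   `epp_amplitude`.
#' @export
measure_epp <- function(sweep, sampling_rate, stim_time, window_ms = 50,
                        baseline_ms = 20) {
  n <- length(sweep)
  i_stim <- floor(stim_time * sampling_rate) + 1L
  i_end <- i_stim + round(window_ms / 1000 * sampling_rate)
  if (i_end > n)
    stop("post-stimulus window exceeds sweep extent", call. = FALSE)
  if (i_stim < 2L) stop("stimulus at sweep start", call. = FALSE)
  b0 <- max(1L, i_stim - round(baseline_ms / 1000 * sampling_rate))
  baseline <- mean(sweep[b0:(i_stim - 1L)])
  ws <- smooth_sg5(sweep[i_stim:i_end])
  pk <- peak_refine(ws)
  data.frame(stimulus_time = stim_time, baseline = baseline,
             epp_amplitude = pk$value - baseline)
}

#' Measure all sweeps of a sweep set
#'
#' @param sweepset an `nmj_sweepset` from [simulate_evoked()].
#' @param window_ms,baseline_ms passed to [measure_epp()].
#' @return a data.frame with one row per sweep: `sweep`, `stimulus_time`,
#'   `baseline`, `epp_amplitude`, `rmp_at_sweep`.
#' @export
measure_sweeps <- function(sweepset, window_ms = 50, baseline_ms = 20) {
  stopifnot(inherits(sweepset, "nmj_sweepset"))
  res <- lapply(seq_len(ncol(sweepset$sweeps)), function(j)
    measure_epp(sweepset$sweeps[, j], sweepset$sampling_rate,
                sweepset$stim_time, window_ms, baseline_ms))
  out <- do.call(rbind, res)
  out <- cbind(sweep = seq_len(nrow(out)), out)
  out$rmp_at_sweep <- sweepset$rmp
  out
}

#' Spontaneous event frequencies
#'
#' Events per second by class, from the number of events counted over the
#' recording duration.
#'
#' @param events an `nmj_events` data.frame (or any data.frame with an
#'   `event_class` column).
#' @param duration recording duration in s; defaults to the `duration`
#'   attribute of `events`.
#' @return named numeric vector `c(MEPP=, GMEPP=)` in events/s.
#' @export
event_frequency <- function(events, duration = attr(events, "duration")) {
  if (is.null(duration) || !is.numeric(duration) || duration <= 0)
    stop("'duration' must be positive", call. = FALSE)
  c(MEPP = sum(events$event_class == "MEPP") / duration,
    GMEPP = sum(events$event_class == "GMEPP") / duration)
}
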