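#' Normalize a synaptic amplitude to the -75 mV reference potential
#'
#' Applies the driving-force correction
#' \deqn{V_{NOR} = V_{OBS} \times (-75) / RMP,}
#' which rescales an amplitude recorded at resting membrane potential `rmp`
#' to the value it would have at the -75 mV reference. The identity holds at
#' `rmp = -75`; amplitudes recorded at more depolarized potentials are
#' scaled up, at more hyperpolarized potentials scaled down.
#'
#' @param v_obs observed amplitude(s), mV, non-negative.
#' @param rmp recorded resting membrane potential(s), mV, strictly negative;
#'   recycled against `v_obs`.
#' @return normalized amplitude(s), mV.
#' @examples
#' normalize_amplitude(20, -60)  # 25
#' normalize_amplitude(16, -80)  # 15
#' @export
normalize_amplitude <- function(v_obs, rmp) {
  if (!is.numeric(rmp) || any(!is.finite(rmp)) || any(rmp >= 0))
    stop("'rmp' must be strictly negative (mV)", call. = FALSE)
  if (!is.numeric(v_obs) || any(!is.finite(v_obs)) || any(v_obs < 0))
    stop("'v_obs' must be non-negative", call. = FALSE)
  v_obs * (-75) / rmp
}

#' Resting membrane potential acceptance window
#'
#' Fibers are analyzable only when their resting membrane potential is
#' stable and lies between -80 and -60 mV, bounds included.
#'
#' @param rmp resting membrane potential(s), mV.
#' @return logical vector, `TRUE` for accepted.
#' @export
check_rmp <- function(rmp) {
  if (!is.numeric(rmp)) stop("'rmp' must be numeric", call. = FALSE)
  is.finite(rmp) & rmp >= -80 & rmp <= -60
}

#' Mean evoked EPP amplitude of a fiber
#'
#' Averages the first `n_use` (default 60) consecutive sweeps. Each sweep's
#' amplitude is normalized with that sweep's resting membrane potential
#' before averaging. When fewer than `n_use` sweeps are available all are
#' used and the result is flagged as a short record.
#'
#' @param epp_amplitudes numeric vector of per-sweep EPP amplitudes (mV).
#' @param rmp per-sweep resting membrane potential(s), mV (a scalar is
#'   recycled).
#' @param n_use number of consecutive sweeps to average.
#' @return list with `mean_raw`, `mean_nor`, `sem_nor`, `n_used`,
#'   `short_record`.
#' @export
mean_epp <- function(epp_amplitudes, rmp, n_use = 60) {
  if (!length(epp_amplitudes))
    stop("no EPP amplitudes supplied", call. = FALSE)
  rmp <- rep_len(rmp, length(epp_amplitudes))
  k <- as.integer(min(n_use, length(epp_amplitudes)))
  a <- epp_amplitudes[seq_len(k)]
  r <- rmp[seq_len(k)]
  nor <- normalize_amplitude(pmax(a, 0), r)
  list(mean_raw = mean(a), mean_nor = mean(nor),
       sem_nor = stats::sd(nor) / sqrt(k), n_used = k,
       short_record = k < n_use)
}

#' Mean MEPP features of a fiber
#'
#' Averages amplitude, normalized amplitude, rise time and decay time over
#' the first `n_use` (default 100) consecutive MEPPs. Giant events must be
#' excluded before calling; their presence is an error, matching the
#' definition of the MEPP band. Records with fewer than `n_use` MEPPs are
#' averaged in full and flagged.
#'
#' @param events an `nmj_events` data.frame containing MEPP-class events
#'   only.
#' @param rmp the fiber's resting membrane potential (mV).
#' @param n_use number of consecutive MEPPs to average.
#' @return list with `mean_amp`, `mean_amp_nor`, `mean_rise`, `mean_decay`,
#'   `sem_amp`, `sem_amp_nor`, `sem_rise`, `sem_decay`, `n_used`,
#'   `short_record`.
#' @export
mean_mepp <- function(events, rmp, n_use = 100) {
  if (!nrow(events)) stop("no MEPPs supplied", call. = FALSE)
  if (any(events$event_class != "MEPP"))
    stop("'events' must contain MEPP-class events only", call. = FALSE)
  k <- as.integer(min(n_use, nrow(events)))
  e <- events[seq_len(k), , drop = FALSE]
  nor <- normalize_amplitude(e$amplitude, rmp)
  msem <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(NA_real_, NA_real_))
    c(mean(x), stats::sd(x) / sqrt(length(x)))
  }
  amp <- msem(e$amplitude); ann <- msem(nor)
  ris <- msem(e$rise_time); dec <- msem(e$decay_time)
  list(mean_amp = amp[1], mean_amp_nor = ann[1], mean_rise = ris[1],
       mean_decay = dec[1], sem_amp = amp[2], sem_amp_nor = ann[2],
       sem_rise = ris[2], sem_decay = dec[2], n_used = k,
       short_record = k < n_use)
}

#' Quantal content by the ratio-of-means method
#'
#' The mean number of quanta released per nerve impulse, estimated as the
#' normalized mean EPP amplitude divided by the normalized mean MEPP
#' amplitude of the same fiber acquired during the same session. Both
#' inputs must be positive; an undefined MEPP mean yields `NA`.
#'
#' @param mean_epp_nor normalized mean EPP amplitude (mV).
#' @param mean_mepp_nor normalized mean MEPP amplitude (mV).
#' @return dimensionless quantal content (`NA` when undefined).
#' @examples
#' quantal_content(18, 0.6)  # 30
#' @export
quantal_content <- function(mean_epp_nor, mean_mepp_nor) {
  if (!is.finite(mean_epp_nor) || !is.finite(mean_mepp_nor) ||
      mean_mepp_nor <= 0 || mean_epp_nor <= 0)
    return(NA_real_)
  mean_epp_nor / mean_mepp_nor
}

#' Per-fiber GMEPP/MEPP frequency ratio
#'
#' Defined only for fibers exhibiting at least one giant event; fibers
#' without GMEPPs return `NA` and are excluded from group means of this
#' measure.
#'
#' @param gmepp_freq giant-event frequency (events/s).
#' @param mepp_freq MEPP frequency (events/s), `> 0`.
#' @return dimensionless frequency ratio, or `NA` when undefined.
#' @export
gmepp_mepp_ratio <- function(gmepp_freq, mepp_freq) {
  if (!is.finite(gmepp_freq) || !is.finite(mepp_freq)) return(NA_real_)
  if (gmepp_freq <= 0) return(NA_real_)
  if (mepp_freq <= 0) return(NA_real_)
  gmepp_freq / mepp_freq
}

#' Assemble a per-fiber summary record
#'
#' Combines detected spontaneous events, measured evoked sweeps and the
#' fiber's resting membrane potential into one row holding every per-fiber
#' quantity used downstream: raw and normalized mean EPP, mean MEPP
#' features, event frequencies, quantal content and the GMEPP/MEPP ratio.
#' A fiber whose resting potential falls outside the acceptance window is
#' returned with `accepted = FALSE` and all downstream fields `NA`. Missing
#' spontaneous or evoked data leave the corresponding fields `NA`.
#'
#' @param fiber_id identifier for the fiber.
#' @param rmp resting membrane potential (mV).
#' @param events detected events (`nmj_events`), or `NULL`.
#' @param duration spontaneous recording duration (s); defaults to the
#'   events' `duration` attribute.
#' @param epp data.frame from [measure_sweeps()] (columns `epp_amplitude`,
#'   `rmp_at_sweep`), or `NULL`.
#' @param group optional group label.
#' @return a one-row data.frame (a fiber record).
#' @export
summarize_fiber <- function(fiber_id, rmp, events = NULL, duration = NULL,
                            epp = NULL, group = NA_character_) {
  rec <- data.frame(
    fiber_id = fiber_id, group = group, rmp = rmp,
    accepted = check_rmp(rmp), mean_epp = NA_real_, mean_epp_nor = NA_real_,
    mean_mepp = NA_real_, mean_mepp_nor = NA_real_,
    quantal_content = NA_real_, mepp_rise = NA_real_, mepp_decay = NA_real_,
    mepp_freq = NA_real_, gmepp_freq = NA_real_, has_gmepps = NA,
    gmepp_mepp_ratio = NA_real_, n_mepps = NA_integer_,
    n_gmepps = NA_integer_, n_sweeps = NA_integer_,
    short_mepp_record = NA, short_epp_record = NA,
    stringsAsFactors = FALSE)
  if (!rec$accepted) return(rec)

  if (!is.null(events)) {
    if (is.null(duration)) duration <- attr(events, "duration")
    fr <- event_frequency(events, duration)
    rec$mepp_freq <- fr[["MEPP"]]
    rec$gmepp_freq <- fr[["GMEPP"]]
    rec$n_mepps <- sum(events$event_class == "MEPP")
    rec$n_gmepps <- sum(events$event_class == "GMEPP")
    rec$has_gmepps <- rec$n_gmepps > 0L
    rec$gmepp_mepp_ratio <- gmepp_mepp_ratio(rec$gmepp_freq, rec$mepp_freq)
    if (rec$n_mepps > 0L) {
      mm <- mean_mepp(events[events$event_class == "MEPP", , drop = FALSE],
                      rmp)
      rec$mean_mepp <- mm$mean_amp
      rec$mean_mepp_nor <- mm$mean_amp_nor
      rec$mepp_rise <- mm$mean_rise
      rec$mepp_decay <- mm$mean_decay
      rec$short_mepp_record <- mm$short_record
    }
  }
  if (!is.null(epp) && nrow(epp)) {
    me <- mean_epp(epp$epp_amplitude,
                   if ("rmp_at_sweep" %in% names(epp)) epp$rmp_at_sweep
                   else rmp)
    rec$mean_epp <- me$mean_raw
    rec$mean_epp_nor <- me$mean_nor
    rec$n_sweeps <- me$n_used
    rec$short_epp_record <- me$short_record
  }
  if (is.finite(rec$mean_epp_nor) && is.finite(rec$mean_mepp_nor))
    rec$quantal_content <- quantal_content(rec$mean_epp_nor,
                                           rec$mean_mepp_nor)
  rec
}

#' Analyze one simulated or recorded fiber end to end
#'
#' Runs spontaneous event detection on the fiber's gap-free trace, measures
#' its evoked sweeps when present, and assembles the fiber record.
#'
#' @param fiber a fiber entry from [simulate_ensemble()] (a list with
#'   `fiber_id`, `group`, `recording`, `sweeps`), or an `nmj_recording`.
#' @param config a [detect_config()].
#' @return a one-row fiber record data.frame; the detected events are
#'   attached as attribute `"events"`.
#' @export
analyze_fiber <- function(fiber, config = detect_config()) {
  if (inherits(fiber, "nmj_recording"))
    fiber <- list(fiber_id = "fiber", group = NA_character_,
                  recording = fiber, sweeps = NULL)
  rec <- fiber$recording
  ev <- detect_spontaneous(rec$trace, config)
  epp <- if (!is.null(fiber$sweeps)) measure_sweeps(fiber$sweeps) else NULL
  out <- summarize_fiber(fiber$fiber_id, rec$trace$rmp, events = ev,
                         epp = epp, group = fiber$group)
  attr(out, "events") <- ev
  out
}

#' Analyze every fiber of an ensemble
#'
#' @param ensemble an [simulate_ensemble()] result.
#' @param config a [detect_config()].
#' @return a fiber table: one row per fiber, plus an attribute
#'   `"pooled_events"` holding all detected events with fiber and group
#'   columns prepended (the input for pooled amplitude histograms).
#' @export
analyze_ensemble <- function(ensemble, config = detect_config()) {
  stopifnot(inherits(ensemble, "nmj_ensemble"))
  rows <- vector("list", length(ensemble))
  pooled <- vector("list", length(ensemble))
  for (i in seq_along(ensemble)) {
    r <- analyze_fiber(ensemble[[i]], config)
    ev <- attr(r, "events")
    attr(r, "events") <- NULL
    rows[[i]] <- r
    if (nrow(ev))
      pooled[[i]] <- cbind(fiber_id = r$fiber_id, group = r$group,
                           as.data.frame(ev))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "pooled_events") <-
    do.call(rbind, pooled[!vapply(pooled, is.null, TRUE)])
  tab
}
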