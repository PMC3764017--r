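#' Intracellular trace container
#'
#' A minimal container for a uniformly sampled intracellular voltage record:
#' the voltage series (mV), its sampling rate (Hz), the start time (s) and
#' an estimate of the resting membrane potential.
#'
#' @param voltage numeric vector of membrane potential samples (mV).
#' @param sampling_rate sampling rate (Hz).
#' @param start_time time of the first sample (s).
#' @param rmp resting membrane potential estimate (mV); if `NULL`, the
#'   median voltage is used.
#' @return an object of class `nmj_trace`.
#' @export
nmj_trace <- function(voltage, sampling_rate, start_time = 0, rmp = NULL) {
  if (!is.numeric(voltage) || !all(is.finite(voltage)))
    stop("'voltage' must be a finite numeric vector", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be positive", call. = FALSE)
  if (is.null(rmp)) rmp <- stats::median(voltage)
  structure(list(voltage = as.numeric(voltage),
                 sampling_rate = sampling_rate,
                 start_time = start_time, rmp = rmp),
            class = "nmj_trace")
}

#' @export
print.nmj_trace <- function(x, ...) {
  cat(sprintf("<nmj_trace> %d samples, %.6g s @ %g Hz, RMP estimate %.2f mV\n",
              length(x$voltage), length(x$voltage) / x$sampling_rate,
              x$sampling_rate, x$rmp))
  invisible(x)
}

trace_duration <- function(trace) length(trace$voltage) / trace$sampling_rate

#' Simulate a gap-free intracellular recording
#'
#' Generates a continuous voltage trace as a resting-potential baseline plus
#' additive white Gaussian noise, with spontaneous events superposed. MEPP
#' times follow a homogeneous Poisson process of rate `mepp_rate` with
#' amplitudes drawn from a Gaussian truncated at zero; the GMEPP process is
#' independent, with its own rate and an amplitude distribution truncated at
#' 1 mV. Events may overlap additively (no refractory period). Every
#' injected event is listed in the returned ground truth, whose class labels
#' reflect the generating process, not the detector's amplitude bands.
#'
#' @param params a [sim_params()] object. When `params$seed` is set the
#'   output is fully reproducible.
#' @return an object of class `nmj_recording`: a list with elements
#'   `trace` (an [nmj_trace()]), `truth` (data.frame with columns `time` s,
#'   `amplitude` mV, `class` "MEPP"/"GMEPP") and `params`.
#' @examples
#' rec <- simulate_gapfree(sim_params(duration = 10, seed = 1))
#' nrow(rec$truth)
#' @export
simulate_gapfree <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$sampling_rate
  n <- round(fs * params$duration)
  v <- stats::rnorm(n, 0, params$noise_sd)
  truth <- draw_event_train(params)
  if (nrow(truth)) {
    klen <- ceiling(fs * 8 * params$tau_decay / 1000)
    tk <- (seq_len(klen) - 1) / fs * 1000
    kern <- event_waveform(tk, 1, params$tau_rise, params$tau_decay)
    for (i in seq_len(nrow(truth))) {
      i0 <- floor(truth$time[i] * fs) + 1L
      idx <- i0:min(n, i0 + klen - 1L)
      v[idx] <- v[idx] + truth$amplitude[i] * kern[seq_along(idx)]
    }
  }
  v <- v + params$rmp
  structure(list(trace = nmj_trace(v, fs, rmp = params$rmp),
                 truth = truth, params = params),
            class = "nmj_recording")
}

draw_event_train <- function(params) {
  dur <- params$duration
  n_m <- stats::rpois(1, params$mepp_rate * dur)
  n_g <- stats::rpois(1, params$gmepp_rate * dur)
  t_m <- sort(stats::runif(n_m, 0, dur))
  a_m <- rtrunc_norm(n_m, params$mepp_amp_mean, params$mepp_amp_sd, 0)
  t_g <- sort(stats::runif(n_g, 0, dur))
  a_g <- rtrunc_norm(n_g, params$gmepp_amp_mean, params$gmepp_amp_sd, 1)
  ev <- data.frame(time = c(t_m, t_g), amplitude = c(a_m, a_g),
                   class = rep(c("MEPP", "GMEPP"), c(n_m, n_g)),
                   stringsAsFactors = FALSE)
  ev[order(ev$time), , drop = FALSE]
}

#' @export
print.nmj_recording <- function(x, ...) {
  cat(sprintf("<nmj_recording> %.6g s @ %g Hz, %d ground-truth events (%d MEPP, %d GMEPP)\n",
              x$params$duration, x$params$sampling_rate, nrow(x$truth),
              sum(x$truth$class == "MEPP"), sum(x$truth$class == "GMEPP")))
  invisible(x)
}

#' Simulate a stimulus-locked sweep set of evoked responses
#'
#' For each of `n_sweeps` stimuli the quantal count is drawn from a Poisson
#' distribution with mean `quantal_mean`, and the true EPP amplitude is the
#' sum of that many independent draws from the fiber's MEPP amplitude
#' distribution (linear quantal summation; no nonlinear-summation
#' correction is applied anywhere in the package). Each stored sweep
#' contains the resting baseline, recording noise, and a single EPP kernel
#' at a fixed latency after the stimulus.
#'
#' @inheritParams simulate_gapfree
#' @return an object of class `nmj_sweepset`: a list with `sweeps` (matrix,
#'   samples x sweeps, mV), `sampling_rate`, `stim_time` (s), `rmp`, `truth`
#'   (data.frame with `sweep`, `quantal_count`, `true_amplitude`) and
#'   `params`.
#' @export
simulate_evoked <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$sampling_rate
  ns <- params$n_sweeps
  k <- stats::rpois(ns, params$quantal_mean)
  amp <- vapply(k, function(ki) {
    if (ki == 0L) 0
    else sum(rtrunc_norm(ki, params$mepp_amp_mean, params$mepp_amp_sd, 0))
  }, numeric(1))
  nsamp <- round(fs * params$sweep_duration)
  m <- matrix(stats::rnorm(nsamp * ns, 0, params$noise_sd), nrow = nsamp)
  onset <- floor((params$stim_time + params$epp_latency) * fs) + 1L
  klen <- min(nsamp - onset + 1L, ceiling(fs * 8 * params$tau_decay / 1000))
  tk <- (seq_len(klen) - 1) / fs * 1000
  kern <- event_waveform(tk, 1, params$tau_rise, params$tau_decay)
  idx <- onset:(onset + klen - 1L)
  for (j in seq_len(ns)) if (amp[j] > 0)
    m[idx, j] <- m[idx, j] + amp[j] * kern
  m <- m + params$rmp
  structure(list(sweeps = m, sampling_rate = fs,
                 stim_time = params$stim_time, rmp = params$rmp,
                 truth = data.frame(sweep = seq_len(ns), quantal_count = k,
                                    true_amplitude = amp),
                 params = params),
            class = "nmj_sweepset")
}

#' @export
print.nmj_sweepset <- function(x, ...) {
  cat(sprintf("<nmj_sweepset> %d sweeps of %.3g s @ %g Hz, stimulus at %.3g s\n",
              ncol(x$sweeps), nrow(x$sweeps) / x$sampling_rate,
              x$sampling_rate, x$stim_time))
  invisible(x)
}

#' Simulate a multi-fiber ensemble with known group labels
#'
#' Draws independent fibers from one or more [population_preset()]s. Each
#' fiber receives its own deterministic seed (derived from the master seed
#' with [derive_seed()]), a resting membrane potential drawn uniformly in
#' \[-80, -60\] mV, and fiber-level parameters drawn around the preset means
#' with the preset's between-fiber SDs. Its gap-free recording and
#' (optionally) its evoked sweep set are then simulated. True group labels
#' are retained for recovery tests.
#'
#' @param presets a named integer vector, e.g.
#'   `c("WT-young" = 40, "SOD1-pre" = 40)`, or a list of
#'   `population_preset` objects with an `n_fibers` attribute set via the
#'   names of the list.
#' @param seed master integer seed for the ensemble.
#' @param sampling_rate,duration recording geometry applied to every fiber.
#' @param evoked logical; also simulate evoked sweep sets (default `TRUE`).
#' @param n_sweeps sweeps per fiber when `evoked`.
#' @return an object of class `nmj_ensemble`: a list of fibers, each a list
#'   with `fiber_id`, `group`, `params`, `recording` and `sweeps` (or
#'   `NULL`).
#' @examples
#' ens <- simulate_ensemble(c("SOD1a" = 2, "SOD1b" = 2), seed = 1,
#'                          sampling_rate = 2000, duration = 10,
#'                          evoked = FALSE)
#' vapply(ens, `[[`, "", "group")
#' @export
simulate_ensemble <- function(presets, seed, sampling_rate = 10000,
                              duration = 100, evoked = TRUE, n_sweeps = 60) {
  mix <- resolve_preset_mix(presets)
  if (!length(mix)) stop("empty preset mix", call. = FALSE)
  fibers <- vector("list", sum(vapply(mix, `[[`, 0, "n")))
  fid <- 0L
  for (entry in mix) {
    preset <- entry$preset
    for (j in seq_len(entry$n)) {
      fid <- fid + 1L
      fseed <- derive_seed(seed, fid)
      set.seed(fseed)
      fp <- draw_fiber_params(preset, sampling_rate = sampling_rate,
                              duration = duration, n_sweeps = n_sweeps)
      fp$seed <- derive_seed(fseed, 1L)
      rec <- simulate_gapfree(fp)
      sw <- NULL
      if (evoked) {
        fp2 <- fp
        fp2$seed <- derive_seed(fseed, 2L)
        sw <- simulate_evoked(fp2)
      }
      fibers[[fid]] <- list(fiber_id = sprintf("f%03d", fid),
                            group = preset$name, params = fp,
                            recording = rec, sweeps = sw)
    }
  }
  structure(fibers, class = "nmj_ensemble", seed = seed)
}

resolve_preset_mix <- function(presets) {
  if (is.numeric(presets)) {
    if (is.null(names(presets)) || any(!nzchar(names(presets))))
      stop("'presets' given as counts must be named by preset", call. = FALSE)
    if (any(presets < 1))
      stop("each preset must contribute at least one fiber", call. = FALSE)
    lapply(seq_along(presets), function(i)
      list(preset = population_preset(names(presets)[i]),
           n = as.integer(presets[i])))
  } else if (is.list(presets)) {
    lapply(presets, function(e) {
      if (inherits(e, "population_preset")) return(list(preset = e, n = 1L))
      if (is.list(e) && inherits(e$preset, "population_preset")) {
        if (is.null(e$n) || e$n < 1)
          stop("each preset must contribute at least one fiber",
               call. = FALSE)
        return(list(preset = e$preset, n = as.integer(e$n)))
      }
      stop("cannot interpret preset mix entry", call. = FALSE)
    })
  } else stop("cannot interpret 'presets'", call. = FALSE)
}

#' @export
print.nmj_ensemble <- function(x, ...) {
  g <- table(vapply(x, `[[`, "", "group"))
  cat(sprintf("<nmj_ensemble> %d fibers (%s)\n", length(x),
              paste(sprintf("%s: %d", names(g), g), collapse = ", ")))
  invisible(x)
}
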