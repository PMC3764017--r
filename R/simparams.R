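#' Simulation parameters for one fiber
#'
#' Bundles and validates the generative parameters of a single simulated
#' muscle fiber: the resting membrane potential, recording noise, the
#' Poisson rates and truncated-Gaussian amplitude distributions of the
#' spontaneous MEPP and GMEPP processes, the event kernel time constants,
#' and the evoked-response settings (stimulation rate, number of sweeps,
#' mean quantal count per stimulus).
#'
#' @param sampling_rate sampling rate in Hz (default 10000).
#' @param duration gap-free recording length in s (default 100, the
#'   acquisition window over which spontaneous event frequencies are
#'   counted).
#' @param rmp resting membrane potential in mV; must lie in the acceptance
#'   window \[-80, -60\].
#' @param noise_sd additive white Gaussian recording noise SD (mV).
#' @param mepp_rate,gmepp_rate Poisson event rates (events/s), `>= 0`.
#' @param mepp_amp_mean,mepp_amp_sd MEPP amplitude distribution (mV);
#'   amplitudes are drawn from a Gaussian truncated at zero.
#' @param gmepp_amp_mean,gmepp_amp_sd GMEPP amplitude distribution (mV);
#'   truncated below at 1 mV so that generated giants lie in the giant band.
#' @param tau_rise,tau_decay event kernel time constants (ms), positive;
#'   the defaults are calibrated so the measured kinetics are a ~1.3 ms
#'   10--90\% rise and a ~4 ms fitted decay constant, typical of diaphragm
#'   MEPPs (see [calibrate_kernel()]).
#' @param stim_rate nerve stimulation rate (Hz, default 0.5).
#' @param n_sweeps number of evoked sweeps (default 60, the averaging
#'   window for the mean EPP).
#' @param quantal_mean mean quantal count per stimulus (dimensionless).
#' @param sweep_duration stored length of each evoked sweep (s).
#' @param stim_time stimulus time within a sweep (s).
#' @param epp_latency synaptic latency from stimulus to EPP onset (s).
#' @param seed optional integer seed; identical parameters and seed yield
#'   bit-identical simulations.
#' @return an object of class `sim_params` (a validated list).
#' @seealso [simulate_gapfree()], [simulate_evoked()], [population_preset()]
#' @export
sim_params <- function(sampling_rate = 10000, duration = 100, rmp = -70,
                       noise_sd = 0.05, mepp_rate = 0.6,
                       mepp_amp_mean = 0.55, mepp_amp_sd = 0.09,
                       gmepp_rate = 0, gmepp_amp_mean = 2.0,
                       gmepp_amp_sd = 0.5, tau_rise = 2.95,
                       tau_decay = 3.56, stim_rate = 0.5, n_sweeps = 60,
                       quantal_mean = 30, sweep_duration = 0.2,
                       stim_time = 0.05, epp_latency = 0.0015,
                       seed = NULL) {
  p <- list(sampling_rate = sampling_rate, duration = duration, rmp = rmp,
            noise_sd = noise_sd, mepp_rate = mepp_rate,
            mepp_amp_mean = mepp_amp_mean, mepp_amp_sd = mepp_amp_sd,
            gmepp_rate = gmepp_rate, gmepp_amp_mean = gmepp_amp_mean,
            gmepp_amp_sd = gmepp_amp_sd, tau_rise = tau_rise,
            tau_decay = tau_decay, stim_rate = stim_rate,
            n_sweeps = n_sweeps, quantal_mean = quantal_mean,
            sweep_duration = sweep_duration, stim_time = stim_time,
            epp_latency = epp_latency, seed = seed)
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(p$sampling_rate) || p$sampling_rate <= 0)
    stop("'sampling_rate' must be a positive number", call. = FALSE)
  if (!num1(p$duration) || p$duration <= 0)
    stop("'duration' must be positive", call. = FALSE)
  n <- p$sampling_rate * p$duration
  if (abs(n - round(n)) > 1e-6)
    stop("sampling_rate * duration must be an integer sample count",
         call. = FALSE)
  if (!num1(p$rmp) || p$rmp < -80 || p$rmp > -60)
    stop("'rmp' must lie in the acceptance window [-80, -60] mV",
         call. = FALSE)
  for (f in c("mepp_rate", "gmepp_rate", "stim_rate"))
    if (!num1(p[[f]]) || p[[f]] < 0)
      stop(sprintf("'%s' must be >= 0", f), call. = FALSE)
  for (f in c("noise_sd", "mepp_amp_sd", "gmepp_amp_sd"))
    if (!num1(p[[f]]) || p[[f]] < 0)
      stop(sprintf("'%s' must be >= 0", f), call. = FALSE)
  if (!num1(p$quantal_mean) || p$quantal_mean < 0)
    stop("'quantal_mean' must be >= 0", call. = FALSE)
  if (!num1(p$n_sweeps) || p$n_sweeps < 1 ||
      abs(p$n_sweeps - round(p$n_sweeps)) > 0)
    stop("'n_sweeps' must be a positive integer", call. = FALSE)
  check_taus(p$tau_rise, p$tau_decay)
  if (!num1(p$mepp_amp_mean) || p$mepp_amp_mean <= 0)
    stop("'mepp_amp_mean' must be positive", call. = FALSE)
  if (!num1(p$gmepp_amp_mean) || p$gmepp_amp_mean <= 1)
    stop("'gmepp_amp_mean' must exceed 1 mV", call. = FALSE)
  if (!num1(p$sweep_duration) || p$sweep_duration <= p$stim_time)
    stop("'sweep_duration' must exceed 'stim_time'", call. = FALSE)
  if (!is.null(p$seed) &&
      (!num1(p$seed) || abs(p$seed - round(p$seed)) > 0))
    stop("'seed' must be an integer or NULL", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  trace: %g s @ %g Hz, RMP %g mV, noise SD %g mV\n",
              x$duration, x$sampling_rate, x$rmp, x$noise_sd))
  cat(sprintf("  MEPPs: %g /s, amp %g +/- %g mV; GMEPPs: %g /s, amp %g +/- %g mV\n",
              x$mepp_rate, x$mepp_amp_mean, x$mepp_amp_sd,
              x$gmepp_rate, x$gmepp_amp_mean, x$gmepp_amp_sd))
  cat(sprintf("  kernel: tau_rise %.3g ms, tau_decay %.3g ms\n",
              x$tau_rise, x$tau_decay))
  cat(sprintf("  evoked: %d sweeps @ %g Hz, mean quantal count %g\n",
              x$n_sweeps, x$stim_rate, x$quantal_mean))
  invisible(x)
}

#' Deterministic per-fiber seed derivation
#'
#' Maps a master seed and a fiber index to a stream seed via a fixed
#' multiplicative-congruential step modulo 2^31 - 1. Stable across platforms
#' and R versions; the same master seed always yields the same family of
#' per-fiber seeds.
#'
#' @param master integer master seed.
#' @param index positive integer stream index.
#' @return a single integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- as.numeric(master) %% m
  s <- (s * 48271) %% m
  s <- (s + (as.numeric(index) %% m) * 69621) %% m
  as.integer(s)
}

# population presets -------------------------------------------------------

preset_names <- function() c("WT-young", "SOD1-pre", "WT-adult", "SOD1a", "SOD1b")

#' Population presets for fiber ensembles
#'
#' A population preset couples a [sim_params()] template (the expected
#' fiber) with between-fiber standard deviations, so that ensembles drawn
#' from it reproduce both the group means and the fiber-to-fiber spread of
#' the cohort it emulates. Five presets are available:
#' `"WT-young"` and `"SOD1-pre"` (pre-symptomatic cohorts, 4--6 weeks),
#' `"WT-adult"` (12--15 weeks controls), and `"SOD1a"`/`"SOD1b"` (the low-
#' and high-MEPP-amplitude junction subpopulations of symptomatic
#' SOD1(G93A) mice).
#'
#' Group means come from [nmj_reference_summaries()]; between-fiber SDs are
#' reconstructed from the printed standard errors as `sem * sqrt(n)`.
#' Kernel time constants are calibrated with [calibrate_kernel()] so that
#' *measured* rise and decay times match the cohort means. The MEPP
#' amplitude SD within a fiber defaults to 0.09 mV; GMEPP amplitudes default
#' to 2.0 +/- 0.5 mV (truncated at 1 mV), a typical giant-event scale.
#'
#' @param name one of `"WT-young"`, `"SOD1-pre"`, `"WT-adult"`, `"SOD1a"`,
#'   `"SOD1b"`.
#' @param sampling_rate,duration recording geometry passed to the template.
#' @return an object of class `population_preset`: a list with elements
#'   `name`, `means` (named numeric), `between_sd` (named numeric) and
#'   `template` (a `sim_params` object for the average fiber).
#' @export
population_preset <- function(name, sampling_rate = 10000, duration = 100) {
  name <- match.arg(name, preset_names())
  ref <- nmj_reference_summaries()
  grab <- function(measure) {
    i <- which(ref$group == name & ref$measure == measure)
    ref[i[1L], c("mean", "sem", "n")]
  }
  fields <- c(mepp_amp = "mean_mepp", mepp_rate = "mepp_freq",
              gmepp_rate = "gmepp_freq", quantal_mean = "quantal_content",
              rise = "mepp_rise", decay = "mepp_decay")
  means <- numeric(0); between <- numeric(0)
  for (f in names(fields)) {
    r <- grab(fields[[f]])
    means[f] <- r$mean
    between[f] <- r$sem * sqrt(r$n)
  }
  rise_t <- min(means[["rise"]], 0.36 * means[["decay"]])
  taus <- calibrate_kernel(rise_t, means[["decay"]])
  template <- sim_params(
    sampling_rate = sampling_rate, duration = duration,
    rmp = grab("rmp")$mean,
    mepp_rate = means[["mepp_rate"]], mepp_amp_mean = means[["mepp_amp"]],
    gmepp_rate = means[["gmepp_rate"]],
    tau_rise = taus[["tau_rise"]], tau_decay = taus[["tau_decay"]],
    quantal_mean = means[["quantal_mean"]])
  structure(list(name = name, means = means, between_sd = between,
                 template = template),
            class = "population_preset")
}

#' @export
print.population_preset <- function(x, ...) {
  cat(sprintf("<population_preset> %s\n", x$name))
  m <- rbind(mean = x$means, between_fiber_sd = x$between_sd)
  print(round(m, 3))
  invisible(x)
}

# Draw one fiber's sim_params from a preset, using the current RNG stream.
# Between-fiber draws are truncated at plausibility floors so every fiber
# remains analyzable; the GMEPP rate is censored at zero, which produces
# fibers that exhibit no giant events.
draw_fiber_params <- function(preset, sampling_rate = NULL, duration = NULL,
                              n_sweeps = 60) {
  stopifnot(inherits(preset, "population_preset"))
  tpl <- preset$template
  if (is.null(sampling_rate)) sampling_rate <- tpl$sampling_rate
  if (is.null(duration)) duration <- tpl$duration
  m <- preset$means; s <- preset$between_sd
  rmp <- stats::runif(1, -80, -60)
  # gamma draws carry the cohort mean and SD exactly on positive support
  # (a truncated normal would inflate the mean when the SD is large)
  amp <- rgamma_ms(m[["mepp_amp"]], s[["mepp_amp"]])
  rate <- max(rgamma_ms(m[["mepp_rate"]], s[["mepp_rate"]]), 0.02)
  # censored normal: the point mass at zero yields fibers without giants
  grate <- max(0, stats::rnorm(1, m[["gmepp_rate"]], s[["gmepp_rate"]]))
  qm <- max(rgamma_ms(m[["quantal_mean"]], s[["quantal_mean"]]), 1)
  repeat {
    rise <- rtrunc_norm(1, m[["rise"]], s[["rise"]], lower = 0.35)
    decay <- rtrunc_norm(1, m[["decay"]], s[["decay"]], lower = 1.2)
    if (rise <= 0.36 * decay) break  # kernel-family feasibility
  }
  taus <- calibrate_kernel(rise, decay)
  sim_params(sampling_rate = sampling_rate, duration = duration, rmp = rmp,
             noise_sd = tpl$noise_sd, mepp_rate = rate, mepp_amp_mean = amp,
             mepp_amp_sd = tpl$mepp_amp_sd, gmepp_rate = grate,
             gmepp_amp_mean = tpl$gmepp_amp_mean,
             gmepp_amp_sd = tpl$gmepp_amp_sd,
             tau_rise = taus[["tau_rise"]], tau_decay = taus[["tau_decay"]],
             n_sweeps = n_sweeps, quantal_mean = qm)
}

# one gamma draw parameterized by mean and SD
rgamma_ms <- function(mean, sd) {
  if (sd <= 0) return(mean)
  shape <- (mean / sd)^2
  stats::rgamma(1, shape = shape, scale = sd^2 / mean)
}

# Gaussian truncated below at `lower`, by rejection.
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(max(mean, lower), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
    guard <- guard + 1L
    if (guard > 10000L) { x[bad] <- lower + abs(sd) * 1e-3; break }
  }
  x
}
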