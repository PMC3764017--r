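#' Write a trace to the columnar text format
#'
#' The format is a '#'-prefixed metadata header (sampling rate, resting
#' membrane potential, start time, column units) followed by two
#' tab-separated columns, `time_s` and `voltage_mV`, printed with 12
#' significant digits so that a write/read round trip is lossless well
#' beyond the stated 9-digit precision.
#'
#' @param trace an [nmj_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "nmj_trace"))
  tt <- trace$start_time + (seq_along(trace$voltage) - 1) /
    trace$sampling_rate
  hdr <- c(sprintf("# sampling_rate_hz: %.12g", trace$sampling_rate),
           sprintf("# rmp_mv: %.12g", trace$rmp),
           sprintf("# start_time_s: %.12g", trace$start_time),
           "# columns: time_s voltage_mV")
  writeLines(c(hdr, paste(sprintf("%.12g", tt), sprintf("%.12g",
                                                        trace$voltage),
                          sep = "\t")), path)
  invisible(path)
}

#' Read a trace from the columnar text format
#'
#' Validates the header (the sampling rate is mandatory) and the time
#' column, which must be uniformly sampled at the stated rate; gaps or
#' irregular sampling are a parse error.
#'
#' @param path file written by [write_trace()].
#' @return an [nmj_trace()].
#' @export
read_trace <- function(path) {
  head_lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    m <- regmatches(l, regexec("^#\\s*([a-z_]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  if (is.null(meta$sampling_rate_hz))
    stop("trace header is missing the required field 'sampling_rate_hz'",
         call. = FALSE)
  fs <- as.numeric(meta$sampling_rate_hz)
  if (!is.finite(fs) || fs <= 0)
    stop("invalid 'sampling_rate_hz' in trace header", call. = FALSE)
  dat <- utils::read.table(path, comment.char = "#", sep = "\t",
                           col.names = c("time_s", "voltage_mV"))
  if (nrow(dat) < 2L) stop("trace has fewer than 2 samples", call. = FALSE)
  dt <- diff(dat$time_s)
  if (any(abs(dt - 1 / fs) > 1e-6 / fs))
    stop("non-uniform sampling: time column does not match sampling_rate",
         call. = FALSE)
  rmp <- if (!is.null(meta$rmp_mv)) as.numeric(meta$rmp_mv) else NULL
  start <- if (!is.null(meta$start_time_s)) as.numeric(meta$start_time_s)
  else dat$time_s[1]
  nmj_trace(dat$voltage_mV, fs, start_time = start, rmp = rmp)
}

#' Write a detected-events table
#'
#' Tab-separated table, one row per event, preceded by a '#' header
#' documenting the measurement conventions (rise/decay definitions and
#' amplitude bands) recorded by the detector.
#'
#' @param events an `nmj_events` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  hdr <- c(sprintf("# duration_s: %.12g", attr(events, "duration")),
           sprintf("# rise_time: %s", attr(events, "rise_convention")),
           sprintf("# decay_time: %s", attr(events, "decay_convention")),
           sprintf("# amplitude_bands: %s", attr(events, "amplitude_bands")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(events), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Unknown keys are
#' rejected; the fully resolved configuration is logged with every run.
#'
#' @param ... overrides of the defaults: `groups` (named fiber counts per
#'   preset), `seed`, `sampling_rate`, `duration`, `evoked`, `n_sweeps`,
#'   `classify_group` (preset name to split by amplitude, or `NA`),
#'   `cutoff` (`NA` for the pooled-mean rule), `bin_width`,
#'   `mepp_min`, `gmepp_min`, `candidate_threshold`, `detector`,
#'   `validate_tol`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    groups = c("WT-young" = 10, "SOD1-pre" = 10),
    seed = 1L, sampling_rate = 10000, duration = 100, evoked = TRUE,
    n_sweeps = 60, classify_group = NA_character_, cutoff = NA_real_,
    bin_width = 0.05, mepp_min = 0.2, gmepp_min = 1.0,
    candidate_threshold = 0.15, detector = "template", validate_tol = 0.05)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  structure(cfg, class = "run_config")
}

format_config <- function(cfg) {
  vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (!is.null(names(v)) && length(v) > 1)
      v <- paste(sprintf("%s=%s", names(v), v), collapse = ",")
    sprintf("%s: %s", k, paste(format(v), collapse = " "))
  }, "")
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end: simulate the configured fiber ensemble,
#' detect spontaneous events and measure evoked sweeps on every fiber,
#' assemble the fiber table, optionally decompose one group's pooled MEPP
#' amplitude distribution and split it at the amplitude cutoff, and compare
#' the resulting groups. When `out_dir` is given, writes `fibers.tsv`,
#' `events.tsv`, `summary.tsv`, `comparisons.tsv`, `fits.json` and
#' `log.txt` there. Identical configuration and seed reproduce identical
#' tables.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if missing).
#' @return invisibly, a list with `fiber_table`, `groups`, `summary`,
#'   and when classification ran: `fits`, `selection`, `assignment`,
#'   `validation`; plus the `log` lines.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!length(config$groups))
    stop("configuration names no input groups", call. = FALSE)
  log <- c("resolved configuration:",
           paste0("  ", format_config(config)))
  say <- function(...) log <<- c(log, sprintf(...))

  ens <- simulate_ensemble(config$groups, seed = config$seed,
                           sampling_rate = config$sampling_rate,
                           duration = config$duration,
                           evoked = config$evoked,
                           n_sweeps = config$n_sweeps)
  say("simulate: %d fibers in %d groups", length(ens),
      length(config$groups))

  dcfg <- detect_config(detector = config$detector,
                        mepp_min = config$mepp_min,
                        gmepp_min = config$gmepp_min,
                        candidate_threshold = config$candidate_threshold)
  tab <- analyze_ensemble(ens, dcfg)
  pooled <- attr(tab, "pooled_events")
  say("detect+quantify: %d events across %d accepted fibers",
      if (is.null(pooled)) 0L else nrow(pooled), sum(tab$accepted))

  groups <- split(tab, tab$group)
  fits <- NULL; selection <- NULL; assignment <- NULL; validation <- NULL
  if (!is.na(config$classify_group)) {
    g <- config$classify_group
    if (!g %in% tab$group)
      stop("classify_group not present in the ensemble", call. = FALSE)
    amps <- pooled$amplitude[pooled$group == g &
                               pooled$event_class == "MEPP"]
    hist <- build_histogram(amps, bin_width = config$bin_width)
    failed <- function(e) list(converged = FALSE,
                               message = conditionMessage(e))
    single <- tryCatch(fit_gaussian(hist), error = failed)
    double <- tryCatch(fit_two_gaussians(hist), error = failed)
    selection <- select_model(single, double)
    cutoff <- if (is.na(config$cutoff)) NULL else config$cutoff
    assignment <- classify_fibers(tab[tab$group == g, , drop = FALSE],
                                  cutoff)
    say("classify: %s; cutoff %.3f mV; %d A / %d B fibers",
        selection$decision, attr(assignment, "cutoff"),
        sum(assignment$label == "A", na.rm = TRUE),
        sum(assignment$label == "B", na.rm = TRUE))
    sub <- merge(tab[tab$group == g, , drop = FALSE],
                 assignment[, c("fiber_id", "label")], by = "fiber_id")
    ga <- sub[sub$label %in% "A", , drop = FALSE]
    gb <- sub[sub$label %in% "B", , drop = FALSE]
    fit_sub <- function(ids) {
      a <- pooled$amplitude[pooled$group == g &
                              pooled$event_class == "MEPP" &
                              pooled$fiber_id %in% ids]
      if (length(a) < 30) return(NULL)
      tryCatch(fit_gaussian(build_histogram(a, bin_width = config$bin_width)),
               error = failed)
    }
    fa <- fit_sub(ga$fiber_id); fb <- fit_sub(gb$fiber_id)
    if (!is.null(fa) && !is.null(fb)) {
      validation <- validate_grouping(fa, fb, double,
                                      tol = config$validate_tol)
      say("validate_grouping: %s", as.character(validation))
    }
    fits <- list(single = single, double = double, group_a = fa,
                 group_b = fb)
    groups[[g]] <- NULL
    if (nrow(ga)) groups[[paste0(g, "-a")]] <- ga
    if (nrow(gb)) groups[[paste0(g, "-b")]] <- gb
  }

  summary <- build_summary_table(groups)
  say("compare: %d measures x %d group pairs",
      length(unique(summary$summary$measure)),
      length(utils::combn(names(groups), 2L, simplify = FALSE)))

  res <- list(fiber_table = tab, groups = groups, summary = summary,
              fits = fits, selection = selection,
              assignment = assignment, validation = validation, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(tab, "fibers.tsv")
    if (!is.null(pooled)) wt(pooled, "events.tsv")
    wt(summary$summary, "summary.tsv")
    wt(summary$comparisons, "comparisons.tsv")
    if (!is.null(fits)) {
      strip <- function(f) if (is.null(f)) NULL else
        f[intersect(names(f), c("n_components", "height", "mean", "sd",
                                "r_squared", "converged"))]
      jsonlite::write_json(
        list(fits = lapply(fits, strip),
             selection = selection[c("decision", "delta_r2", "separation",
                                     "height_frac")],
             cutoff = attr(assignment, "cutoff"),
             validation = as.character(validation)),
        file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA,
        null = "null")
    }
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  invisible(res)
}
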