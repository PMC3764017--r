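#' Published cohort summary statistics
#'
#' Per-group summary statistics (mean, SEM, n) for the wild-type and
#' SOD1(G93A) mouse diaphragm cohorts that the simulation presets emulate:
#' pre-symptomatic (4--6 weeks) and symptomatic (12--15 weeks) animals, the
#' latter both pooled and split into the low-amplitude (SOD1a) and
#' high-amplitude (SOD1b) junction subgroups. Rows cover resting membrane
#' potential, evoked EPP amplitude (raw and normalized to -75 mV), quantal
#' content, MEPP amplitude/kinetics/frequency, GMEPP frequency and the
#' per-fiber GMEPP/MEPP frequency ratio, plus Rotarod latency-to-fall and
#' counts of junctions exhibiting GMEPPs.
#'
#' These printed values serve two purposes: they parameterize
#' [population_preset()] and they are the inputs of the worked percent-change
#' examples (e.g. the ~31\% quantal content increase in the pre-symptomatic
#' transgenics).
#'
#' @return a data.frame with columns `cohort` (pre_symptomatic, symptomatic,
#'   symptomatic_split), `measure`, `group`, `mean`, `sem`, `n`.
#' @examples
#' ref <- nmj_reference_summaries()
#' subset(ref, measure == "quantal_content" & cohort == "pre_symptomatic")
#' @export
nmj_reference_summaries <- function() {
  row <- function(cohort, measure, group, mean, sem, n)
    data.frame(cohort = cohort, measure = measure, group = group,
               mean = mean, sem = sem, n = n, stringsAsFactors = FALSE)
  rbind(
    # motor performance, symptomatic cohort (n = mice)
    row("symptomatic", "latency_fall_10rpm", "WT",   263, 13.9, 10),
    row("symptomatic", "latency_fall_10rpm", "SOD1", 181, 31.3, 10),
    row("pre_symptomatic", "latency_fall_10rpm", "WT",   257, 11.8, 16),
    row("pre_symptomatic", "latency_fall_10rpm", "SOD1", 236, 21.8, 11),

    # pre-symptomatic cohort (4-6 weeks; n = fibers)
    row("pre_symptomatic", "rmp",             "WT-young", -69.0, 1.74, 40),
    row("pre_symptomatic", "mean_epp",        "WT-young", 16.6, 1.48, 40),
    row("pre_symptomatic", "mean_epp_nor",    "WT-young", 18.3, 1.64, 40),
    row("pre_symptomatic", "quantal_content", "WT-young", 29.0, 1.89, 40),
    row("pre_symptomatic", "mean_mepp",       "WT-young", 0.55, 0.02, 40),
    row("pre_symptomatic", "mepp_rise",       "WT-young", 1.32, 0.07, 40),
    row("pre_symptomatic", "mepp_decay",      "WT-young", 4.00, 0.15, 40),
    row("pre_symptomatic", "mepp_freq",       "WT-young", 0.64, 0.07, 40),
    row("pre_symptomatic", "n_with_gmepps",   "WT-young", 30, NA, 40),
    row("pre_symptomatic", "gmepp_freq",      "WT-young", 0.23, 0.06, 30),
    row("pre_symptomatic", "gmepp_mepp_ratio","WT-young", 2.27, 1.35, 30),

    row("pre_symptomatic", "rmp",             "SOD1-pre", -67.6, 1.80, 40),
    row("pre_symptomatic", "mean_epp",        "SOD1-pre", 24.3, 1.61, 40),
    row("pre_symptomatic", "mean_epp_nor",    "SOD1-pre", 26.8, 1.54, 40),
    row("pre_symptomatic", "quantal_content", "SOD1-pre", 38.1, 2.42, 40),
    row("pre_symptomatic", "mean_mepp",       "SOD1-pre", 0.63, 0.02, 40),
    row("pre_symptomatic", "mepp_rise",       "SOD1-pre", 1.11, 0.08, 40),
    row("pre_symptomatic", "mepp_decay",      "SOD1-pre", 3.67, 0.14, 40),
    row("pre_symptomatic", "mepp_freq",       "SOD1-pre", 0.59, 0.06, 40),
    row("pre_symptomatic", "n_with_gmepps",   "SOD1-pre", 33, NA, 40),
    row("pre_symptomatic", "gmepp_freq",      "SOD1-pre", 0.44, 0.08, 33),
    row("pre_symptomatic", "gmepp_mepp_ratio","SOD1-pre", 1.86, 0.45, 33),

    # symptomatic cohort, pooled (12-15 weeks)
    row("symptomatic", "rmp",             "WT-adult", -64.8, 2.50, 30),
    row("symptomatic", "mean_epp",        "WT-adult", 21.0, 2.45, 30),
    row("symptomatic", "mean_epp_nor",    "WT-adult", 23.6, 2.21, 30),
    row("symptomatic", "quantal_content", "WT-adult", 41.3, 3.79, 30),
    row("symptomatic", "mean_mepp",       "WT-adult", 0.50, 0.03, 30),
    row("symptomatic", "mepp_rise",       "WT-adult", 0.98, 0.07, 30),
    row("symptomatic", "mepp_decay",      "WT-adult", 3.12, 0.14, 30),
    row("symptomatic", "mepp_freq",       "WT-adult", 0.76, 0.11, 30),
    row("symptomatic", "n_with_gmepps",   "WT-adult", 16, NA, 30),
    row("symptomatic", "gmepp_freq",      "WT-adult", 0.44, 0.12, 16),
    row("symptomatic", "gmepp_mepp_ratio","WT-adult", 1.58, 0.49, 16),

    row("symptomatic", "rmp",             "SOD1-sym", -65.8, 1.69, 39),
    row("symptomatic", "mean_epp",        "SOD1-sym", 18.3, 1.88, 39),
    row("symptomatic", "mean_epp_nor",    "SOD1-sym", 18.3, 1.88, 39),
    row("symptomatic", "quantal_content", "SOD1-sym", 35.8, 2.74, 39),
    row("symptomatic", "mean_mepp",       "SOD1-sym", 0.49, 0.03, 39),
    row("symptomatic", "mepp_rise",       "SOD1-sym", 1.15, 0.07, 39),
    row("symptomatic", "mepp_decay",      "SOD1-sym", 3.21, 0.13, 39),
    row("symptomatic", "mepp_freq",       "SOD1-sym", 0.80, 0.11, 39),
    row("symptomatic", "n_with_gmepps",   "SOD1-sym", 20, NA, 39),
    row("symptomatic", "gmepp_freq",      "SOD1-sym", 0.32, 0.10, 20),
    row("symptomatic", "gmepp_mepp_ratio","SOD1-sym", 1.21, 0.68, 20),

    # symptomatic SOD1 junctions split at the 0.49 mV cohort-mean cutoff
    row("symptomatic_split", "rmp",             "SOD1a", -64.4, 2.05, 19),
    row("symptomatic_split", "mean_epp",        "SOD1a", 11.4, 2.00, 19),
    row("symptomatic_split", "mean_epp_nor",    "SOD1a", 12.8, 2.06, 19),
    row("symptomatic_split", "quantal_content", "SOD1a", 32.7, 4.40, 19),
    row("symptomatic_split", "mean_mepp",       "SOD1a", 0.32, 0.02, 19),
    row("symptomatic_split", "mepp_rise",       "SOD1a", 1.39, 0.12, 19),
    row("symptomatic_split", "mepp_decay",      "SOD1a", 3.12, 0.17, 19),
    row("symptomatic_split", "mepp_freq",       "SOD1a", 0.61, 0.11, 19),
    row("symptomatic_split", "n_with_gmepps",   "SOD1a", 3, NA, 19),
    row("symptomatic_split", "gmepp_freq",      "SOD1a", 0.07, 0.03, 3),
    row("symptomatic_split", "gmepp_mepp_ratio","SOD1a", 0.11, 0.07, 3),

    row("symptomatic_split", "rmp",             "SOD1b", -67.1, 2.67, 20),
    row("symptomatic_split", "mean_epp",        "SOD1b", 24.9, 2.33, 20),
    row("symptomatic_split", "mean_epp_nor",    "SOD1b", 28.1, 2.41, 20),
    row("symptomatic_split", "quantal_content", "SOD1b", 38.8, 3.30, 20),
    row("symptomatic_split", "mean_mepp",       "SOD1b", 0.64, 0.02, 20),
    row("symptomatic_split", "mepp_rise",       "SOD1b", 0.93, 0.06, 20),
    row("symptomatic_split", "mepp_decay",      "SOD1b", 3.28, 0.20, 20),
    row("symptomatic_split", "mepp_freq",       "SOD1b", 1.26, 0.33, 20),
    row("symptomatic_split", "n_with_gmepps",   "SOD1b", 17, NA, 20),
    row("symptomatic_split", "gmepp_freq",      "SOD1b", 0.38, 0.12, 17),
    row("symptomatic_split", "gmepp_mepp_ratio","SOD1b", 1.40, 0.80, 17)
  )
}
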