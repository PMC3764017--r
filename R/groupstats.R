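#' Mean and standard error of the mean
#'
#' @param values numeric vector (non-empty).
#' @return list with `mean`, `sem` (sample SD over sqrt(n); `NA` and
#'   flagged undefined for a single value) and `n`.
#' @export
mean_sem <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (!n) stop("no finite values supplied", call. = FALSE)
  list(mean = mean(values),
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Select the two-group comparison test
#'
#' The parametric Student's t test is used when both groups pass the
#' Shapiro-Wilk normality test and the two-sided F test finds no variance
#' inequality; Welch's t test when only the equality-of-variances condition
#' fails; and the Mann-Whitney U test when either group is non-normal.
#' Groups too small for normality testing fall back to Mann-Whitney with a
#' logged note.
#'
#' @param a,b numeric samples.
#' @param alpha gatekeeper significance level for both the normality and
#'   variance tests.
#' @return a list of class `test_choice`: `test_name` (`"student_t"`,
#'   `"welch_t"` or `"mann_whitney"`), `shapiro_p` (length 2), `f_p`, and
#'   `note`.
#' @export
choose_test <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L)
    return(structure(list(test_name = "mann_whitney",
                          shapiro_p = c(NA_real_, NA_real_), f_p = NA_real_,
                          note = "group too small for normality testing"),
                     class = "test_choice"))
  sw <- function(x) tryCatch(stats::shapiro.test(x)$p.value,
                             error = function(e) 0)  # constant -> non-normal
  p_a <- sw(a); p_b <- sw(b)
  if (min(p_a, p_b) < alpha)
    return(structure(list(test_name = "mann_whitney",
                          shapiro_p = c(p_a, p_b), f_p = NA_real_,
                          note = NULL),
                     class = "test_choice"))
  f_p <- tryCatch(stats::var.test(a, b)$p.value, error = function(e) NA_real_)
  test <- if (is.finite(f_p) && f_p < alpha) "welch_t" else "student_t"
  structure(list(test_name = test, shapiro_p = c(p_a, p_b), f_p = f_p,
                 note = NULL),
            class = "test_choice")
}

#' Compare two groups with the selected test
#'
#' Applies [choose_test()] and runs the chosen two-sided test at the 5\%
#' level. No multiple-testing correction is applied across measures; every
#' report states this.
#'
#' @inheritParams choose_test
#' @return a one-row data.frame of class `nmj_test_result`: `test_name`,
#'   `statistic`, `p_value`, `significant`, the gatekeeper p-values
#'   (`shapiro_p_a`, `shapiro_p_b`, `f_p`), group sizes and a `degenerate`
#'   flag for constant inputs.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 finite values per group", call. = FALSE)
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  choice <- choose_test(a, b, alpha)
  res <- switch(choice$test_name,
    student_t = stats::t.test(a, b, var.equal = TRUE),
    welch_t = stats::t.test(a, b, var.equal = FALSE),
    mann_whitney = suppressWarnings(stats::wilcox.test(a, b)))
  out <- data.frame(test_name = choice$test_name,
                    statistic = unname(res$statistic),
                    p_value = res$p.value,
                    significant = is.finite(res$p.value) &&
                      res$p.value < 0.05,
                    shapiro_p_a = choice$shapiro_p[1],
                    shapiro_p_b = choice$shapiro_p[2],
                    f_p = choice$f_p, n_a = length(a), n_b = length(b),
                    degenerate = degenerate, stringsAsFactors = FALSE)
  class(out) <- c("nmj_test_result", "data.frame")
  out
}

#' Signed percent change between two group means
#'
#' `100 * (test_mean - reference_mean) / reference_mean`, returned both
#' unrounded and rounded half-up to an integer percent (the convention used
#' when percent changes are quoted in text).
#'
#' @param reference_mean reference (baseline) group mean, nonzero.
#' @param test_mean test group mean.
#' @return list with `percent` (unrounded) and `rounded` (half-up integer).
#' @examples
#' percent_change(29.0, 38.1)$rounded  # +31
#' percent_change(263, 181)$rounded    # -31
#' @export
percent_change <- function(reference_mean, test_mean) {
  if (!is.finite(reference_mean) || reference_mean == 0)
    stop("'reference_mean' must be nonzero", call. = FALSE)
  pc <- 100 * (test_mean - reference_mean) / reference_mean
  list(percent = pc, rounded = round_half_up(pc))
}

#' Round half away from zero to integer
#'
#' @param x numeric vector.
#' @return integer-valued numeric; halves round away from zero
#'   (14.5 to 15, -14.5 to -15).
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Build a group summary table with pairwise comparisons
#'
#' One row per measure and group with mean +/- SEM and n, plus pairwise
#' test results (test chosen per [choose_test()], two-sided, 5\% level,
#' uncorrected across rows). The GMEPP frequency and GMEPP/MEPP ratio rows
#' are restricted to fibers exhibiting giant events. Significance markers
#' follow the convention `#` Mann-Whitney, `*` Student t, `+` Welch t.
#'
#' @param groups named list of fiber tables (from [analyze_ensemble()] or
#'   [summarize_fiber()] rows), two or more groups.
#' @param measures character vector of fiber-table columns to summarize;
#'   default: the standard set of per-fiber transmission measures.
#' @return an object of class `nmj_summary`: list with `summary`
#'   (measure x group means) and `comparisons` (pairwise test results with
#'   markers).
#' @export
build_summary_table <- function(groups, measures = NULL) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)))
    stop("'groups' must be a named list of at least two fiber tables",
         call. = FALSE)
  if (is.null(measures))
    measures <- c("rmp", "mean_epp", "mean_epp_nor", "quantal_content",
                  "mean_mepp", "mepp_rise", "mepp_decay", "mepp_freq",
                  "gmepp_freq", "gmepp_mepp_ratio")
  restricted <- c("gmepp_freq", "gmepp_mepp_ratio")
  get_vals <- function(tab, m) {
    if (!m %in% names(tab)) return(numeric(0))
    v <- tab[[m]]
    if (m %in% restricted && "has_gmepps" %in% names(tab))
      v <- v[tab$has_gmepps %in% TRUE]
    v[is.finite(v)]
  }
  marker <- c(mann_whitney = "#", student_t = "*", welch_t = "+")

  sum_rows <- list(); cmp_rows <- list()
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  for (m in measures) {
    for (g in names(groups)) {
      v <- get_vals(groups[[g]], m)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        measure = m, group = g,
        mean = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
    for (pr in pairs) {
      v1 <- get_vals(groups[[pr[1]]], m)
      v2 <- get_vals(groups[[pr[2]]], m)
      if (length(v1) < 2L || length(v2) < 2L) {
        cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
          measure = m, group1 = pr[1], group2 = pr[2],
          test_name = NA_character_, statistic = NA_real_,
          p_value = NA_real_, significant = NA, marker = "",
          stringsAsFactors = FALSE)
        next
      }
      tr <- compare_groups(v1, v2)
      cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
        measure = m, group1 = pr[1], group2 = pr[2],
        test_name = tr$test_name, statistic = tr$statistic,
        p_value = tr$p_value, significant = tr$significant,
        marker = if (isTRUE(tr$significant)) marker[[tr$test_name]] else "",
        stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, sum_rows),
                 comparisons = do.call(rbind, cmp_rows),
                 note = paste("two-sided tests at the 5% level,",
                              "uncorrected across rows;",
                              "markers: # Mann-Whitney, * Student t,",
                              "+ Welch t")),
            class = "nmj_summary")
}

#' @export
print.nmj_summary <- function(x, digits = 3, ...) {
  cat("Group summary (mean +/- SEM):\n")
  s <- x$summary
  s$value <- sprintf("%.*g +/- %.*g (n=%d)", digits, s$mean, digits, s$sem,
                     s$n)
  wide <- stats::reshape(s[, c("measure", "group", "value")],
                         idvar = "measure", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE)
  cat("\nPairwise comparisons:\n")
  cmp <- x$comparisons
  cmp$p_value <- signif(cmp$p_value, 3)
  cmp$statistic <- signif(cmp$statistic, 4)
  print(cmp, row.names = FALSE)
  cat("\n", x$note, "\n", sep = "")
  invisible(x)
}
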