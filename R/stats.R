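# Cohort statistics: group comparisons and the speed-knee-load regression.

#' Independent two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) test by default, Welch optionally; computable
#' directly from printed group summaries (mean, sd, n).
#'
#' @param mean1,sd1,n1 group 1 summary
#' @param mean2,sd2,n2 group 2 summary
#' @param var_equal pooled variance (TRUE, default) or Welch
#' @return list with `t`, `df`, `p` (two-sided)
#' @examples
#' # group stature summaries: 155.4 +/- 4.9 vs 150.6 +/- 6.0 cm, n = 8 + 8
#' t_test_summary(155.4, 4.9, 8, 150.6, 6.0, 8)$p  # ~0.10
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  d <- mean1 - mean2
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    # degenerate: zero variance in both groups
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = df,
                p = if (d == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- d / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), degenerate = FALSE)
}

#' Independent two-sample t-test on raw values
#'
#' @param x,y numeric vectors (n >= 2 each)
#' @param var_equal pooled variance (default) or Welch
#' @return list with `t`, `df`, `p`
#' @export
independent_t_test <- function(x, y, var_equal = TRUE) {
  t_test_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y), var_equal = var_equal)
}

#' Walking speed versus peak knee load regression
#'
#' Ordinary least squares of peak compressive tibiofemoral force (xBW) on
#' self-selected walking speed (m/s) across subjects.
#'
#' @param speed walking speeds (m/s)
#' @param peak_ctf_bw peak normalized compressive forces (xBW)
#' @return list with `slope`, `intercept`, `r_squared`, `n`, and
#'   `underdetermined` (TRUE when only two points)
#' @export
speed_load_regression <- function(speed, peak_ctf_bw) {
  if (length(speed) != length(peak_ctf_bw))
    stop("speed and peak_ctf_bw lengths differ")
  if (length(speed) < 2L) stop("need at least 2 points")
  if (stats::sd(speed) == 0) stop("degenerate regression: speeds all equal")
  fit <- stats::lm(peak_ctf_bw ~ speed)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((peak_ctf_bw - mean(peak_ctf_bw))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, n = length(speed),
       underdetermined = length(speed) == 2L)
}

#' Summarize a cohort's pipeline outputs
#'
#' Per-subject peaks are extracted first (averaging a subject's trials),
#' then group means and standard deviations are formed; forces are
#' normalized by each subject's own body weight.
#'
#' @param subject_results list of per-subject results as returned by
#'   [run_subject()]: each has `anthro`, `peak_ctf_bw`, `peak_forces_bw`
#'   (named: quadriceps, hamstrings, gastrocnemius), `peak_pct_gc`
#' @return a `cohort_summary`: data.frame `per_subject` plus `means`, `sds`
#' @export
summarize_cohort <- function(subject_results) {
  if (!length(subject_results)) stop("no subject results supplied")
  missing_out <- vapply(subject_results, function(s)
    is.null(s$peak_ctf_bw) || anyNA(s$peak_ctf_bw), TRUE)
  if (any(missing_out))
    stop("missing pipeline output for subject(s): ",
         paste(vapply(subject_results[missing_out],
                      function(s) s$anthro$subject_id, ""), collapse = ", "))
  per <- do.call(rbind, lapply(subject_results, function(s) {
    data.frame(subject_id = s$anthro$subject_id, group = s$anthro$group,
               mass = s$anthro$mass, height = s$anthro$height,
               bmi = bmi(s$anthro), speed = s$anthro$walking_speed,
               peak_ctf_bw = s$peak_ctf_bw,
               peak_ctf_pct_gc = s$peak_pct_gc,
               quadriceps_bw = s$peak_forces_bw[["quadriceps"]],
               hamstrings_bw = s$peak_forces_bw[["hamstrings"]],
               gastrocnemius_bw = s$peak_forces_bw[["gastrocnemius"]],
               stringsAsFactors = FALSE)
  }))
  num <- per[, !(names(per) %in% c("subject_id", "group"))]
  structure(list(per_subject = per,
                 means = colMeans(num),
                 sds = vapply(num, function(col)
                   if (nrow(per) > 1L) stats::sd(col) else 0, 0),
                 n = nrow(per), group = per$group[1L]),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s group, n = %d\n", x$group, x$n))
  cat(sprintf("  peak CTF    %.2f +/- %.2f xBW (at %.0f%% GC)\n",
              x$means["peak_ctf_bw"], x$sds["peak_ctf_bw"],
              x$means["peak_ctf_pct_gc"]))
  cat(sprintf("  quadriceps  %.2f +/- %.2f xBW\n",
              x$means["quadriceps_bw"], x$sds["quadriceps_bw"]))
  cat(sprintf("  hamstrings  %.2f +/- %.2f xBW\n",
              x$means["hamstrings_bw"], x$sds["hamstrings_bw"]))
  cat(sprintf("  gastrocnem. %.2f +/- %.2f xBW\n",
              x$means["gastrocnemius_bw"], x$sds["gastrocnemius_bw"]))
  invisible(x)
}

#' Compare two cohort summaries row by row
#'
#' Builds the normalized joint-loading comparison table (peak CTF and the
#' three knee-crossing muscle-group forces, xBW) with group means, sds and
#' pooled t-test p-values, plus significance markers at p < 0.05 / p < 0.01.
#'
#' @param summary_ob obese-group `cohort_summary`
#' @param summary_nw normal-weight `cohort_summary`
#' @param var_equal pooled (default) or Welch t-test
#' @return data.frame with one row per measure
#' @export
compare_cohorts <- function(summary_ob, summary_nw, var_equal = TRUE) {
  rows <- c(CTF = "peak_ctf_bw", Hamstring = "hamstrings_bw",
            Quadriceps = "quadriceps_bw", Gastrocnemius = "gastrocnemius_bw")
  out <- do.call(rbind, lapply(names(rows), function(lab) {
    col <- rows[[lab]]
    a <- summary_ob$per_subject[[col]]
    b <- summary_nw$per_subject[[col]]
    tt <- independent_t_test(a, b, var_equal = var_equal)
    data.frame(measure = lab,
               obese_mean = mean(a), obese_sd = stats::sd(a),
               normal_mean = mean(b), normal_sd = stats::sd(b),
               t = tt$t, p = tt$p,
               signif = if (tt$p < 0.01) "**" else if (tt$p < 0.05) "*"
               else "", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
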