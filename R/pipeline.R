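# End-to-end pipeline: trial -> IK -> ID -> static optimization -> joint
# reaction -> peaks; subject and cohort drivers; result-table analogues.

#' Run the analysis pipeline on one trial
#'
#' Inverse kinematics on the trial's markers, smoothing/differentiation,
#' inverse dynamics with the measured GRF, static optimization, knee joint
#' reaction analysis, and stance-peak extraction for the right limb.
#'
#' @param trial a `gait_trial`
#' @param model the subject's scaled `gait_model`
#' @param cutoff_hz filter cutoff for [differentiate_states()]; `NULL`
#'   (default) selects 6 Hz for noisy markers and no filtering for
#'   noise-free trials (filtering noise-free data only distorts it)
#' @param reserve_weight static-optimization reserve penalty
#' @param event_threshold GRF event threshold (N)
#' @return list with `states`, `loads`, `solution`, `knee`, `events`,
#'   `peak_ctf_bw`, `peak_pct_gc`, `peak_forces_bw`, `residuals`
#' @export
run_trial_pipeline <- function(trial, model, cutoff_hz = NULL,
                               reserve_weight = 1000,
                               event_threshold = 20) {
  if (is.null(cutoff_hz))
    cutoff_hz <- if (isTRUE(trial$meta$noise_sd == 0)) Inf else 6
  states <- inverse_kinematics(trial, model)
  states <- differentiate_states(states, cutoff_hz)
  events <- detect_events(trial, event_threshold)
  states$events <- events
  loads <- net_joint_loads(states, trial, model)
  solution <- decompose_trial(loads, states, model, reserve_weight)
  knee <- knee_reaction(states, solution, model, trial, side = "r")
  knee$events <- events
  pk <- peak_ctf(knee)
  grouped <- group_forces(solution, side = "r",
                          groups = c("quadriceps", "hamstrings",
                                     "gastrocnemius"))
  bw <- trial$subject$mass * 9.81
  stance_peak <- function(col) {
    norm <- time_normalize(states$time, cbind(col), events, side = "r")
    to <- if (is.na(norm$toe_off_pct)) 60 else norm$toe_off_pct
    max(norm$x[norm$pct <= to, 1L])
  }
  peak_forces_bw <- vapply(colnames(grouped), function(gname)
    stance_peak(grouped[, gname]) / bw, 0)
  list(states = states, loads = loads, solution = solution, knee = knee,
       events = events, peak_ctf_bw = pk$peak_bw, peak_pct_gc = pk$pct_gc,
       peak_forces_bw = peak_forces_bw,
       residuals = residual_report(loads))
}

#' Run the pipeline for one subject (several trials)
#'
#' Generates `trials_per_subject` synthetic trials and averages the
#' per-trial peaks (peak-then-average convention).
#'
#' @param anthro a [subject_anthropometry()]
#' @param waveforms a [gait_waveforms()] set (already adapted for group)
#' @param trials_per_subject number of trials
#' @param seed integer; per-trial seeds derive from it
#' @param noise_sd marker noise (m)
#' @param cutoff_hz,reserve_weight,event_threshold pipeline tunables
#' @param keep_trials retain the full per-trial objects
#' @return list with `anthro`, `peak_ctf_bw`, `peak_forces_bw`,
#'   `peak_pct_gc`, `residual_pass`, and optionally `trials`
#' @export
run_subject <- function(anthro, waveforms, trials_per_subject = 3,
                        seed = 1, noise_sd = 0.002, cutoff_hz = NULL,
                        reserve_weight = 1000, event_threshold = 20,
                        keep_trials = FALSE) {
  model <- cache_model(scale_model(anthro))
  res <- vector("list", trials_per_subject)
  for (k in seq_len(trials_per_subject)) {
    trial <- generate_trial(anthro, model, waveforms, seed = seed + k,
                            noise_sd = noise_sd)
    res[[k]] <- run_trial_pipeline(trial, model, cutoff_hz, reserve_weight,
                                   event_threshold)
  }
  pf <- rowMeans(vapply(res, `[[`, numeric(3L), "peak_forces_bw"))
  out <- list(
    anthro = anthro,
    peak_ctf_bw = mean(vapply(res, `[[`, 0, "peak_ctf_bw")),
    peak_pct_gc = mean(vapply(res, `[[`, 0, "peak_pct_gc")),
    peak_forces_bw = pf,
    residual_pass = all(vapply(res, function(r) r$residuals$pass, TRUE)))
  if (keep_trials) out$trials <- res
  out
}

#' Run the full cohort pipeline
#'
#' Samples a cohort, applies the obesity adaptation for the obese group,
#' runs every subject through the pipeline and summarizes.
#'
#' @param spec a [cohort_spec()]
#' @param waveforms base waveform set (normative)
#' @param obesity_severity adaptation severity applied when
#'   `spec$group == "obese"`
#' @param noise_sd,cutoff_hz,reserve_weight,event_threshold tunables
#' @param keep_subjects retain full per-subject results
#' @return a `cohort_summary` (see [summarize_cohort()]); per-subject
#'   results in `attr(, "subjects")` when requested
#' @export
run_cohort_pipeline <- function(spec, waveforms = gait_waveforms(),
                                obesity_severity = 1, noise_sd = 0.002,
                                cutoff_hz = NULL, reserve_weight = 1000,
                                event_threshold = 20,
                                keep_subjects = FALSE) {
  wf <- if (spec$group == "obese")
    apply_obesity_adaptation(waveforms, obesity_severity) else waveforms
  cohort <- sample_cohort(spec)
  subjects <- lapply(seq_along(cohort), function(i)
    run_subject(cohort[[i]], wf,
                trials_per_subject = spec$trials_per_subject,
                seed = spec$seed * 1000L + i * 10L,
                noise_sd = noise_sd, cutoff_hz = cutoff_hz,
                reserve_weight = reserve_weight,
                event_threshold = event_threshold))
  summ <- summarize_cohort(subjects)
  if (keep_subjects) attr(summ, "subjects") <- subjects
  summ
}

#' Run both cohorts and produce the result-table analogues
#'
#' Executes the full two-group study: normal-weight and obese synthetic
#' cohorts through the complete pipeline, the normalized loading comparison
#' table, the demographics table, and the speed-load regression.
#'
#' @param config configuration list (see [default_config()])
#' @param out_dir optional directory for CSV outputs
#' @return list with `normal`, `obese` (cohort summaries),
#'   `table1_analogue`, `table2_analogue`, `regression`
#' @export
run_study <- function(config = default_config(), out_dir = NULL) {
  wf <- gait_waveforms()
  nw <- run_cohort_pipeline(config$cohorts$normal, wf,
                            obesity_severity = config$obesity_severity,
                            noise_sd = config$marker_noise_sd,
                            cutoff_hz = config$filter_cutoff_hz,
                            reserve_weight = config$reserve_weight,
                            event_threshold = config$event_threshold_n)
  ob <- run_cohort_pipeline(config$cohorts$obese, wf,
                            obesity_severity = config$obesity_severity,
                            noise_sd = config$marker_noise_sd,
                            cutoff_hz = config$filter_cutoff_hz,
                            reserve_weight = config$reserve_weight,
                            event_threshold = config$event_threshold_n)
  t1 <- demographics_table(ob, nw, var_equal = config$t_test$var_equal)
  t2 <- compare_cohorts(ob, nw, var_equal = config$t_test$var_equal)
  speeds <- c(nw$per_subject$speed, ob$per_subject$speed)
  peaks <- c(nw$per_subject$peak_ctf_bw, ob$per_subject$peak_ctf_bw)
  reg <- speed_load_regression(speeds, peaks)
  out <- list(normal = nw, obese = ob, table1_analogue = t1,
              table2_analogue = t2, regression = reg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(t1, file.path(out_dir, "table1_analogue.csv"),
                     row.names = FALSE)
    utils::write.csv(t2, file.path(out_dir, "table2_analogue.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(nw$per_subject, ob$per_subject),
                     file.path(out_dir, "per_subject.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(slope = reg$slope,
                                intercept = reg$intercept,
                                r_squared = reg$r_squared, n = reg$n),
                     file.path(out_dir, "speed_regression.csv"),
                     row.names = FALSE)
  }
  out
}

#' Demographics comparison table
#'
#' @param summary_ob,summary_nw cohort summaries
#' @param var_equal pooled (default) or Welch t-test
#' @return data.frame: measure, group means/sds, p
#' @export
demographics_table <- function(summary_ob, summary_nw, var_equal = TRUE) {
  rows <- c(`Weight (kg)` = "mass", `Height (m)` = "height",
            `Body mass index (kg/m2)` = "bmi",
            `Self-selected speed (m/s)` = "speed")
  out <- do.call(rbind, lapply(names(rows), function(lab) {
    col <- rows[[lab]]
    a <- summary_ob$per_subject[[col]]
    b <- summary_nw$per_subject[[col]]
    tt <- independent_t_test(a, b, var_equal = var_equal)
    data.frame(measure = lab, obese_mean = mean(a),
               obese_sd = stats::sd(a), normal_mean = mean(b),
               normal_sd = stats::sd(b), p = tt$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
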