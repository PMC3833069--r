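# Shared fixtures: one reference subject/model/trial and a cached full
# pipeline run, so expensive pieces are computed once per test session.

.world <- new.env(parent = emptyenv())

nw_subject <- function() {
  subject_anthropometry("NW-REF", mass = 43.1, height = 1.506, age = 10,
                        group = "normal", walking_speed = 1.22)
}

nw_model <- function() {
  if (is.null(.world$model)) .world$model <- cache_model(scale_model(nw_subject()))
  .world$model
}

# Noise-free reference trial + exact generator states
ref_trial <- function() {
  if (is.null(.world$trial))
    .world$trial <- generate_trial(nw_subject(), nw_model(), gait_waveforms(),
                                   seed = 7, noise_sd = 0)
  .world$trial
}

truth_states <- function(trial, subject = trial$subject) {
  truth <- attr(trial, "truth")
  structure(list(time = trial$time, q = truth$q, qd = truth$qd,
                 qdd = truth$qdd, events = trial$events, subject = subject,
                 meta = trial$meta),
            class = "state_trajectory")
}

# Full pipeline on the reference trial (with the default 2 mm marker noise)
ref_pipeline <- function() {
  if (is.null(.world$pipe)) {
    trial <- generate_trial(nw_subject(), nw_model(), gait_waveforms(),
                            seed = 11, noise_sd = 0.002)
    .world$pipe <- c(list(trial = trial),
                     run_trial_pipeline(trial, nw_model()))
  }
  .world$pipe
}

# Exact pipeline pieces on the noise-free trial (generator states, no filter)
ref_exact <- function() {
  if (is.null(.world$exact)) {
    trial <- ref_trial()
    states <- truth_states(trial)
    loads <- net_joint_loads(states, trial, nw_model())
    solution <- decompose_trial(loads, states, nw_model())
    .world$exact <- list(trial = trial, states = states, loads = loads,
                         solution = solution)
  }
  .world$exact
}

# Full two-cohort study at the study's size (n = 8 x 3 trials); computed
# once, shared between the acceptance tests.
study_results <- function() {
  if (is.null(.world$study)) {
    wf <- gait_waveforms()
    .world$study <- list(
      normal = run_cohort_pipeline(cohort_spec("normal", seed = 42), wf,
                                   keep_subjects = TRUE),
      obese = run_cohort_pipeline(cohort_spec("obese", seed = 42), wf,
                                  keep_subjects = TRUE))
  }
  .world$study
}

# First local maximum of a stance waveform (101-point normalized curve)
first_stance_peak <- function(pct, x, toe_off_pct = 60) {
  stance <- which(pct <= toe_off_pct)
  xs <- x[stance]
  for (i in 2:(length(xs) - 1L))
    if (xs[i] >= xs[i - 1L] && xs[i] > xs[i + 1L])
      return(list(value = xs[i], pct = pct[stance][i]))
  i <- which.max(xs)
  list(value = xs[i], pct = pct[stance][i])
}
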