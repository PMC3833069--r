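# Inverse dynamics: net joint moments, intersegmental forces, residuals.

#' Net joint loads from states and measured ground reaction forces
#'
#' Generalized-coordinate inverse dynamics: the applied generalized force
#' needed to reproduce the measured motion is
#' `tau = M(q) qdd + b(q, qd) - Q_gravity - Q_grf`.  Entries at the joint
#' coordinates are the net internal joint moments (flexion positive at hip
#' and knee, dorsiflexion positive at the ankle; see `conventions` in the
#' result for the knee-extension-positive view); entries at the pelvis
#' coordinates are the residual force (N) and moment (N m) closing the
#' chain, which vanish on dynamically consistent data.  Intersegmental
#' forces are subtree force balances in the ground frame.
#'
#' @param states a differentiated `state_trajectory` (q, qd, qdd)
#' @param trial the `gait_trial` providing GRF and COP
#' @param model the subject's scaled `gait_model`
#' @return a `net_joint_loads` object: `moments` (frames x 6),
#'   `residual_force` (frames x 2), `residual_moment` (frames),
#'   `interseg_force` (list per joint of frames x 2 matrices)
#' @export
net_joint_loads <- function(states, trial, model) {
  if (length(states$time) != length(trial$time) ||
      max(abs(states$time - trial$time)) > 1e-9)
    stop("state and trial time grids differ")
  n <- length(states$time)
  tau <- matrix(0, n, 9L, dimnames = list(NULL, GAIT_COORDS))
  subtree <- list(
    hip_r = c("thigh_r", "shank_r", "foot_r"),
    knee_r = c("shank_r", "foot_r"),
    ankle_r = "foot_r",
    hip_l = c("thigh_l", "shank_l", "foot_l"),
    knee_l = c("shank_l", "foot_l"),
    ankle_l = "foot_l")
  interseg <- lapply(subtree, function(s) matrix(0, n, 2L))
  cs <- com_specs(model)
  g <- model$gravity
  for (i in seq_len(n)) {
    qi <- states$q[i, ]; qdi <- states$qd[i, ]; qddi <- states$qdd[i, ]
    Qg <- gravity_gen(model, qi)
    Qgrf <- numeric(9L)
    for (side in c("r", "l")) {
      F <- trial$grf[[side]][i, ]
      if (sum(abs(F)) > 0) {
        cop <- c(trial$cop[[side]][i], 0)
        Qgrf <- Qgrf + ext_force_gen(model, paste0("foot_", side), cop, F, qi)
      }
    }
    tau[i, ] <- mass_matrix(model, qi) %*% qddi + bias_gen(model, qi, qdi) -
      Qg - Qgrf
    for (jn in names(subtree)) {
      fsum <- c(0, 0)
      for (seg in subtree[[jn]]) {
        ci <- cs[[seg]]
        fsum <- fsum + ci$mass * (pt_acc(ci$spec, qi, qdi, qddi) - g)
      }
      side <- sub("^.*_", "", jn)
      fsum <- fsum - trial$grf[[side]][i, ]
      interseg[[jn]][i, ] <- fsum
    }
  }
  structure(list(
    time = states$time,
    moments = tau[, 4L:9L, drop = FALSE],
    residual_force = tau[, 1L:2L, drop = FALSE],
    residual_moment = tau[, 3L],
    interseg_force = interseg,
    conventions = paste("internal (muscle) moments; flexion positive at",
                        "hip/knee, dorsiflexion positive at ankle;",
                        "knee extension moment = -moments[, 'knee_*']"),
    subject = trial$subject),
    class = "net_joint_loads")
}

#' Residual diagnostics report
#'
#' Summarizes the pelvis residual force and moment left by inverse
#' dynamics, the dynamic-consistency diagnostic standing in for a residual
#' reduction step: synthetic trials are consistent by construction, so
#' residuals beyond threshold indicate corrupted inputs.
#'
#' @param loads a `net_joint_loads`
#' @param force_tol RMS residual force threshold, fraction of body weight
#' @param moment_tol RMS residual moment threshold, fraction of BW m
#' @return list with max/RMS residuals (absolute and BW-normalized) and
#'   `pass`
#' @export
residual_report <- function(loads, force_tol = 0.02, moment_tol = 0.02) {
  if (is.null(loads$residual_force) || nrow(loads$residual_force) == 0L)
    stop("empty loads: no residuals to report")
  bw <- loads$subject$mass * 9.81
  fmag <- sqrt(rowSums(loads$residual_force^2))
  mmag <- abs(loads$residual_moment)
  out <- list(
    rms_force = sqrt(mean(fmag^2)), max_force = max(fmag),
    rms_moment = sqrt(mean(mmag^2)), max_moment = max(mmag),
    rms_force_bw = sqrt(mean(fmag^2)) / bw,
    rms_moment_bwm = sqrt(mean(mmag^2)) / bw,
    force_tol = force_tol, moment_tol = moment_tol)
  out$pass <- out$rms_force_bw < force_tol && out$rms_moment_bwm < moment_tol
  out
}
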