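# Inverse kinematics, gait events and time normalization.

#' Inverse kinematics on a marker trial
#'
#' Per-frame weighted least squares of model marker positions against the
#' measured markers, solved by Gauss-Newton with analytic Jacobians and
#' warm-started from the previous frame.  Frames that fail to converge
#' within `max_iter` iterations are flagged and linearly interpolated from
#' their neighbours; the trial is rejected if more than 5% of frames flag.
#'
#' @param trial a `gait_trial`
#' @param model the subject's scaled `gait_model`
#' @param weights optional per-marker weights (default 1)
#' @param max_iter Gauss-Newton iteration cap per frame
#' @param tol step-norm convergence tolerance
#' @return a `state_trajectory` with `time`, `q` (frames x 9), per-frame
#'   `rms_error` (m), `flagged` frame indices, and the trial's events
#' @export
inverse_kinematics <- function(trial, model, weights = NULL,
                               max_iter = 50L, tol = 1e-10) {
  mtab <- model_markers(model)
  meas_names <- dimnames(trial$markers)[[2L]]
  idx <- match(mtab$name, meas_names)
  if (anyNA(idx)) stop("trial lacks model markers: ",
                       paste(mtab$name[is.na(idx)], collapse = ", "))
  nmark <- nrow(mtab)
  if (2L * nmark < 9L) stop("need at least as many marker coordinates as DOF")
  w <- if (is.null(weights)) rep(1, nmark) else rep_len(weights, nmark)
  specs <- lapply(seq_len(nmark), function(k)
    point_spec(model, mtab$segment[k], c(mtab$lx[k], mtab$ly[k])))
  n <- length(trial$time)
  q <- matrix(0, n, 9L, dimnames = list(NULL, GAIT_COORDS))
  rms <- numeric(n)
  flagged <- logical(n)
  sw <- sqrt(rep(w, each = 2L))

  q0 <- init_pose(trial, model, idx, mtab)
  for (i in seq_len(n)) {
    target <- as.numeric(t(trial$markers[i, idx, ]))  # x1,y1,x2,y2,...
    qi <- if (i == 1L) q0 else q[i - 1L, ]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      r <- numeric(2L * nmark)
      J <- matrix(0, 2L * nmark, 9L)
      for (k in seq_len(nmark)) {
        rows <- (2L * k - 1L):(2L * k)
        r[rows] <- pt_pos(specs[[k]], qi) - target[rows]
        J[rows, ] <- pt_jac(specs[[k]], qi)
      }
      step <- tryCatch(
        qr.solve(sw * J, sw * r),
        error = function(e) rep(NA_real_, 9L))
      if (anyNA(step)) break
      qi <- qi - step
      if (sqrt(sum(step^2)) < tol) { ok <- TRUE; break }
    }
    if (!ok && !anyNA(step)) ok <- sqrt(sum(step^2)) < 1e-6  # near-converged
    flagged[i] <- !ok
    q[i, ] <- qi
    resid <- vapply(seq_len(nmark), function(k)
      sum((pt_pos(specs[[k]], qi) - target[(2L * k - 1L):(2L * k)])^2),
      0)
    rms[i] <- sqrt(mean(resid))
  }
  if (mean(flagged) > 0.05)
    stop(sprintf("inverse kinematics failed on %.1f%% of frames (> 5%%)",
                 100 * mean(flagged)))
  if (any(flagged)) {
    goodi <- which(!flagged)
    for (j in seq_len(9L))
      q[flagged, j] <- stats::approx(trial$time[goodi], q[goodi, j],
                                     xout = trial$time[flagged],
                                     rule = 2L)$y
  }
  structure(list(time = trial$time, q = q, qd = NULL, qdd = NULL,
                 rms_error = rms, flagged = which(flagged),
                 events = trial$events, subject = trial$subject,
                 meta = trial$meta),
            class = "state_trajectory")
}

# Crude initial pose from the pelvis markers: translation from their
# centroid, standing angles elsewhere.
init_pose <- function(trial, model, idx, mtab) {
  hat_rows <- which(mtab$segment == "hat")
  cen <- colMeans(trial$markers[1L, idx[hat_rows], , drop = FALSE][1L, , ])
  off <- c(mean(mtab$lx[hat_rows]), mean(mtab$ly[hat_rows]))
  q0 <- numeric(9L); names(q0) <- GAIT_COORDS
  q0["pelvis_tx"] <- cen[1L] - off[1L]
  q0["pelvis_ty"] <- cen[2L] - off[2L]
  q0
}

#' Add velocities and accelerations to a state trajectory
#'
#' Runs [smooth_differentiate()] over the coordinate histories.
#'
#' @param states a `state_trajectory` (q only)
#' @param cutoff_hz low-pass cutoff (Hz); `Inf` disables filtering
#' @return the trajectory with smoothed `q` and filled `qd`, `qdd`
#' @export
differentiate_states <- function(states, cutoff_hz = 6) {
  sd_ <- smooth_differentiate(states$time, states$q, cutoff_hz)
  states$q <- sd_$q; states$qd <- sd_$qd; states$qdd <- sd_$qdd
  states
}

#' Detect gait events from vertical ground reaction force
#'
#' Heel strike = vertical GRF rising through the threshold; toe-off =
#' falling through it (first crossing wins on ties).
#'
#' @param trial a `gait_trial` (or any list with `time` and `grf`)
#' @param threshold event threshold (N), default 20
#' @return list with `hs_r`, `to_r`, `hs_l`, `to_l` event times (s)
#' @export
detect_events <- function(trial, threshold = 20) {
  out <- list()
  for (side in c("r", "l")) {
    fy <- trial$grf[[side]][, 2L]
    up <- which(fy[-1L] >= threshold & fy[-length(fy)] < threshold)
    dn <- which(fy[-1L] < threshold & fy[-length(fy)] >= threshold)
    interp_t <- function(i) {
      f0 <- fy[i]; f1 <- fy[i + 1L]
      trial$time[i] + (threshold - f0) / (f1 - f0) *
        (trial$time[i + 1L] - trial$time[i])
    }
    hs <- vapply(up, interp_t, 0)
    to <- vapply(dn, interp_t, 0)
    # leading-edge starts: force already in stance at t = 0
    if (fy[1L] >= threshold) hs <- c(trial$time[1L], hs)
    out[[paste0("hs_", side)]] <- hs
    out[[paste0("to_", side)]] <- to
  }
  if (length(out$hs_r) < 2L && length(out$hs_l) < 2L)
    stop("no full gait cycle found in the ground reaction force")
  out
}

#' Normalize a time series to the gait cycle
#'
#' Resamples heel-strike-to-heel-strike (right side by default) onto 101
#' points, 0-100% GC inclusive.
#'
#' @param time time grid (s)
#' @param x numeric vector or matrix (frames x k) on that grid
#' @param events event list as from [detect_events()]
#' @param side which limb's heel strikes bound the cycle
#' @param cycle which full cycle to use (1 = first)
#' @return list with `pct` (0..100) and `x` (101 x k matrix), plus
#'   `toe_off_pct` for the ipsilateral toe-off
#' @export
time_normalize <- function(time, x, events, side = "r", cycle = 1L) {
  hs <- events[[paste0("hs_", side)]]
  if (length(hs) < cycle + 1L) stop("fewer than one full gait cycle")
  t0 <- hs[cycle]; t1 <- hs[cycle + 1L]
  x <- as.matrix(x)
  pct <- seq(0, 100, length.out = 101L)
  tt <- t0 + pct / 100 * (t1 - t0)
  out <- apply(x, 2L, function(col)
    stats::approx(time, col, xout = tt, rule = 2L)$y)
  to <- events[[paste0("to_", side)]]
  to <- to[to > t0 & to < t1]
  list(pct = pct, x = out,
       toe_off_pct = if (length(to)) 100 * (to[1L] - t0) / (t1 - t0)
       else NA_real_,
       t0 = t0, t1 = t1)
}
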