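# Normative sagittal gait waveforms and the obesity adaptation.

#' Normative gait waveform set
#'
#' Joint-angle templates over the gait cycle (0-100%, heel strike to
#' ipsilateral heel strike) as periodic cubic splines through knot tables,
#' plus pelvis oscillation amplitudes and the cadence model.  Defaults:
#' hip flexion +30 deg at heel strike, -10 deg in late stance, back to +30;
#' knee flexion 5 -> 18 (15% GC, loading response) -> 5 -> 60 (73% GC, swing)
#' -> 5; ankle 0 -> +10 dorsiflexion -> -15 plantarflexion (60% GC) -> 0;
#' pelvis tilt constant.  Stance occupies the first 60% of the cycle, the
#' contralateral limb is offset by 50%, so contralateral toe-off falls at
#' ~10% GC.
#'
#' @param hip,knee,ankle data.frames with columns `pct` (0-100) and `deg`
#'   (the 0% and 100% knots must agree; 100% knot may be omitted)
#' @param pelvis_tilt_deg constant pelvis/HAT tilt (deg, CCW positive)
#' @param pelvis_osc_amp vertical pelvis oscillation amplitude (m) at twice
#'   the stride frequency (double-bump source)
#' @param pelvis_fore_aft_amp fore-aft pelvis oscillation amplitude (m)
#'   (braking/propulsion source)
#' @param cadence_slope,cadence_intercept cadence model
#'   `cadence [steps/min] = slope * speed [m/s] + intercept`
#' @param stance_fraction fraction of the cycle in stance
#' @return an object of class `gait_waveforms`
#' @export
gait_waveforms <- function(
    hip = data.frame(pct = c(0, 50), deg = c(30, -10)),
    knee = data.frame(pct = c(0, 15, 42, 73), deg = c(5, 18, 5, 60)),
    ankle = data.frame(pct = c(0, 45, 60), deg = c(0, 10, -15)),
    pelvis_tilt_deg = 0,
    pelvis_osc_amp = 0.02,
    pelvis_fore_aft_amp = 0.014,
    cadence_slope = 43, cadence_intercept = 65,
    stance_fraction = 0.6, smooth_sd = 2,
    interp = c(hip = "spline", knee = "smooth", ankle = "smooth"),
    pelvis_vert_phase = 0.045,
    trunk_lean_deg = 5,
    cop_rollover = list(s = c(0, 0.15, 0.5, 0.75, 0.88, 1),
                        u = c(0, 0.15, 0.28, 0.50, 1, 1))) {
  knots <- list(hip = hip, knee = knee, ankle = ankle)
  for (nm in names(knots)) {
    k <- knots[[nm]]
    stopifnot(is.data.frame(k), all(c("pct", "deg") %in% names(k)))
    if (k$pct[1L] != 0) stop(nm, " knots must start at 0% GC")
    if (max(k$pct) < 100) {
      k <- rbind(k, data.frame(pct = 100, deg = k$deg[1L]))
    } else if (abs(k$deg[k$pct == 100] - k$deg[1L]) > 1e-12) {
      stop(nm, " waveform not periodic: 0% and 100% knots differ")
    }
    knots[[nm]] <- k
  }
  structure(list(knots = knots, pelvis_tilt_deg = pelvis_tilt_deg,
                 pelvis_osc_amp = pelvis_osc_amp,
                 pelvis_fore_aft_amp = pelvis_fore_aft_amp,
                 cadence_slope = cadence_slope,
                 cadence_intercept = cadence_intercept,
                 stance_fraction = stance_fraction,
                 smooth_sd = smooth_sd, interp = interp,
                 pelvis_vert_phase = pelvis_vert_phase,
                 trunk_lean_deg = trunk_lean_deg,
                 cop_rollover = cop_rollover),
            class = "gait_waveforms")
}

# Waveform evaluator (deg as a function of %GC), with derivatives.
# Two constructions: "spline" fits a periodic cubic spline straight
# through the knots (right choice for sparse, smooth templates like the
# hip's, where it cannot ring); "smooth" interpolates the knots linearly
# (shape preserving, no overshoot), applies circular Gaussian smoothing
# (sd in %GC) for C2 periodicity, then fits the periodic spline through
# the smoothed dense samples (right choice for dense, cornered templates
# like the knee's and ankle's).
waveform_fun <- function(wf, joint) {
  k <- wf$knots[[joint]]
  method <- (wf$interp %||% c())[joint]
  if (identical(unname(method), "spline"))
    return(stats::splinefun(k$pct, k$deg, method = "periodic"))
  step <- 0.25
  p <- seq(0, 100 - step, by = step)
  v <- stats::approx(k$pct, k$deg, xout = p, rule = 2L)$y
  sd_ <- wf$smooth_sd %||% 0
  if (sd_ > 0) {
    half <- ceiling(4 * sd_ / step)
    kern <- stats::dnorm(seq(-half, half) * step, sd = sd_)
    kern <- kern / sum(kern)
    np <- length(p)
    vpad <- c(v[(np - half + 1L):np], v, v[1L:half])
    v <- stats::filter(vpad, kern, sides = 2L)[(half + 1L):(half + np)]
  }
  stats::splinefun(c(p, 100), c(v, v[1L]), method = "periodic")
}

#' Evaluate a joint-angle waveform
#'
#' @param wf a [gait_waveforms()] set
#' @param joint `"hip"`, `"knee"` or `"ankle"`
#' @param pct percent gait cycle (any real; wrapped mod 100)
#' @param deriv derivative order w.r.t. pct (0..2)
#' @return angle in degrees (or deg per %GC^deriv)
#' @export
eval_waveform <- function(wf, joint, pct, deriv = 0) {
  f <- waveform_fun(wf, joint)
  f(pct %% 100, deriv = deriv)
}

#' Cadence and stride timing for a walking speed
#'
#' @param wf a [gait_waveforms()] set
#' @param speed walking speed (m/s)
#' @return list with `cadence` (steps/min), `stride_time` (s),
#'   `stride_length` (m)
#' @export
stride_timing <- function(wf, speed) {
  if (speed <= 0) stop("speed must be positive")
  cad <- wf$cadence_slope * speed + wf$cadence_intercept
  stride_time <- 120 / cad  # two steps per stride
  list(cadence = cad, stride_time = stride_time,
       stride_length = speed * stride_time)
}

#' Apply the obese-gait adaptation to a waveform set
#'
#' Obese children walk with a flatter loading response and damped vertical
#' pelvis excursion (on top of the slower self-selected speed, which is a
#' cohort property): the early-stance knee-flexion excursion is scaled by
#' `1 - 0.2 * severity` and the pelvis vertical oscillation amplitude by
#' `1 - 0.15 * severity`.
#'
#' @param wf a [gait_waveforms()] set
#' @param severity adaptation severity in `[0, 1]` (1 = full obese pattern)
#' @return modified `gait_waveforms`
#' @export
apply_obesity_adaptation <- function(wf, severity = 1) {
  if (!is.finite(severity) || severity < 0 || severity > 1)
    stop("severity must be in [0, 1]")
  out <- wf
  k <- out$knots$knee
  base <- k$deg[1L]
  lr <- which(k$pct > 0 & k$pct < 50)  # loading-response knots
  if (length(lr)) {
    peak_i <- lr[which.max(k$deg[lr])]
    k$deg[peak_i] <- base + (k$deg[peak_i] - base) * (1 - 0.2 * severity)
  }
  out$knots$knee <- k
  out$pelvis_osc_amp <- wf$pelvis_osc_amp * (1 - 0.15 * severity)
  out
}
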