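# Synthetic cohorts and dynamically consistent synthetic gait trials.

#' Cohort specification
#'
#' Defaults reproduce the reference populations: eight obese boys
#' (75.1 +/- 11.0 kg, 155.4 +/- 4.9 cm, self-selected speed 1.10 +/- 0.08
#' m/s) and eight normal-weight boys (43.1 +/- 10.5 kg, 150.6 +/- 6.0 cm,
#' 1.22 +/- 0.08 m/s), three walking trials each.
#'
#' @param group `"normal"` or `"obese"`
#' @param n number of subjects (>= 1)
#' @param mass_mean,mass_sd body mass distribution (kg)
#' @param height_mean,height_sd stature distribution (m)
#' @param speed_mean,speed_sd walking-speed distribution (m/s)
#' @param trials_per_subject walking trials per subject
#' @param seed integer RNG seed for [sample_cohort()]
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(group = c("normal", "obese"), n = 8,
                        mass_mean = NULL, mass_sd = NULL,
                        height_mean = NULL, height_sd = NULL,
                        speed_mean = NULL, speed_sd = NULL,
                        trials_per_subject = 3, seed = 42) {
  group <- match.arg(group)
  def <- if (group == "obese") {
    list(mass = c(75.1, 11.0), height = c(1.554, 0.049), speed = c(1.10, 0.08))
  } else {
    list(mass = c(43.1, 10.5), height = c(1.506, 0.060), speed = c(1.22, 0.08))
  }
  spec <- list(group = group, n = as.integer(n),
               mass_mean = mass_mean %||% def$mass[1L],
               mass_sd = mass_sd %||% def$mass[2L],
               height_mean = height_mean %||% def$height[1L],
               height_sd = height_sd %||% def$height[2L],
               speed_mean = speed_mean %||% def$speed[1L],
               speed_sd = speed_sd %||% def$speed[2L],
               trials_per_subject = as.integer(trials_per_subject),
               seed = as.integer(seed))
  if (spec$n < 1L) stop("n must be >= 1")
  if (any(c(spec$mass_sd, spec$height_sd, spec$speed_sd) < 0))
    stop("standard deviations must be >= 0")
  structure(spec, class = "cohort_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated-normal draw (+/- `trunc` sd) by rejection; sd 0 returns the mean.
rtruncnorm1 <- function(n, mean, sd, trunc = 2.5) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (abs(x - mean) <= trunc * sd) break
    }
    out[i] <- x
  }
  out
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a synthetic cohort
#'
#' Draws `n` subjects from truncated normal distributions (truncated at
#' +/- 2.5 sd) for mass, height and walking speed; deterministic for a
#' fixed spec seed.
#'
#' @param spec a [cohort_spec()]
#' @return list of [subject_anthropometry()] objects
#' @examples
#' cohort <- sample_cohort(cohort_spec("normal", n = 4, seed = 1))
#' sapply(cohort, function(s) s$mass)
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    mass <- rtruncnorm1(spec$n, spec$mass_mean, spec$mass_sd)
    height <- rtruncnorm1(spec$n, spec$height_mean, spec$height_sd)
    speed <- rtruncnorm1(spec$n, spec$speed_mean, spec$speed_sd)
    age <- floor(stats::runif(spec$n, 8, 13))
    lapply(seq_len(spec$n), function(i)
      subject_anthropometry(
        sprintf("%s%02d", toupper(substr(spec$group, 1L, 2L)), i),
        mass = mass[i], height = height[i], age = age[i],
        group = spec$group, walking_speed = speed[i]))
  })
}

# Marker protocol: planar-sufficient reduced set; local coordinates per
# segment, scaled geometry.  4 HAT/pelvis markers + 2 thigh, 2 shank,
# 3 foot markers per side.
model_markers <- function(model) {
  g <- model$geometry; hs <- g$height_scale
  Lt <- model$segments$thigh_r$length
  Ls <- model$segments$shank_r$length
  Lf <- model$segments$foot_r$length
  h <- g$ankle_height
  hat <- data.frame(
    name = c("ASIS", "PSIS", "ILCF", "ILCB"), segment = "hat",
    lx = c(0.10, -0.11, 0.07, -0.07) * hs,
    ly = c(0.03, 0.04, 0.12, 0.12) * hs, stringsAsFactors = FALSE)
  per_side <- function(side) {
    S <- toupper(side)
    data.frame(
      name = paste0(S, c("THI1", "THI2", "SHA1", "SHA2", "HEE", "TOE", "MID")),
      segment = c(rep(paste0("thigh_", side), 2L),
                  rep(paste0("shank_", side), 2L),
                  rep(paste0("foot_", side), 3L)),
      lx = c(0.040 * hs, 0.035 * hs, 0.035 * hs, 0.030 * hs,
             -0.25 * Lf, 0.70 * Lf, 0.25 * Lf),
      ly = c(-0.35 * Lt, -0.72 * Lt, -0.30 * Ls, -0.70 * Ls,
             -h + 0.015 * hs, -h + 0.010 * hs, -h + 0.055 * hs),
      stringsAsFactors = FALSE)
  }
  rbind(hat, per_side("r"), per_side("l"))
}

# Fore-aft pelvis acceleration shape: harmonics (sin/cos pairs, k = 1..6)
# of the step cycle fitted to the physiological whole-body anteroposterior
# profile (braking trough ~13% GC, propulsion peak ~48% GC wrapping into
# the next step, zero net impulse).  Unit amplitude = braking trough of 1.
FORE_AFT_COEF <- matrix(c(
  -0.77440, 0.73146, -0.12808, 0.27035, 0.01292, 0.13533,
  0.03268, 0.07667, 0.02949, 0.04181, 0.03462, 0.02408) / 1.022,
  nrow = 2L)

# Analytic generalized coordinates for a subject walking with waveform set
# `wf` at `speed`; returns q, qd, qdd matrices over the time grid.
# `tilt_A`/`tilt_B` are cosine/sine harmonic coefficients (rad) of a
# periodic pelvis-tilt oscillation at multiples of the stride frequency,
# solved by the generator so the whole-body moment balance closes on the
# heel-to-toe COP template (trunk sway as the angular-momentum regulator).
waveform_states <- function(model, wf, speed, t, tilt_A = NULL,
                            tilt_B = NULL) {
  tim <- stride_timing(wf, speed)
  T <- tim$stride_time
  d2r <- pi / 180
  rate <- 100 / T  # d pct / dt
  n <- length(t)
  q <- matrix(0, n, 9L, dimnames = list(NULL, GAIT_COORDS))
  qd <- q; qdd <- q
  pct_r <- (t / T * 100)
  pct_l <- pct_r + 50
  lean <- (wf$trunk_lean_deg %||% 0) * d2r
  for (side in c("r", "l")) {
    pct <- if (side == "r") pct_r else pct_l
    for (joint in c("hip", "knee", "ankle")) {
      f <- waveform_fun(wf, joint)
      cn <- paste0(joint, "_", side)
      q[, cn] <- f(pct %% 100) * d2r
      qd[, cn] <- f(pct %% 100, deriv = 1L) * d2r * rate
      qdd[, cn] <- f(pct %% 100, deriv = 2L) * d2r * rate^2
    }
    # trunk-only forward lean (positive = forward = negative tilt in the
    # CCW convention): carried by pelvis_tilt below, compensated in the
    # relative hip angle so absolute leg kinematics stay normative
    q[, paste0("hip_", side)] <- q[, paste0("hip_", side)] + lean
  }
  om <- 4 * pi / T  # pelvis oscillation at twice the stride frequency
  A <- wf$pelvis_osc_amp
  B <- wf$pelvis_fore_aft_amp
  Lleg <- model$segments$thigh_r$length + model$segments$shank_r$length
  y0 <- 0.96 * Lleg + model$geometry$ankle_height
  q[, "pelvis_tx"] <- speed * t
  qd[, "pelvis_tx"] <- speed
  qdd[, "pelvis_tx"] <- 0
  accel_scale <- B * om^2  # braking-trough acceleration magnitude
  for (k in seq_len(ncol(FORE_AFT_COEF))) {
    sk <- sin(k * om * t); ck <- cos(k * om * t)
    ak <- FORE_AFT_COEF[1L, k]; bk <- FORE_AFT_COEF[2L, k]
    # displacement harmonic reproducing accel = scale*(ak sin + bk cos)
    dk <- -accel_scale / (k * om)^2
    q[, "pelvis_tx"] <- q[, "pelvis_tx"] + dk * (ak * sk + bk * ck)
    qd[, "pelvis_tx"] <- qd[, "pelvis_tx"] +
      dk * (k * om) * (ak * ck - bk * sk)
    qdd[, "pelvis_tx"] <- qdd[, "pelvis_tx"] +
      accel_scale * (ak * sk + bk * ck)
  }
  ph <- (wf$pelvis_vert_phase %||% 0) * T  # COM low point lags heel strike
  q[, "pelvis_ty"] <- y0 - A * cos(om * (t - ph))
  qd[, "pelvis_ty"] <- A * om * sin(om * (t - ph))
  qdd[, "pelvis_ty"] <- A * om^2 * cos(om * (t - ph))
  q[, "pelvis_tilt"] <- wf$pelvis_tilt_deg * d2r - lean
  if (!is.null(tilt_A)) {
    Om <- 2 * pi / T
    for (k in seq_along(tilt_A)) {
      ck <- cos(k * Om * t); sk <- sin(k * Om * t)
      q[, "pelvis_tilt"] <- q[, "pelvis_tilt"] + tilt_A[k] * ck +
        tilt_B[k] * sk
      qd[, "pelvis_tilt"] <- qd[, "pelvis_tilt"] +
        k * Om * (-tilt_A[k] * sk + tilt_B[k] * ck)
      qdd[, "pelvis_tilt"] <- qdd[, "pelvis_tilt"] -
        (k * Om)^2 * (tilt_A[k] * ck + tilt_B[k] * sk)
    }
  }
  list(q = q, qd = qd, qdd = qdd, stride_time = T, pct_r = pct_r %% 100)
}

# Whole-body kinetics on a state set: total external force requirement,
# moment requirement about the origin, and heel/toe world x per foot.
wb_kinetics <- function(model, st) {
  n <- nrow(st$q)
  g <- model$gravity
  cs <- com_specs(model)
  Lf <- model$segments$foot_r$length
  hh <- model$geometry$ankle_height
  af <- model$geometry$ankle_from_heel
  heel_r <- point_spec(model, "foot_r", c(-af * Lf, -hh))
  toe_r <- point_spec(model, "foot_r", c((1 - af) * Lf, -hh))
  heel_l <- point_spec(model, "foot_l", c(-af * Lf, -hh))
  toe_l <- point_spec(model, "foot_l", c((1 - af) * Lf, -hh))
  Ftot <- matrix(0, n, 2L)
  tau_req <- numeric(n)
  heel_x <- matrix(0, n, 2L); toe_x <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    qi <- st$q[i, ]; qdi <- st$qd[i, ]; qddi <- st$qdd[i, ]
    for (ci in cs) {
      a <- pt_acc(ci$spec, qi, qdi, qddi)
      p <- pt_pos(ci$spec, qi)
      f <- ci$mass * (a - g)
      Ftot[i, ] <- Ftot[i, ] + f
      tau_req[i] <- tau_req[i] + (p[1L] * f[2L] - p[2L] * f[1L]) +
        ci$inertia * sum(ci$cvec * qddi)
    }
    heel_x[i, ] <- c(pt_pos(heel_r, qi)[1L], pt_pos(heel_l, qi)[1L])
    toe_x[i, ] <- c(pt_pos(toe_r, qi)[1L], pt_pos(toe_l, qi)[1L])
  }
  list(Ftot = Ftot, tau_req = tau_req, heel_x = heel_x, toe_x = toe_x)
}

# Whole-body moment of inertia about the pelvis point (mean over frames):
# the gain of the tilt-harmonic solver.
inertia_about_pelvis <- function(model, st) {
  cs <- com_specs(model)
  n <- nrow(st$q)
  idx <- unique(round(seq(1L, n, length.out = min(n, 20L))))
  vals <- vapply(idx, function(i) {
    qi <- st$q[i, ]
    P <- c(qi[1L], qi[2L])
    s <- 0
    for (ci in cs) {
      rho <- pt_pos(ci$spec, qi) - P
      s <- s + ci$inertia + ci$mass * sum(rho^2)
    }
    s
  }, 0)
  mean(vals)
}

# Canonical single-foot anteroposterior GRF shape (N): braking lobe after
# heel strike (trough ~13% GC), propulsive lobe through push-off (peak
# ~50% GC, ending at toe-off).  During double support the two feet carry
# opposite-sign shear, which a shared split ratio cannot represent; the
# per-foot fore-aft force is this shape plus a load-share-weighted
# correction so the two feet sum exactly to the whole-body requirement.
foot_fore_aft_shape <- function(pct, bw, stance_pct = 60) {
  lobe <- function(q, q0) ifelse(q < 0 | q > 1, 0,
    ifelse(q <= q0, sin(pi / 2 * q / q0),
           sin(pi / 2 * (1 + (q - q0) / (1 - q0)))))
  p <- pct %% 100
  -0.20 * bw * lobe((p - 3) / 30, 10 / 30) +
    0.23 * bw * lobe((p - 33) / (stance_pct - 33), 17 / (stance_pct - 33))
}

# Cosine weight-transfer ramp: right-foot share of the total GRF as a
# function of %GC (stance 0..60, double support 0..10 and 50..60).
stance_share <- function(pct, stance_pct = 60) {
  p <- pct %% 100
  ramp <- stance_pct - 50  # double-support duration in %GC
  ifelse(p < ramp, (1 - cos(pi * p / ramp)) / 2,
         ifelse(p < 50, 1,
                ifelse(p < stance_pct,
                       (1 + cos(pi * (p - 50) / ramp)) / 2, 0)))
}

#' Generate a dynamically consistent synthetic gait trial
#'
#' Joint angles follow the waveform templates time-scaled to the subject's
#' cadence; the pelvis advances at the mean speed with a vertical sinusoid
#' at twice the stride frequency.  The total ground reaction force is then
#' *derived* from whole-body Newton-Euler mechanics
#' (`F(t) = sum_i m_i (a_i(t) - g)`), split between the feet with a cosine
#' ramp over double support, and the centers of pressure are placed so the
#' whole-body moment balance closes as well - so inverse dynamics on a
#' noise-free trial returns near-zero pelvis residuals by construction.
#' Markers are synthesized at fixed anatomical offsets with additive
#' Gaussian noise.
#'
#' @param anthro a [subject_anthropometry()]
#' @param model the scaled `gait_model` for this subject
#' @param waveforms a [gait_waveforms()] set
#' @param speed walking speed (m/s); defaults to the subject's
#' @param seed RNG seed for the marker noise
#' @param noise_sd marker noise standard deviation (m); 0 for noise-free
#' @param n_strides strides to synthesize
#' @param fs sampling rate (Hz)
#' @return an object of class `gait_trial` with elements `time`, `markers`
#'   (frames x markers x 2 array), `grf`/`cop` per foot, `events`,
#'   `subject`, and a `truth` attribute holding the generating states
#' @export
generate_trial <- function(anthro, model, waveforms,
                           speed = anthro$walking_speed, seed = 1,
                           noise_sd = 0.002, n_strides = 2, fs = 100) {
  if (!is.finite(speed) || speed <= 0) stop("speed must be positive")
  wf <- waveforms
  tim <- stride_timing(wf, speed)
  T <- tim$stride_time
  t <- seq(0, n_strides * T, by = 1 / fs)
  n <- length(t)
  stance_pct <- wf$stance_fraction * 100
  Om <- 2 * pi / T
  K <- 25L
  tilt_A <- numeric(K); tilt_B <- numeric(K)
  harm <- cbind(outer(t, seq_len(K) * Om, function(tt, w) cos(w * tt)),
                outer(t, seq_len(K) * Om, function(tt, w) sin(w * tt)))

  # Iteratively solve the pelvis-tilt harmonics so the whole-body moment
  # requirement matches the moment applied by the heel-to-toe COP template:
  # trunk sway absorbs the angular-momentum mismatch.
  st <- NULL; kin <- NULL; Ieff <- NULL
  grf_parts <- function(kin, st) {
    pct_r <- st$pct_r
    pct_l <- (pct_r + 50) %% 100
    s_r <- stance_share(pct_r, stance_pct)
    s_l <- stance_share(pct_l, stance_pct)
    # physiological roll-over: quick heel-to-midfoot progression, then on
    # to the forefoot by heel rise (concave power law, ends at 95% of the
    # foot); monotone in stance progress
    roll <- wf$cop_rollover %||%
      list(s = c(0, 0.15, 0.5, 0.75, 0.88, 1), u = c(0, 0.15, 0.28, 0.50, 1, 1))
    u_r <- stats::approx(roll$s, roll$u, pmin(pct_r / stance_pct, 1),
                         rule = 2L)$y
    u_l <- stats::approx(roll$s, roll$u, pmin(pct_l / stance_pct, 1),
                         rule = 2L)$y
    cop_r <- kin$heel_x[, 1L] + u_r * (kin$toe_x[, 1L] - kin$heel_x[, 1L])
    cop_l <- kin$heel_x[, 2L] + u_l * (kin$toe_x[, 2L] - kin$heel_x[, 2L])
    list(s_r = s_r, s_l = s_l, cop_r = cop_r, cop_l = cop_l,
         grf_r = s_r * kin$Ftot, grf_l = s_l * kin$Ftot)
  }
  rms_prev <- Inf
  for (it in seq_len(16L)) {
    st <- waveform_states(model, wf, speed, t, tilt_A, tilt_B)
    kin <- wb_kinetics(model, st)
    gp <- grf_parts(kin, st)
    applied <- gp$cop_r * gp$grf_r[, 2L] + gp$cop_l * gp$grf_l[, 2L]
    dtau <- kin$tau_req - applied
    if (is.null(Ieff)) Ieff <- inertia_about_pelvis(model, st)
    cf <- stats::lm.fit(cbind(1, harm), dtau)$coefficients
    ac <- cf[2L:(K + 1L)]; bc <- cf[(K + 2L):(2L * K + 1L)]
    rms <- sqrt(mean((dtau - cf[1L])^2))
    # stop once the periodic mismatch is negligible or has plateaued (the
    # DC component is handled by the COP correction below)
    if (rms < 0.05 || rms > 0.995 * rms_prev) break
    rms_prev <- rms
    damp <- 0.7
    kfac <- (seq_len(K) * Om)^2 * Ieff
    tilt_A <- tilt_A + damp * ac / kfac
    tilt_B <- tilt_B + damp * bc / kfac
  }
  gp <- grf_parts(kin, st)
  s_r <- gp$s_r; s_l <- gp$s_l
  grf_r <- gp$grf_r; grf_l <- gp$grf_l
  Ftot <- kin$Ftot
  if (any(grf_r[s_r > 0, 2L] < 0) || any(grf_l[s_l > 0, 2L] < 0))
    stop("kinematics dynamically inconsistent with contact ",
         "(derived vertical GRF < 0 during stance)")

  # reallocate the fore-aft component: per-foot physiological shape plus a
  # load-share-weighted correction summing exactly to the net requirement
  # (applied at ground level, so the moment balance is unaffected)
  bw_n <- total_mass(model) * 9.81
  pct_r <- st$pct_r; pct_l <- (pct_r + 50) %% 100
  shp_r <- foot_fore_aft_shape(pct_r, bw_n, stance_pct) * (s_r > 0)
  shp_l <- foot_fore_aft_shape(pct_l, bw_n, stance_pct) * (s_l > 0)
  corr <- Ftot[, 1L] - shp_r - shp_l
  grf_r[, 1L] <- shp_r + s_r * corr
  grf_l[, 1L] <- shp_l + s_l * corr

  # Residual (non-periodic/DC) moment mismatch goes into a shared COP
  # shift; small once the tilt solve has converged.
  applied <- gp$cop_r * grf_r[, 2L] + gp$cop_l * grf_l[, 2L]
  delta <- (kin$tau_req - applied) / Ftot[, 2L]
  cop_r <- gp$cop_r + delta
  cop_l <- gp$cop_l + delta
  cop_r[s_r == 0] <- NA_real_
  cop_l[s_l == 0] <- NA_real_

  # Markers with additive noise
  mtab <- model_markers(model)
  specs <- lapply(seq_len(nrow(mtab)), function(k)
    point_spec(model, mtab$segment[k], c(mtab$lx[k], mtab$ly[k])))
  markers <- array(0, dim = c(n, nrow(mtab), 2L),
                   dimnames = list(NULL, mtab$name, c("x", "y")))
  for (i in seq_len(n))
    for (k in seq_len(nrow(mtab)))
      markers[i, k, ] <- pt_pos(specs[[k]], st$q[i, ])
  if (noise_sd > 0) {
    markers <- with_seed(seed, markers + array(
      stats::rnorm(length(markers), 0, noise_sd), dim = dim(markers)))
  }

  events <- list(
    hs_r = T * seq(0, n_strides),
    to_r = T * (wf$stance_fraction + seq(0, n_strides - 1)),
    hs_l = T * (0.5 + seq(0, n_strides - 1)),
    to_l = T * (wf$stance_fraction - 0.5 + seq(0, n_strides)))
  events <- lapply(events, function(e) e[e >= 0 & e <= max(t)])

  structure(list(time = t, markers = markers,
                 grf = list(r = grf_r, l = grf_l),
                 cop = list(r = cop_r, l = cop_l),
                 events = events, subject = anthro,
                 meta = list(speed = speed, fs = fs, stride_time = T,
                             stance_fraction = wf$stance_fraction,
                             noise_sd = noise_sd)),
            class = "gait_trial",
            truth = list(q = st$q, qd = st$qd, qdd = st$qdd))
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> %s: %.2f s @ %d Hz, %d markers, speed %.2f m/s\n",
    x$subject$subject_id, max(x$time), x$meta$fs, dim(x$markers)[2L],
    x$meta$speed))
  invisible(x)
}
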