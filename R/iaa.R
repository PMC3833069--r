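# Induced acceleration analysis: per-muscle contributions to the vertical
# (support) and fore-aft (progression) acceleration of the whole-body COM.

# Generalized force of muscle m at one frame via its signed moment arms.
muscle_gen_force <- function(model, muscle, force, q) {
  Q <- numeric(9L)
  for (cn in names(muscle$arms))
    Q[coord_index(cn)] <- Q[coord_index(cn)] +
      moment_arm(muscle, cn, q[cn]) * force
  Q
}

reserve_gen_force <- function(reserves) {
  Q <- numeric(9L)
  Q[4L:9L] <- reserves
  Q
}

# Stance-foot contact constraints at one frame: a kinematic pin at the
# material point currently under the COP, driven at that point's measured
# acceleration (a "moving pin").  On dynamically consistent data the pin's
# constraint force reproduces the measured GRF, so the source decomposition
# closes on the measured COM acceleration exactly.
frame_constraints <- function(model, trial, states, i) {
  cons <- list()
  qi <- states$q[i, ]; qdi <- states$qd[i, ]; qddi <- states$qdd[i, ]
  for (side in c("r", "l")) {
    if (sum(abs(trial$grf[[side]][i, ])) == 0) next
    cop <- c(trial$cop[[side]][i], 0)
    if (anyNA(cop)) next
    seg <- paste0("foot_", side)
    local <- world_to_local(model, seg, cop, qi)
    spec <- point_spec(model, seg, local)
    cons[[length(cons) + 1L]] <-
      list(spec = spec, acc = pt_acc(spec, qi, qdi, qddi), side = side)
  }
  cons
}

#' Induced acceleration analysis (matrix method)
#'
#' For each frame and each muscle, solves the constrained equations of
#' motion with only that muscle's generalized force applied (stance foot
#' kinematically pinned at the center of pressure; swing unconstrained) and
#' maps the resulting generalized accelerations to COM acceleration through
#' the COM Jacobian.  Gravity, velocity (Coriolis/centrifugal plus the
#' constraint's inhomogeneous term), reserve-actuator and pelvis-residual
#' contributions are reported as their own terms so that the superposition
#' over all sources reproduces the measured COM acceleration.
#'
#' @param states differentiated `state_trajectory`
#' @param muscle_solution a `muscle_solution`
#' @param model scaled `gait_model`
#' @param trial the `gait_trial`
#' @param loads optional `net_joint_loads` supplying pelvis residuals
#' @param frames frame indices to analyze (default all)
#' @return an `iaa_result` with arrays `muscle_fx`/`muscle_fy`
#'   (frames x muscles), vectors for `gravity`, `velocity`, `reserve`,
#'   `residual` terms (frames x 2 each), and `total` = sum of all terms
#' @export
iaa_matrix <- function(states, muscle_solution, model, trial, loads = NULL,
                       frames = NULL) {
  n <- length(states$time)
  frames <- frames %||% seq_len(n)
  mus <- model$muscles
  nm <- length(mus)
  fx <- matrix(NA_real_, n, nm, dimnames = list(NULL, names(mus)))
  fy <- fx
  grav <- matrix(NA_real_, n, 2L); velo <- grav; resv <- grav; resi <- grav
  tot <- grav
  flagged <- integer(0)
  for (i in frames) {
    qi <- states$q[i, ]; qdi <- states$qd[i, ]
    cons <- frame_constraints(model, trial, states, i)
    Jcom <- com_jacobian(model, qi)
    acc0 <- com_acc0(model, qi, qdi)
    solve_src <- function(Q, vel_term = FALSE) {
      cc <- cons
      if (!vel_term)  # homogeneous constraint for force sources
        cc <- lapply(cc, function(cn) {
          cn$acc <- pt_acc0(cn$spec, qi, qdi); cn })
      sol <- tryCatch(
        constrained_qdd(model, qi, qdi, Q, cc),
        error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      out <- as.numeric(Jcom %*% sol$qdd)
      if (vel_term) out <- out + acc0
      out
    }
    bad <- FALSE
    for (j in seq_len(nm)) {
      Q <- muscle_gen_force(model, mus[[j]], muscle_solution$forces[i, j], qi)
      a <- solve_src(Q)
      if (is.null(a)) { bad <- TRUE; break }
      fx[i, j] <- a[1L]; fy[i, j] <- a[2L]
    }
    if (bad) { flagged <- c(flagged, i); next }
    grav[i, ] <- solve_src(gravity_gen(model, qi))
    velo[i, ] <- solve_src(-bias_gen(model, qi, qdi), vel_term = TRUE)
    resv[i, ] <- solve_src(reserve_gen_force(muscle_solution$reserves[i, ]))
    resi[i, ] <- if (is.null(loads)) c(0, 0) else
      solve_src(c(loads$residual_force[i, ], loads$residual_moment[i],
                  numeric(6L)))
    tot[i, ] <- c(sum(fx[i, ], na.rm = FALSE), sum(fy[i, ])) +
      grav[i, ] + velo[i, ] + resv[i, ] + resi[i, ]
  }
  structure(list(time = states$time, frames = frames,
                 muscle_fx = fx, muscle_fy = fy,
                 gravity = grav, velocity = velo, reserve = resv,
                 residual = resi, total = tot, flagged = flagged,
                 method = "matrix", constraint = "pin_at_cop",
                 subject = trial$subject, events = trial$events),
            class = "iaa_result")
}

#' Induced acceleration analysis (short forward-integration method)
#'
#' The perturbation variant: from each analyzed frame the constrained
#' model is integrated forward over a short interval (default 0.01 s) with
#' all forces, and again with one muscle's force removed; the muscle's
#' contribution is `2 * (delta COM displacement) / dt^2`.  Agrees with the
#' matrix method to O(dt).
#'
#' @param states,muscle_solution,model,trial,loads as in [iaa_matrix()]
#' @param dt forward-integration horizon (s)
#' @param frames frame indices to analyze
#' @param n_steps RK4 steps across `dt`
#' @return an `iaa_result` (muscle terms only)
#' @export
iaa_perturbation <- function(states, muscle_solution, model, trial,
                             loads = NULL, dt = 0.01, frames = NULL,
                             n_steps = 2L) {
  n <- length(states$time)
  frames <- frames %||% seq_len(n)
  mus <- model$muscles
  nm <- length(mus)
  fx <- matrix(NA_real_, n, nm, dimnames = list(NULL, names(mus)))
  fy <- fx
  flagged <- integer(0)
  for (i in frames) {
    qi <- states$q[i, ]; qdi <- states$qd[i, ]
    cons <- frame_constraints(model, trial, states, i)
    Qbase <- gravity_gen(model, qi) +
      reserve_gen_force(muscle_solution$reserves[i, ]) +
      (if (is.null(loads)) 0 else
        c(loads$residual_force[i, ], loads$residual_moment[i], numeric(6L)))
    Qmus <- lapply(seq_len(nm), function(j)
      muscle_gen_force(model, mus[[j]], muscle_solution$forces[i, j], qi))
    Qall <- Qbase + Reduce(`+`, Qmus)
    integrate_com <- function(Q_active) {
      # forces held constant over dt; bias re-evaluated along the way
      y <- c(qi, qdi)
      h <- dt / n_steps
      deriv <- function(y) {
        qq <- y[1L:9L]; vv <- y[10L:18L]
        # pin target held at the analysis-frame value across the interval
        sol <- constrained_qdd(model, qq, vv,
                               Q_active - bias_gen(model, qq, vv), cons)
        c(vv, sol$qdd)
      }
      ok <- TRUE
      for (s in seq_len(n_steps)) {
        k1 <- tryCatch(deriv(y), error = function(e) NULL)
        if (is.null(k1)) { ok <- FALSE; break }
        k2 <- deriv(y + h / 2 * k1)
        k3 <- deriv(y + h / 2 * k2)
        k4 <- deriv(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      if (!ok) return(NULL)
      com_position(model, y[1L:9L])
    }
    base_com <- integrate_com(Qall)
    if (is.null(base_com)) { flagged <- c(flagged, i); next }
    for (j in seq_len(nm)) {
      pj <- integrate_com(Qall - Qmus[[j]])
      if (is.null(pj)) { flagged <- c(flagged, i); break }
      d <- 2 * (base_com - pj) / dt^2
      fx[i, j] <- d[1L]; fy[i, j] <- d[2L]
    }
  }
  structure(list(time = states$time, frames = frames,
                 muscle_fx = fx, muscle_fy = fy,
                 gravity = NULL, velocity = NULL, reserve = NULL,
                 residual = NULL, total = NULL, flagged = flagged,
                 method = "perturbation", dt = dt,
                 constraint = "pin_at_cop",
                 subject = trial$subject, events = trial$events),
            class = "iaa_result")
}

#' Group induced-acceleration contributions
#'
#' Sums per-muscle COM-acceleration contributions into functional groups
#' (quadriceps = rectus femoris + vasti, etc.) for one limb, and extracts
#' per-group peak vertical (support) and forward (progression)
#' contributions.
#'
#' @param result an `iaa_result`
#' @param side limb to group
#' @param groups group labels
#' @return list with `fx`, `fy` (frames x groups) and `peaks`
#'   (data.frame: group, peak_vertical, peak_forward)
#' @export
group_iaa <- function(result, side = "r",
                      groups = c("gluteus_maximus", "iliopsoas",
                                 "hamstrings", "quadriceps", "vasti",
                                 "gastrocnemius", "soleus",
                                 "dorsiflexors")) {
  map <- list(
    gluteus_maximus = "glut_max", iliopsoas = "iliopsoas",
    hamstrings = "hamstrings", quadriceps = c("rect_fem", "vasti"),
    vasti = "vasti", rectus_femoris = "rect_fem",
    gastrocnemius = "gastroc", soleus = "soleus",
    dorsiflexors = "dorsiflex")
  bad <- setdiff(groups, names(map))
  if (length(bad)) stop("unknown muscle group: ", paste(bad, collapse = ", "))
  gx <- sapply(groups, function(gname) {
    cols <- paste0(map[[gname]], "_", side)
    rowSums(result$muscle_fx[, cols, drop = FALSE])
  })
  gy <- sapply(groups, function(gname) {
    cols <- paste0(map[[gname]], "_", side)
    rowSums(result$muscle_fy[, cols, drop = FALSE])
  })
  gx <- matrix(gx, nrow = nrow(result$muscle_fx),
               dimnames = list(NULL, groups))
  gy <- matrix(gy, nrow = nrow(result$muscle_fy),
               dimnames = list(NULL, groups))
  peaks <- data.frame(
    group = groups,
    peak_vertical = apply(gy, 2L, max, na.rm = TRUE),
    peak_forward = apply(gx, 2L, max, na.rm = TRUE),
    row.names = NULL)
  list(fx = gx, fy = gy, peaks = peaks)
}
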