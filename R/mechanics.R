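# Planar multibody engine for the 9-DOF sagittal gait model.
#
# Generalized coordinates (fixed order):
#   pelvis_tx, pelvis_ty  [m]   pelvis (= mid-hip point) translation
#   pelvis_tilt           [rad] HAT absolute angle, CCW positive
#   hip_{r,l}             [rad] flexion positive (thigh forward)
#   knee_{r,l}            [rad] flexion positive (shank backward rel. thigh)
#   ankle_{r,l}           [rad] dorsiflexion positive
#
# World frame: x forward (walking direction), y up.  Every segment's
# absolute angle is a fixed linear combination of the coordinates, so
# angular velocity/acceleration are linear in qd/qdd and all point
# kinematics have closed forms.

#' Generalized coordinate names of the planar model
#'
#' @format character vector of length 9, in the canonical order used by
#'   every `q`/`qd`/`qdd` matrix in the package
#' @export
GAIT_COORDS <- c("pelvis_tx", "pelvis_ty", "pelvis_tilt",
                 "hip_r", "knee_r", "ankle_r",
                 "hip_l", "knee_l", "ankle_l")
GAIT_SEGMENTS <- c("hat", "thigh_r", "shank_r", "foot_r",
                   "thigh_l", "shank_l", "foot_l")

coord_index <- function(name) match(name, GAIT_COORDS)

rot2 <- function(phi) {
  c2 <- cos(phi); s2 <- sin(phi)
  matrix(c(c2, s2, -s2, c2), 2, 2)
}

perp2 <- function(v) c(-v[2L], v[1L])

# Coefficient vector c such that the segment's absolute angle is sum(c * q).
seg_cvec <- function(seg) {
  cv <- numeric(9L)
  cv[3L] <- 1
  side <- if (grepl("_r$", seg)) "r" else if (grepl("_l$", seg)) "l" else ""
  if (seg == "hat") return(cv)
  hip <- coord_index(paste0("hip_", side))
  knee <- coord_index(paste0("knee_", side))
  ank <- coord_index(paste0("ankle_", side))
  base <- sub("_[rl]$", "", seg)
  cv[hip] <- 1
  if (base %in% c("shank", "foot")) cv[knee] <- -1
  if (base == "foot") cv[ank] <- 1
  cv
}

# Chain of rotated link vectors from the pelvis origin to the segment's
# proximal reference point (hip for thigh, knee for shank, ankle for foot).
seg_chain <- function(model, seg) {
  if (seg == "hat") return(list())
  side <- if (grepl("_r$", seg)) "r" else "l"
  base <- sub("_[rl]$", "", seg)
  th <- paste0("thigh_", side); sh <- paste0("shank_", side)
  elems <- list()
  if (base %in% c("shank", "foot"))
    elems <- c(elems, list(list(c = seg_cvec(th),
                                v = c(0, -model$segments[[th]]$length))))
  if (base == "foot")
    elems <- c(elems, list(list(c = seg_cvec(sh),
                                v = c(0, -model$segments[[sh]]$length))))
  elems
}

#' Build a kinematic point specification
#'
#' A point fixed to a segment, given in the segment's local frame (origin at
#' the segment's proximal reference point: pelvis for HAT, hip for thigh,
#' knee for shank, ankle for foot; local y along the segment as modeled at
#' zero joint angles).
#'
#' @param model a scaled `gait_model`
#' @param segment one of `"hat"`, `"thigh_r"`, ..., `"foot_l"`
#' @param local numeric length-2 local coordinates (m)
#' @return an opaque point specification for the kinematics helpers
#' @keywords internal
point_spec <- function(model, segment, local) {
  elems <- c(seg_chain(model, segment),
             list(list(c = seg_cvec(segment), v = as.numeric(local))))
  structure(list(elems = elems, segment = segment), class = "gait_point")
}

pt_pos <- function(spec, q) {
  p <- c(q[1L], q[2L])
  for (e in spec$elems) p <- p + rot2(sum(e$c * q)) %*% e$v
  as.numeric(p)
}

pt_jac <- function(spec, q) {
  J <- matrix(0, 2L, 9L)
  J[1L, 1L] <- 1; J[2L, 2L] <- 1
  for (e in spec$elems) {
    w <- as.numeric(rot2(sum(e$c * q)) %*% e$v)
    pw <- perp2(w)
    idx <- which(e$c != 0)
    for (i in idx) J[, i] <- J[, i] + e$c[i] * pw
  }
  J
}

pt_vel <- function(spec, q, qd) {
  v <- c(qd[1L], qd[2L])
  for (e in spec$elems) {
    w <- as.numeric(rot2(sum(e$c * q)) %*% e$v)
    v <- v + sum(e$c * qd) * perp2(w)
  }
  v
}

# Point acceleration with qdd = 0 (i.e. Jdot %*% qd).
pt_acc0 <- function(spec, q, qd) {
  a <- c(0, 0)
  for (e in spec$elems) {
    w <- as.numeric(rot2(sum(e$c * q)) %*% e$v)
    om <- sum(e$c * qd)
    a <- a - om * om * w
  }
  a
}

pt_acc <- function(spec, q, qd, qdd) {
  as.numeric(pt_jac(spec, q) %*% qdd) + pt_acc0(spec, q, qd)
}

# Per-segment COM point specs with mass/inertia, cached on the model.
com_specs <- function(model) {
  if (!is.null(model$.com_specs)) return(model$.com_specs)
  out <- lapply(GAIT_SEGMENTS, function(seg) {
    s <- model$segments[[seg]]
    local <- if (seg == "hat") {
      c(0, s$com_offset * s$length)
    } else if (grepl("^foot", seg)) {
      g <- model$geometry
      c(s$com_offset * s$length - g$ankle_from_heel * s$length,
        -0.5 * g$ankle_height)
    } else {
      c(0, -s$com_offset * s$length)
    }
    list(spec = point_spec(model, seg, local), mass = s$mass,
         inertia = s$inertia, cvec = seg_cvec(seg), segment = seg)
  })
  names(out) <- GAIT_SEGMENTS
  out
}

#' Precompute the model's kinematic caches
#'
#' Attaches the per-segment center-of-mass point specifications to the
#' model so repeated mechanics calls skip rebuilding them.  Call once after
#' [scale_model()] (the cache depends only on segment lengths).
#'
#' @param model a scaled `gait_model`
#' @return the model with caches attached
#' @export
cache_model <- function(model) {
  model$.com_specs <- NULL
  model$.com_specs <- com_specs(model)
  model
}

total_mass <- function(model) sum(vapply(model$segments, `[[`, 0, "mass"))

#' System mass matrix
#'
#' @param model scaled `gait_model`
#' @param q generalized coordinates (length 9)
#' @return 9 x 9 positive-definite mass matrix
#' @export
mass_matrix <- function(model, q) {
  M <- matrix(0, 9L, 9L)
  for (cs in com_specs(model)) {
    J <- pt_jac(cs$spec, q)
    M <- M + cs$mass * crossprod(J) + cs$inertia * tcrossprod(cs$cvec)
  }
  M
}

# Generalized bias (Coriolis/centrifugal) force vector b(q, qd) such that
# the equations of motion read  M(q) qdd + b = Q_applied + Q_gravity.
# Segment angular accelerations are linear in qdd with no velocity products
# (absolute angles are linear in q), so only translational terms appear.
bias_gen <- function(model, q, qd) {
  b <- numeric(9L)
  for (cs in com_specs(model)) {
    J <- pt_jac(cs$spec, q)
    b <- b + cs$mass * as.numeric(crossprod(J, pt_acc0(cs$spec, q, qd)))
  }
  b
}

gravity_gen <- function(model, q) {
  g <- model$gravity
  Q <- numeric(9L)
  for (cs in com_specs(model)) {
    J <- pt_jac(cs$spec, q)
    Q <- Q + cs$mass * as.numeric(crossprod(J, g))
  }
  Q
}

# Generalized force of an external force applied at a world point attached
# to `segment` (local coordinates resolved at the current configuration).
ext_force_gen <- function(model, segment, world_point, force, q) {
  local <- world_to_local(model, segment, world_point, q)
  spec <- point_spec(model, segment, local)
  as.numeric(crossprod(pt_jac(spec, q), force))
}

world_to_local <- function(model, segment, world_point, q) {
  origin_chain <- seg_chain(model, segment)
  p0 <- c(q[1L], q[2L])
  for (e in origin_chain) p0 <- p0 + rot2(sum(e$c * q)) %*% e$v
  phi <- sum(seg_cvec(segment) * q)
  as.numeric(t(rot2(phi)) %*% (world_point - as.numeric(p0)))
}

com_position <- function(model, q) {
  p <- c(0, 0); mt <- 0
  for (cs in com_specs(model)) {
    p <- p + cs$mass * pt_pos(cs$spec, q); mt <- mt + cs$mass
  }
  p / mt
}

com_jacobian <- function(model, q) {
  J <- matrix(0, 2L, 9L); mt <- 0
  for (cs in com_specs(model)) {
    J <- J + cs$mass * pt_jac(cs$spec, q); mt <- mt + cs$mass
  }
  J / mt
}

com_acc0 <- function(model, q, qd) {
  a <- c(0, 0); mt <- 0
  for (cs in com_specs(model)) {
    a <- a + cs$mass * pt_acc0(cs$spec, q, qd); mt <- mt + cs$mass
  }
  a / mt
}

com_acceleration <- function(model, q, qd, qdd) {
  as.numeric(com_jacobian(model, q) %*% qdd) + com_acc0(model, q, qd)
}

#' Forward dynamics acceleration solve
#'
#' Solves `M(q) qdd + b(q, qd) = Q + Q_gravity` for `qdd`.
#'
#' @param model scaled `gait_model`
#' @param q,qd coordinates and velocities (length 9)
#' @param Q applied generalized force (length 9), gravity excluded
#' @param include_gravity add the gravitational generalized force
#' @return length-9 generalized accelerations (rad/s^2, m/s^2)
#' @export
forward_dynamics <- function(model, q, qd, Q, include_gravity = TRUE) {
  rhs <- Q - bias_gen(model, q, qd)
  if (include_gravity) rhs <- rhs + gravity_gen(model, q)
  as.numeric(solve(mass_matrix(model, q), rhs))
}

# Constrained acceleration solve.  `constraints` is a list of
# list(spec = <gait_point>, acc = <target world acceleration of the point>).
# Returns qdd and the constraint forces lambda (one 2-vector per point).
constrained_qdd <- function(model, q, qd, Q, constraints,
                            include_gravity = FALSE, include_bias = FALSE) {
  rhs <- Q
  if (include_bias) rhs <- rhs - bias_gen(model, q, qd)
  if (include_gravity) rhs <- rhs + gravity_gen(model, q)
  nc <- length(constraints)
  M <- mass_matrix(model, q)
  if (nc == 0L)
    return(list(qdd = as.numeric(solve(M, rhs)), lambda = list()))
  Jc <- do.call(rbind, lapply(constraints, function(cn) pt_jac(cn$spec, q)))
  beta <- unlist(lapply(constraints, function(cn)
    cn$acc - pt_acc0(cn$spec, q, qd)))
  k <- nrow(Jc)
  A <- rbind(cbind(M, -t(Jc)), cbind(Jc, matrix(0, k, k)))
  x <- solve(A, c(rhs, beta))
  lam <- x[10L:(9L + k)]
  list(qdd = x[1L:9L],
       lambda = lapply(seq_len(nc), function(i) lam[(2L * i - 1L):(2L * i)]))
}
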