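# Static optimization: decompose net joint moments into muscle forces by
# minimizing the sum of squared activations, with heavily penalized reserve
# actuators guaranteeing feasibility.

# Signed moment-arm matrix (6 joint coords x muscles), arms evaluated at q.
arm_matrix <- function(model, q = NULL) {
  joints <- GAIT_COORDS[4L:9L]
  mus <- model$muscles
  A <- matrix(0, 6L, length(mus),
              dimnames = list(joints, names(mus)))
  for (j in seq_along(mus)) {
    m <- mus[[j]]
    for (cn in names(m$arms)) {
      ang <- if (is.null(q)) 0 else q[cn]
      A[cn, j] <- moment_arm(m, cn, ang)
    }
  }
  A
}

#' Decompose one frame of net moments into muscle activations
#'
#' Solves the strictly convex program
#' `min sum(a^2) + w * sum(r^2)` subject to
#' `sum_i arm_ij * a_i * fmax_i + r_j = M_j` and `0 <= a <= 1`,
#' where `r` are reserve moments (N m).  Reserves are eliminated by
#' substitution (`r = M - A a`), leaving a strictly convex box-constrained
#' quadratic program solved by projected Newton (L-BFGS-B fallback); the
#' moment constraint is then satisfied exactly by construction.  The
#' reserve penalty acts on reserves normalized by subject mass relative to
#' the 43.1 kg reference subject, making the redundancy resolution
#' invariant under pure mass scaling.
#'
#' @param net_moments named length-6 vector of net joint moments (N m) in
#'   coordinate conventions (`hip_r`, `knee_r`, `ankle_r`, `hip_l`, ...)
#' @param q optional coordinates for angle-dependent moment arms
#' @param model scaled `gait_model`
#' @param reserve_weight penalty weight `w` on squared reserve moments
#' @param start optional warm-start activations
#' @return list with `activations`, `forces` (N), `reserves` (N m, per
#'   joint coordinate), `objective`
#' @export
decompose_frame <- function(net_moments, q = NULL, model,
                            reserve_weight = 1000, start = NULL) {
  A <- arm_matrix(model, q)
  fmax <- vapply(model$muscles, `[[`, 0, "f_max")
  G <- A * rep(fmax, each = nrow(A))   # moment per unit activation
  M <- net_moments[rownames(A)]
  nm <- ncol(G)
  # the reserve penalty acts on reserves normalized by subject mass
  # (relative to the 43.1 kg reference subject), which makes the
  # redundancy resolution invariant under pure mass scaling
  mscl <- if (!is.null(model$subject)) 43.1 / model$subject$mass else 1
  w <- reserve_weight * mscl^2
  H <- diag(nm) + w * crossprod(G)   # 0.5 * Hessian
  f <- w * as.numeric(crossprod(G, M))
  sol <- qp_box_active_set(H, f, start, Gs = sqrt(w) * G, ys = sqrt(w) * M)
  if (!sol$converged) {
    obj <- function(a) sum(a^2) + w * sum((M - G %*% a)^2)
    grad <- function(a) 2 * (H %*% a - f)
    fit <- stats::optim(sol$a, obj, grad, method = "L-BFGS-B",
                        lower = rep(0, nm), upper = rep(1, nm),
                        control = list(maxit = 2000L, factr = 1e3))
    sol <- list(a = fit$par, converged = fit$convergence == 0L)
  }
  a <- unname(sol$a)
  r <- as.numeric(M - G %*% a)
  names(r) <- rownames(A)
  list(activations = stats::setNames(a, colnames(A)),
       forces = stats::setNames(a * unname(fmax), colnames(A)),
       reserves = r,
       objective = sum(a^2) + w * sum(r^2),
       converged = sol$converged)
}

# Solver for min a' H a - 2 f' a subject to 0 <= a <= 1 (H pos.def.):
# projected Newton with backtracking line search (Bertsekas-style).  Each
# step solves the Newton system on the currently free variables and
# projects onto the box; backtracking guarantees monotone descent, so the
# iteration cannot cycle.  Strict convexity (H >= I here) gives a unique
# minimizer; KKT conditions are verified at exit.
qp_box_active_set <- function(H, f, start = NULL, max_iter = 200L,
                              Gs = NULL, ys = NULL) {
  nm <- length(f)
  a <- if (is.null(start)) pmin(pmax(solve(H, f), 0), 1)
  else pmin(pmax(as.numeric(start), 0), 1)
  obj <- function(x) sum(x * (H %*% x)) - 2 * sum(f * x)
  gscale <- 2 * (max(abs(f)) + max(abs(H)))
  kkt_ok <- function(x, g) {
    tol <- 1e-11 * gscale
    all(abs(g[x > 1e-12 & x < 1 - 1e-12]) <= tol,
        g[x <= 1e-12] >= -tol, g[x >= 1 - 1e-12] <= tol)
  }
  fo <- obj(a)
  for (it in seq_len(max_iter)) {
    g <- as.numeric(2 * (H %*% a - f))
    if (kkt_ok(a, g)) return(list(a = a, converged = TRUE))
    lo <- a <= 1e-12 & g > 0
    hi <- a >= 1 - 1e-12 & g < 0
    free <- !(lo | hi)
    if (!any(free)) return(list(a = a, converged = TRUE))
    target <- a
    target[lo] <- 0; target[hi] <- 1
    if (!is.null(Gs)) {
      # least-squares form of the Newton system (condition sqrt(kappa(H)))
      k <- sum(free)
      X <- rbind(Gs[, free, drop = FALSE], diag(k))
      yy <- c(ys - as.numeric(Gs[, !free, drop = FALSE] %*% target[!free]),
              numeric(k))
      target[free] <- qr.solve(X, yy)
    } else {
      rhs <- f[free] - as.numeric(H[free, !free, drop = FALSE] %*%
                                    target[!free])
      target[free] <- solve(H[free, free, drop = FALSE], rhs)
    }
    d <- target - a
    stepped <- FALSE
    t <- 1
    for (ls in 1:40) {
      anew <- pmin(pmax(a + t * d, 0), 1)
      fn <- obj(anew)
      if (fn < fo - 1e-16 * abs(fo)) { stepped <- TRUE; break }
      t <- t / 2
    }
    if (!stepped) {
      g <- as.numeric(2 * (H %*% a - f))
      return(list(a = a, converged = kkt_ok(a, g)))
    }
    a <- anew; fo <- fn
  }
  g <- as.numeric(2 * (H %*% a - f))
  list(a = a, converged = kkt_ok(a, g))
}

#' Decompose a whole trial into muscle forces
#'
#' Frame-wise static optimization (no activation dynamics) over the joint
#' moments from inverse dynamics, warm-starting each frame from the last.
#' Frames whose solver fails are flagged and interpolated; more than 2%
#' flagged frames rejects the trial.
#'
#' @param loads `net_joint_loads` from [net_joint_loads()]
#' @param states the matching `state_trajectory`
#' @param model scaled `gait_model`
#' @param reserve_weight reserve penalty (see [decompose_frame()])
#' @return a `muscle_solution`: `activations`, `forces` (frames x muscles),
#'   `reserves` (frames x 6), `objective` per frame
#' @export
decompose_trial <- function(loads, states, model, reserve_weight = 1000) {
  n <- nrow(loads$moments)
  mus_names <- names(model$muscles)
  act <- matrix(0, n, length(mus_names), dimnames = list(NULL, mus_names))
  frc <- act
  res <- matrix(0, n, 6L, dimnames = list(NULL, GAIT_COORDS[4L:9L]))
  objv <- numeric(n)
  flagged <- logical(n)
  warm <- NULL
  for (i in seq_len(n)) {
    sol <- tryCatch(
      decompose_frame(loads$moments[i, ], states$q[i, ], model,
                      reserve_weight, start = warm),
      error = function(e) NULL)
    if (is.null(sol) || !sol$converged) { flagged[i] <- TRUE; next }
    act[i, ] <- sol$activations
    frc[i, ] <- sol$forces
    res[i, ] <- sol$reserves
    objv[i] <- sol$objective
    warm <- sol$activations
  }
  if (mean(flagged) > 0.02)
    stop(sprintf("static optimization failed on %.1f%% of frames (> 2%%)",
                 100 * mean(flagged)))
  if (any(flagged)) {
    goodi <- which(!flagged)
    fill <- function(mat) {
      for (j in seq_len(ncol(mat)))
        mat[flagged, j] <- stats::approx(loads$time[goodi], mat[goodi, j],
                                         xout = loads$time[flagged],
                                         rule = 2L)$y
      mat
    }
    act <- fill(act); frc <- fill(frc); res <- fill(res)
  }
  structure(list(time = loads$time, activations = act, forces = frc,
                 reserves = res, objective = objv,
                 flagged = which(flagged), subject = loads$subject),
            class = "muscle_solution")
}

#' Sum muscle forces into functional groups
#'
#' Grouping follows standard conventions: quadriceps = rectus femoris +
#' vasti; hamstrings, gastrocnemius, soleus, dorsiflexors, gluteus maximus
#' and iliopsoas are the lumped units themselves.
#'
#' @param solution a `muscle_solution`
#' @param side `"r"` or `"l"`
#' @param groups group labels to extract
#' @return matrix (frames x groups) of summed forces (N)
#' @export
group_forces <- function(solution, side = "r",
                         groups = c("quadriceps", "hamstrings",
                                    "gastrocnemius", "soleus",
                                    "dorsiflexors", "gluteus_maximus",
                                    "iliopsoas")) {
  map <- list(
    quadriceps = c("rect_fem", "vasti"),
    hamstrings = "hamstrings",
    gastrocnemius = "gastroc",
    soleus = "soleus",
    dorsiflexors = "dorsiflex",
    gluteus_maximus = "glut_max",
    iliopsoas = "iliopsoas",
    vasti = "vasti",
    rectus_femoris = "rect_fem")
  bad <- setdiff(groups, names(map))
  if (length(bad)) stop("unknown muscle group: ", paste(bad, collapse = ", "))
  out <- sapply(groups, function(gname) {
    cols <- paste0(map[[gname]], "_", side)
    rowSums(solution$forces[, cols, drop = FALSE])
  })
  matrix(out, nrow = nrow(solution$forces),
         dimnames = list(NULL, groups))
}
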