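# Joint reaction analysis: knee reaction force on the tibia with muscle
# forces included, and its compressive (tibia-long-axis) component.

# World-frame endpoints of a muscle's line of action on the shank/foot
# subsystem side.  Returns NULL if the muscle does not cross the knee of
# this side, otherwise list(at = application point, towards = target point).
crossing_action <- function(model, muscle, side, q) {
  sub_segs <- paste0(c("shank_", "foot_"), side)
  o_in <- muscle$origin$segment %in% sub_segs
  i_in <- muscle$insertion$segment %in% sub_segs
  if (o_in == i_in) return(NULL)  # both inside (internal) or both outside
  inner <- if (i_in) muscle$insertion else muscle$origin
  outer <- if (i_in) muscle$origin else muscle$insertion
  # quadriceps route through the patella: the tendon pulls the tibial
  # tuberosity towards the patellar point on the femur
  if (!is.null(muscle$via) && i_in) outer <- muscle$via
  at <- pt_pos(point_spec(model, inner$segment, inner$local), q)
  towards <- pt_pos(point_spec(model, outer$segment, outer$local), q)
  list(at = at, towards = towards)
}

#' Knee joint reaction analysis
#'
#' Newton-Euler force balance of the shank+foot subsystem, solved for the
#' reaction transmitted across the tibiofemoral joint each frame:
#' the reaction equals the subsystem's inertial force minus gravity, ground
#' reaction and the forces of the muscles crossing the knee (quadriceps via
#' the patellar tendon onto the tibial tuberosity, hamstrings at their
#' tibial insertion, gastrocnemius acting on the calcaneus from its femoral
#' origin).  Ankle-crossing uniarticular muscles (soleus, dorsiflexors) are
#' internal to the subsystem and cancel, as they must.  The compressive
#' component is the projection on the tibia long axis (knee to ankle);
#' anterior shear is reported as a secondary output.  The reaction is affine
#' in the muscle-force vector, so group contributions superpose exactly.
#'
#' @param states differentiated `state_trajectory`
#' @param muscle_solution a `muscle_solution` (may be NULL only via
#'   `include_muscles = FALSE` paths such as [knee_reaction_baseline()])
#' @param model scaled `gait_model`
#' @param trial the `gait_trial` with GRF/COP
#' @param side analysis limb
#' @param force_scale optional named vector of per-muscle multipliers
#'   (force-nulling device for group contributions)
#' @return a `knee_load_result`: `reaction` (frames x 2, N, force on tibia),
#'   `compression`/`shear` (N), `compression_bw` (xBW), `ankle_reaction`
#'   (frames x 2), and bookkeeping fields
#' @export
knee_reaction <- function(states, muscle_solution, model, trial,
                          side = "r", force_scale = NULL) {
  if (is.null(muscle_solution))
    stop("muscle solution required; run decompose_trial() first")
  n <- length(states$time)
  g <- model$gravity
  cs <- com_specs(model)
  segs <- paste0(c("shank_", "foot_"), side)
  knee_sp <- point_spec(model, paste0("shank_", side), c(0, 0))
  ankle_sp <- point_spec(model, paste0("foot_", side), c(0, 0))
  reaction <- matrix(0, n, 2L)
  ankle_re <- matrix(0, n, 2L)
  comp <- numeric(n); shear <- numeric(n)
  mus <- model$muscles
  scl <- rep(1, length(mus)); names(scl) <- names(mus)
  if (!is.null(force_scale)) scl[names(force_scale)] <- force_scale

  for (i in seq_len(n)) {
    qi <- states$q[i, ]; qdi <- states$qd[i, ]; qddi <- states$qdd[i, ]
    Fsub <- c(0, 0)
    for (seg in segs) {
      ci <- cs[[seg]]
      Fsub <- Fsub + ci$mass * (pt_acc(ci$spec, qi, qdi, qddi) - g)
    }
    grf <- trial$grf[[side]][i, ]
    R <- Fsub - grf
    # ankle reaction from the foot balance alone (muscles on the foot)
    cf <- cs[[paste0("foot_", side)]]
    Ra <- cf$mass * (pt_acc(cf$spec, qi, qdi, qddi) - g) - grf
    for (mn in names(mus)) {
      m <- mus[[mn]]
      if (m$side != side) next
      Fm <- muscle_solution$forces[i, mn] * scl[mn]
      if (Fm == 0) next
      act <- crossing_action(model, m, side, qi)
      if (!is.null(act)) {
        u <- act$towards - act$at
        u <- u / sqrt(sum(u^2))
        R <- R - Fm * u
      }
      # foot-attached muscle forces for the reported ankle reaction
      if (m$insertion$segment == paste0("foot_", side)) {
        at <- pt_pos(point_spec(model, m$insertion$segment,
                                m$insertion$local), qi)
        tow <- pt_pos(point_spec(model, m$origin$segment,
                                 m$origin$local), qi)
        u <- (tow - at) / sqrt(sum((tow - at)^2))
        Ra <- Ra - Fm * u
      }
    }
    reaction[i, ] <- R
    ankle_re[i, ] <- Ra
    axis <- pt_pos(ankle_sp, qi) - pt_pos(knee_sp, qi)
    axis <- axis / sqrt(sum(axis^2))
    comp[i] <- sum(R * axis)
    shear[i] <- sum(R * perp2(axis))
  }
  bw <- trial$subject$mass * 9.81
  structure(list(time = states$time, reaction = reaction,
                 compression = comp, compression_bw = comp / bw,
                 shear = shear, ankle_reaction = ankle_re,
                 side = side, subject = trial$subject,
                 events = trial$events,
                 meta = list(balance = "planar 2x2 subsystem force balance",
                             axis = "tibia long axis, knee to ankle")),
            class = "knee_load_result")
}

#' Peak compressive tibiofemoral force over stance
#'
#' @param result a `knee_load_result`
#' @param events optional event list (defaults to the result's)
#' @param cycle which gait cycle
#' @return list with `peak_bw` (xBW), `peak_n` (N), `pct_gc` (% gait cycle
#'   of the peak), restricted to the stance phase
#' @export
peak_ctf <- function(result, events = NULL, cycle = 1L) {
  ev <- events %||% result$events
  if (length(result$compression) == 0L) stop("empty knee-load waveform")
  norm <- time_normalize(result$time, cbind(result$compression_bw), ev,
                         side = result$side, cycle = cycle)
  to_pct <- if (is.na(norm$toe_off_pct)) 60 else norm$toe_off_pct
  stance <- norm$pct <= to_pct
  if (!any(stance)) stop("no stance frames in the normalized cycle")
  i <- which.max(norm$x[stance, 1L])
  list(peak_bw = norm$x[stance, 1L][i],
       peak_n = norm$x[stance, 1L][i] * result$subject$mass * 9.81,
       pct_gc = norm$pct[stance][i])
}

#' Muscle-group contributions to the compressive tibiofemoral force
#'
#' Exploits the linearity of the reaction in the muscle forces: each
#' group's contribution is the reaction recomputed with only that group's
#' forces active minus the no-muscle baseline, so baseline + contributions
#' reproduces the total exactly.
#'
#' @param states,muscle_solution,model,trial as in [knee_reaction()]
#' @param side analysis limb
#' @param groups muscle groups to decompose
#' @return list with `total` (the full `knee_load_result`), `baseline`
#'   (no-muscle compression, N), and `contributions` (frames x groups, N)
#' @export
group_contributions <- function(states, muscle_solution, model, trial,
                                side = "r",
                                groups = c("quadriceps", "hamstrings",
                                           "gastrocnemius")) {
  map <- list(quadriceps = c("rect_fem", "vasti"),
              hamstrings = "hamstrings",
              gastrocnemius = "gastroc")
  bad <- setdiff(groups, names(map))
  if (length(bad)) stop("unknown muscle group: ", paste(bad, collapse = ", "))
  all_off <- stats::setNames(rep(0, length(model$muscles)),
                             names(model$muscles))
  base <- knee_reaction(states, muscle_solution, model, trial, side,
                        force_scale = all_off)
  total <- knee_reaction(states, muscle_solution, model, trial, side)
  contrib <- sapply(groups, function(gname) {
    scl <- all_off
    scl[paste0(map[[gname]], "_", side)] <- 1
    on <- knee_reaction(states, muscle_solution, model, trial, side,
                        force_scale = scl)
    on$compression - base$compression
  })
  list(total = total, baseline = base$compression,
       contributions = matrix(contrib, nrow = length(states$time),
                              dimnames = list(NULL, groups)))
}
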