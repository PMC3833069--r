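test_that("static standing with no muscle force matches the closed form", {
  m <- nw_model()
  n <- 3
  q <- matrix(0, n, 9, dimnames = list(NULL, GAIT_COORDS))
  Lleg <- m$segments$thigh_r$length + m$segments$shank_r$length
  q[, "pelvis_ty"] <- Lleg + m$geometry$ankle_height
  zero <- matrix(0, n, 9)
  bw <- m$subject$mass * 9.81
  states <- structure(list(time = seq(0, by = 0.01, length.out = n), q = q,
                           qd = zero, qdd = zero, subject = m$subject),
                      class = "state_trajectory")
  trial <- list(time = states$time,
                grf = list(r = cbind(rep(0, n), rep(bw, n)),
                           l = cbind(rep(0, n), rep(0, n))),
                cop = list(r = rep(0, n), l = rep(NA_real_, n)),
                subject = m$subject, events = NULL)
  sol <- list(forces = matrix(0, n, length(m$muscles),
                              dimnames = list(NULL, names(m$muscles))))
  res <- knee_reaction(states, sol, m, trial, side = "r")
  w_below <- (m$segments$shank_r$mass + m$segments$foot_r$mass) * 9.81
  expect_equal(res$compression, rep(bw - w_below, n), tolerance = 1e-9)
})

test_that("zero muscle forces reproduce the intersegmental force exactly", {
  ex <- ref_exact()
  m <- nw_model()
  sol0 <- ex$solution
  sol0$forces[] <- 0
  res <- knee_reaction(ex$states, sol0, m, ex$trial, side = "r")
  expect_equal(res$reaction, ex$loads$interseg_force$knee_r,
               tolerance = 1e-9)
})

test_that("reaction matches an independent momentum-derivative oracle", {
  # d/dt of the shank+foot subsystem linear momentum must equal the sum of
  # all external forces on the subsystem; solve that for the knee reaction
  # using finite differences of analytically generated velocities.
  ex <- ref_exact()
  m <- nw_model()
  res <- knee_reaction(ex$states, ex$solution, m, ex$trial, side = "r")
  cs <- gaitsim:::com_specs(m)
  segs <- c("shank_r", "foot_r")
  g <- m$gravity
  msub <- sum(vapply(segs, function(s) cs[[s]]$mass, 0))
  dt <- diff(ex$states$time[1:2])
  idx <- seq(10, length(ex$states$time) - 10, by = 23)
  for (i in idx) {
    # momentum at i +/- 1 from the states (positions/velocities only)
    p <- function(k) Reduce(`+`, lapply(segs, function(s)
      cs[[s]]$mass * gaitsim:::pt_vel(cs[[s]]$spec, ex$states$q[k, ],
                                      ex$states$qd[k, ])))
    dpdt <- (p(i + 1) - p(i - 1)) / (2 * dt)
    Fmus <- c(0, 0)
    for (mn in names(m$muscles)) {
      mus <- m$muscles[[mn]]
      if (mus$side != "r") next
      act <- gaitsim:::crossing_action(m, mus, "r", ex$states$q[i, ])
      if (is.null(act)) next
      u <- act$towards - act$at
      Fmus <- Fmus + ex$solution$forces[i, mn] * u / sqrt(sum(u^2))
    }
    oracle <- dpdt - msub * g - ex$trial$grf$r[i, ] - Fmus
    expect_lt(max(abs(oracle - res$reaction[i, ])), 1.5)  # N; O(dt^2) diff
  }
})

test_that("group contributions superpose exactly (affine map)", {
  ex <- ref_exact()
  m <- nw_model()
  gc <- group_contributions(ex$states, ex$solution, m, ex$trial)
  rebuilt <- gc$baseline + rowSums(gc$contributions)
  expect_equal(rebuilt, gc$total$compression, tolerance = 1e-6)
})

test_that("normalized CTF is invariant to subject mass", {
  # scaling mass by c (f_max with it, kinematics and GRF/BW held fixed)
  # scales absolute CTF by c and leaves CTF/BW unchanged
  ex <- ref_exact()
  m <- nw_model()
  c_ <- 1.6
  a2 <- subject_anthropometry("BIG", mass = c_ * 43.1, height = 1.506,
                              group = "normal", walking_speed = 1.22)
  m2 <- cache_model(scale_model(a2))
  trial2 <- ex$trial
  trial2$grf <- lapply(ex$trial$grf, function(gg) c_ * gg)
  trial2$subject <- a2
  states2 <- ex$states; states2$subject <- a2
  loads2 <- net_joint_loads(states2, trial2, m2)
  sol2 <- decompose_trial(loads2, states2, m2)
  r1 <- knee_reaction(ex$states, ex$solution, m, ex$trial, side = "r")
  r2 <- knee_reaction(states2, sol2, m2, trial2, side = "r")
  expect_equal(r2$compression, c_ * r1$compression, tolerance = 1e-6)
  expect_equal(r2$compression_bw, r1$compression_bw, tolerance = 1e-9)
})

test_that("the stance CTF waveform shows the two-peak pattern", {
  pipe <- ref_pipeline()
  norm <- time_normalize(pipe$knee$time, cbind(pipe$knee$compression_bw),
                         pipe$events, side = "r")
  x <- norm$x[, 1]
  p1 <- first_stance_peak(norm$pct, x)
  expect_lt(abs(p1$pct - 10), 8)          # near contralateral toe-off
  # a second local maximum near contralateral heel strike with a valley
  late <- which(norm$pct > 30 & norm$pct <= 60)
  valley <- which(norm$pct > p1$pct & norm$pct <= 35)
  expect_gt(max(x[late]), 1.5 * min(x[valley]))
  expect_gt(p1$value, max(x[valley]))
  expect_error(peak_ctf(structure(list(compression = numeric(0)),
                                  class = "knee_load_result")), "empty")
})
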