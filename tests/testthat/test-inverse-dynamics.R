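# Static equilibrium and consistency checks for the inverse dynamics core.

# A stationary standing posture as a fake trial: all q constant, GRF = BW
# under one foot at the ankle.
standing_fixture <- function(model, n = 5) {
  mass <- model$subject$mass
  q <- matrix(0, n, 9, dimnames = list(NULL, GAIT_COORDS))
  Lleg <- model$segments$thigh_r$length + model$segments$shank_r$length
  q[, "pelvis_ty"] <- Lleg + model$geometry$ankle_height
  zero <- matrix(0, n, 9)
  ankle_x <- 0  # straight legs: ankle under the pelvis
  states <- structure(list(time = seq(0, by = 0.01, length.out = n), q = q,
                           qd = zero, qdd = zero, subject = model$subject),
                      class = "state_trajectory")
  trial <- list(time = states$time,
                grf = list(r = cbind(rep(0, n), rep(mass * 9.81, n)),
                           l = cbind(rep(0, n), rep(0, n))),
                cop = list(r = rep(ankle_x, n), l = rep(NA_real_, n)),
                subject = model$subject)
  list(states = states, trial = trial)
}

test_that("static single-leg standing matches the closed form", {
  m <- nw_model()
  fx <- standing_fixture(m)
  loads <- net_joint_loads(fx$states, fx$trial, m)
  bw <- m$subject$mass * 9.81
  w_below_knee <- (m$segments$shank_r$mass + m$segments$foot_r$mass) * 9.81
  # knee net moment ~ 0 (only the small foot COM offset contributes)
  expect_lt(max(abs(loads$moments[, "knee_r"])), 1.0)
  # vertical intersegmental force at the knee = BW - weight(shank+foot)
  expect_equal(loads$interseg_force$knee_r[1, 2], -(bw - w_below_knee),
               tolerance = 1e-9 * bw)
})

test_that("zero gravity, zero motion, zero GRF gives exactly zero loads", {
  m <- nw_model()
  m$gravity <- c(0, 0)
  m <- cache_model(m)
  fx <- standing_fixture(m)
  fx$trial$grf$r[] <- 0
  fx$trial$cop$r[] <- NA_real_
  loads <- net_joint_loads(fx$states, fx$trial, m)
  expect_equal(max(abs(loads$moments)), 0)
  expect_equal(max(abs(loads$residual_force)), 0)
})

test_that("residual report passes on consistent data, fails on scaled GRF", {
  ex <- ref_exact()
  rep0 <- residual_report(ex$loads)
  expect_true(rep0$pass)
  expect_lt(rep0$rms_force_bw, 0.005)

  bad <- ex$trial
  bad$grf$r <- bad$grf$r * 1.2
  bad$grf$l <- bad$grf$l * 1.2
  loads_bad <- net_joint_loads(ex$states, bad, nw_model())
  rep1 <- residual_report(loads_bad)
  expect_false(rep1$pass)
  # residual ~ 20% of the (stance-average ~1 BW) vertical force
  expect_gt(rep1$rms_force_bw, 0.10)
  expect_error(residual_report(list(residual_force = matrix(0, 0, 2))),
               "empty")
})

test_that("loads scale linearly with subject mass (kinematics held fixed)", {
  ex <- ref_exact()
  m <- nw_model()
  a2 <- subject_anthropometry("2X", mass = 2 * 43.1, height = 1.506,
                              group = "normal", walking_speed = 1.22)
  m2 <- cache_model(scale_model(a2))
  trial2 <- ex$trial
  trial2$grf <- lapply(ex$trial$grf, function(g) 2 * g)
  trial2$subject <- a2
  states2 <- ex$states; states2$subject <- a2
  l1 <- net_joint_loads(ex$states, ex$trial, m)
  l2 <- net_joint_loads(states2, trial2, m2)
  expect_equal(l2$moments, 2 * l1$moments, tolerance = 1e-9)
  expect_equal(l2$interseg_force$knee_r, 2 * l1$interseg_force$knee_r,
               tolerance = 1e-9)
})

test_that("forward dynamics inverts inverse dynamics to 1e-6 rad/s^2", {
  ex <- ref_exact()
  m <- nw_model()
  idx <- seq(5, length(ex$states$time) - 5, by = 17)
  for (i in idx) {
    qi <- ex$states$q[i, ]; qdi <- ex$states$qd[i, ]
    tau <- c(ex$loads$residual_force[i, ], ex$loads$residual_moment[i],
             ex$loads$moments[i, ])
    Qgrf <- numeric(9)
    for (side in c("r", "l")) {
      F <- ex$trial$grf[[side]][i, ]
      if (sum(abs(F)) > 0)
        Qgrf <- Qgrf + gaitsim:::ext_force_gen(
          m, paste0("foot_", side), c(ex$trial$cop[[side]][i], 0), F, qi)
    }
    qdd <- forward_dynamics(m, qi, qdi, tau + Qgrf)
    expect_lt(max(abs(qdd - ex$states$qdd[i, ])), 1e-6)
  }
})
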