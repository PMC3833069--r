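test_that("IK recovers the generating angles from noise-free markers", {
  trial <- ref_trial()
  states <- inverse_kinematics(trial, nw_model())
  truth <- attr(trial, "truth")
  ang <- 4:9
  rms <- sqrt(mean((states$q[, ang] - truth$q[, ang])^2))
  expect_lt(rms * 180 / pi, 0.1)
  expect_lt(max(states$rms_error), 1e-8)
  expect_length(states$flagged, 0)
})

test_that("IK is equivariant to rigid translation of the marker cloud", {
  trial <- ref_trial()
  shifted <- trial
  shifted$markers[, , 1] <- shifted$markers[, , 1] + 0.5
  s0 <- inverse_kinematics(trial, nw_model())
  s1 <- inverse_kinematics(shifted, nw_model())
  expect_equal(s1$q[, "pelvis_tx"], s0$q[, "pelvis_tx"] + 0.5,
               tolerance = 1e-8)
  expect_equal(s1$q[, -1], s0$q[, -1], tolerance = 1e-8)
})

test_that("IK error stays bounded under realistic marker noise", {
  a <- nw_subject(); m <- nw_model(); wf <- gait_waveforms()
  errs <- sapply(1:3, function(s) {
    tr <- generate_trial(a, m, wf, seed = 100 + s, noise_sd = 0.002)
    st <- inverse_kinematics(tr, m)
    truth <- attr(tr, "truth")
    c(rms_marker = mean(st$rms_error),
      rms_angle = sqrt(mean((st$q[, 4:9] - truth$q[, 4:9])^2)) * 180 / pi)
  })
  expect_lt(max(errs["rms_marker", ]), 0.004)
  expect_lt(max(errs["rms_angle", ]), 1.5)
})

test_that("smooth_differentiate matches closed forms", {
  t <- seq(0, 2, by = 0.01)
  # pure sinusoid, no filtering: qdd = -(2 pi)^2 sin
  s <- smooth_differentiate(t, cbind(sin(2 * pi * t)), cutoff_hz = Inf)
  inner <- t > 0.1 & t < 1.9
  expect_lt(max(abs(s$qdd[inner] + (2 * pi)^2 * sin(2 * pi * t[inner]))) /
              (2 * pi)^2, 0.005)
  # constant input is exactly flat
  s2 <- smooth_differentiate(t, cbind(rep(3.2, length(t))), cutoff_hz = 6)
  expect_equal(s2$q[, 1], rep(3.2, length(t)), tolerance = 1e-9)
  expect_equal(max(abs(s2$qd)), 0, tolerance = 1e-9)
  expect_equal(max(abs(s2$qdd)), 0, tolerance = 1e-6)
  # noisy sinusoid: filtered acceleration RMS error < 10% of signal RMS
  set.seed(1)
  noisy <- sin(2 * pi * t) + rnorm(length(t), 0, 0.5 * pi / 180)
  s3 <- smooth_differentiate(t, cbind(noisy), cutoff_hz = 6)
  err <- s3$qdd[inner] + (2 * pi)^2 * sin(2 * pi * t[inner])
  expect_lt(sqrt(mean(err^2)) / ((2 * pi)^2 / sqrt(2)), 0.10)
  expect_error(smooth_differentiate(t[1:5], cbind(sin(t[1:5]))), "warm-up")
})

test_that("integration round-trip: integral of qdot reproduces q", {
  trial <- ref_trial()
  states <- differentiate_states(inverse_kinematics(trial, nw_model()),
                                 cutoff_hz = Inf)
  dt <- diff(trial$time[1:2])
  cyc <- which(trial$time >= 0.1 &
                 trial$time <= 0.1 + trial$meta$stride_time)
  for (j in c("hip_r", "knee_r")) {
    q <- states$q[cyc, j]
    qd <- states$qd[cyc, j]
    qdd <- states$qdd[cyc, j]
    # trapezoid with Euler-Maclaurin end correction (O(h^4))
    inc <- (qd[-1] + qd[-length(qd)]) / 2 * dt -
      dt^2 / 12 * (qdd[-1] - qdd[-length(qdd)])
    rebuilt <- q[1] + c(0, cumsum(inc))
    expect_lt(max(abs(rebuilt - q)) / diff(range(q)), 0.001)
  }
})

test_that("event detection finds heel strikes and toe-offs", {
  trial <- ref_trial()
  ev <- detect_events(trial)
  T <- trial$meta$stride_time
  # threshold crossing lags true contact by the force rise time (~1% GC)
  expect_lt(max(abs(ev$hs_r[1:2] - c(0, T))), 0.02)
  # toe-off near 60% of the cycle; the 20 N crossing sits ~1.3% GC early
  # on this generator's cosine weight-transfer tail
  to_pct <- (ev$to_r[1] %% T) / T * 100
  expect_lt(abs(to_pct - 60), 3)
  # threshold sensitivity bounded by the ramp slope
  e10 <- detect_events(trial, threshold = 10)
  e30 <- detect_events(trial, threshold = 30)
  expect_lt(abs(e10$to_r[1] - e30$to_r[1]) / T * 100, 1)
  # constant-zero force: no events
  flat <- trial
  flat$grf$r[] <- 0; flat$grf$l[] <- 0
  expect_error(detect_events(flat), "gait cycle")
})

test_that("time normalization yields 101-point gait-cycle curves", {
  trial <- ref_trial()
  ev <- detect_events(trial)
  norm <- time_normalize(trial$time, trial$grf$r[, 2], ev, side = "r")
  expect_length(norm$pct, 101)
  expect_equal(norm$pct[c(1, 101)], c(0, 100))
  expect_lt(abs(norm$toe_off_pct - 60), 3)
  short <- list(hs_r = 0.1)
  expect_error(time_normalize(trial$time, trial$grf$r[, 2], short), "cycle")
})
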