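test_that("gravity alone in free fall accelerates the COM at exactly g", {
  m <- nw_model()
  ex <- ref_exact()
  i <- 30
  qi <- ex$states$q[i, ]; qdi <- ex$states$qd[i, ]
  # unconstrained (airborne) solve with only the gravity source
  sol <- gaitsim:::constrained_qdd(m, qi, qdi,
                                  gaitsim:::gravity_gen(m, qi), list())
  acc <- as.numeric(gaitsim:::com_jacobian(m, qi) %*% sol$qdd)
  expect_equal(acc, c(0, -9.81), tolerance = 1e-9)
})

test_that("muscle contributions superpose to the measured COM acceleration", {
  ex <- ref_exact()
  m <- nw_model()
  frames <- seq(4, length(ex$states$time) - 4, by = 11)
  ia <- iaa_matrix(ex$states, ex$solution, m, ex$trial, loads = ex$loads,
                   frames = frames)
  for (i in frames) {
    meas <- gaitsim:::com_acceleration(m, ex$states$q[i, ], ex$states$qd[i, ],
                                       ex$states$qdd[i, ])
    expect_lt(max(abs(ia$total[i, ] - meas)), 0.05)
  }
  # zero-force muscle contributes exactly zero
  zero_force <- which(ex$solution$forces[frames[1], ] == 0)
  if (length(zero_force))
    expect_equal(unname(ia$muscle_fy[frames[1], zero_force[1]]), 0)
})

test_that("contributions are linear in muscle force", {
  ex <- ref_exact()
  m <- nw_model()
  i <- 40
  sol2 <- ex$solution
  sol2$forces[i, "soleus_r"] <- 2 * sol2$forces[i, "soleus_r"]
  ia1 <- iaa_matrix(ex$states, ex$solution, m, ex$trial, frames = i)
  ia2 <- iaa_matrix(ex$states, sol2, m, ex$trial, frames = i)
  expect_equal(ia2$muscle_fy[i, "soleus_r"], 2 * ia1$muscle_fy[i, "soleus_r"],
               tolerance = 1e-9)
  expect_equal(ia2$muscle_fy[i, "vasti_r"], ia1$muscle_fy[i, "vasti_r"],
               tolerance = 1e-9)
})

test_that("perturbation method agrees with the matrix method", {
  ex <- ref_exact()
  m <- nw_model()
  frames <- c(20, 45, 70, 120, 160)
  ia <- iaa_matrix(ex$states, ex$solution, m, ex$trial, loads = ex$loads,
                   frames = frames)
  ip <- iaa_perturbation(ex$states, ex$solution, m, ex$trial,
                         loads = ex$loads, dt = 0.01, frames = frames)
  for (i in frames) {
    v1 <- c(ia$muscle_fx[i, ], ia$muscle_fy[i, ])
    v2 <- c(ip$muscle_fx[i, ], ip$muscle_fy[i, ])
    expect_lt(sqrt(mean((v1 - v2)^2)) / sqrt(mean(v1^2)), 0.05)
  }
  # Richardson-style check: halving dt shrinks the disagreement
  ip2 <- iaa_perturbation(ex$states, ex$solution, m, ex$trial,
                          loads = ex$loads, dt = 0.005, frames = frames[2])
  i <- frames[2]
  e1 <- abs(ip$muscle_fy[i, ] - ia$muscle_fy[i, ])
  e2 <- abs(ip2$muscle_fy[i, ] - ia$muscle_fy[i, ])
  expect_lt(sum(e2), sum(e1) + 1e-9)
})

test_that("group sums equal the sum of members and orderings hold", {
  ex <- ref_exact()
  m <- nw_model()
  T <- ex$trial$meta$stride_time
  pct <- (ex$states$time / T * 100) %% 100
  early <- which(pct >= 5 & pct <= 30 & ex$states$time < T)
  late <- which(pct >= 35 & pct <= 58 & ex$states$time < T)
  ia <- iaa_matrix(ex$states, ex$solution, m, ex$trial, loads = ex$loads,
                   frames = c(early, late))
  g <- group_iaa(ia, side = "r")
  expect_equal(g$fy[, "quadriceps"],
               ia$muscle_fy[, "rect_fem_r"] + ia$muscle_fy[, "vasti_r"])
  expect_error(group_iaa(ia, groups = "unknown_group"), "unknown")

  # vasti generate the majority of early-stance support
  ev <- colMeans(g$fy[early, ], na.rm = TRUE)
  expect_equal(names(which.max(ev[!names(ev) %in% "quadriceps"])), "vasti")
  # plantarflexors provide most of the late-stance forward acceleration
  lf <- colMeans(g$fx[late, ], na.rm = TRUE)
  pf <- lf[["gastrocnemius"]] + lf[["soleus"]]
  others <- sum(pmax(lf[setdiff(names(lf), c("gastrocnemius", "soleus",
                                             "quadriceps"))], 0))
  expect_gt(pf, others)
})
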