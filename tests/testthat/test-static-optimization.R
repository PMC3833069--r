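# Toy model with controllable muscles for closed-form and oracle checks.
toy_model <- function(arms, fmax) {
  # arms: list per muscle of named coordinate arms; fmax: vector
  m <- nw_model()
  mus <- lapply(seq_along(fmax), function(i) {
    list(name = paste0("mus", i), base = paste0("mus", i), group = "toy",
         side = "r", f_max = fmax[i], arms = arms[[i]], biarticular = FALSE)
  })
  names(mus) <- vapply(mus, `[[`, "", "name")
  m$muscles <- mus
  m
}

test_that("single muscle, single DOF solves the closed form", {
  m <- toy_model(list(c(knee_r = 0.05)), fmax = 1000)
  net <- stats::setNames(numeric(6), GAIT_COORDS[4:9])
  net["knee_r"] <- 20
  sol <- decompose_frame(net, NULL, m, reserve_weight = 1000)
  expect_equal(unname(sol$activations[1]), 20 / (0.05 * 1000),
               tolerance = 1e-4)
  expect_lt(max(abs(sol$reserves[names(net) != "knee_r"])), 1e-9)
})

test_that("identical parallel muscles share load equally", {
  m <- toy_model(list(c(knee_r = 0.05), c(knee_r = 0.05)), fmax = c(800, 800))
  net <- stats::setNames(numeric(6), GAIT_COORDS[4:9])
  net["knee_r"] <- 30
  sol <- decompose_frame(net, NULL, m)
  expect_equal(sol$activations[[1]], sol$activations[[2]], tolerance = 1e-8)
})

test_that("solution matches a brute-force grid oracle on a 3-muscle toy", {
  # 3 muscles, 2 DOF; oracle = exhaustive search at 1e-3 activation grid
  arms <- list(c(knee_r = 0.04), c(knee_r = 0.03, ankle_r = -0.04),
               c(ankle_r = -0.05))
  fmax <- c(1500, 900, 2000)
  m <- toy_model(arms, fmax)
  net <- stats::setNames(numeric(6), GAIT_COORDS[4:9])
  net["knee_r"] <- 35; net["ankle_r"] <- -55
  sol <- decompose_frame(net, NULL, m, reserve_weight = 1000)

  G <- rbind(c(0.04 * 1500, 0.03 * 900, 0),
             c(0, -0.04 * 900, -0.05 * 2000))
  Mv <- c(35, -55)
  grid <- seq(0, 1, by = 1e-3)
  # coordinate-descent-free exhaustive oracle over a1; inner 2x2 solved on
  # the grid too (full 1e9 grid is infeasible; sweep a1, grid a2, closed a3)
  best <- c(Inf, NA, NA, NA)
  for (a1 in grid) {
    r1 <- Mv[1] - G[1, 1] * a1
    a2 <- pmin(pmax(seq(0, 1, by = 1e-3), 0), 1)
    r_k <- r1 - G[1, 2] * a2
    # inner minimization over a3 is an exact 1-D quadratic with clamping
    a3 <- 1000 * G[2, 3] * (Mv[2] - G[2, 2] * a2) / (1 + 1000 * G[2, 3]^2)
    a3c <- pmin(pmax(a3, 0), 1)
    r_a <- Mv[2] - G[2, 2] * a2 - G[2, 3] * a3c
    obj <- a1^2 + a2^2 + a3c^2 + 1000 * (r_k^2 + r_a^2)
    i <- which.min(obj)
    if (obj[i] < best[1]) best <- c(obj[i], a1, a2[i], a3c[i])
  }
  expect_equal(unname(sol$activations), best[2:4], tolerance = 5e-3)
  expect_equal(sol$objective, best[1], tolerance = 5e-3)
  # the QP solution must be at least as good as the grid oracle's
  expect_lte(sol$objective, best[1] + 1e-6)
})

test_that("moment reconstruction is exact and trial-level properties hold", {
  ex <- ref_exact()
  m <- nw_model()
  A <- gaitsim:::arm_matrix(m)
  fmax <- vapply(m$muscles, `[[`, 0, "f_max")
  G <- A * rep(fmax, each = 6)
  for (i in seq(1, nrow(ex$solution$forces), by = 25)) {
    rebuilt <- as.numeric(G %*% ex$solution$activations[i, ]) +
      ex$solution$reserves[i, ]
    expect_equal(unname(rebuilt), unname(ex$loads$moments[i, ]),
                 tolerance = 1e-6)
  }
  # activations within bounds, reserves negligible with default sizing
  expect_true(all(ex$solution$activations >= 0 &
                    ex$solution$activations <= 1))
  peak_m <- max(abs(ex$loads$moments))
  expect_lt(max(abs(ex$solution$reserves)), 0.001 * peak_m)
})

test_that("zero net moments give the zero solution", {
  m <- nw_model()
  net <- stats::setNames(numeric(6), GAIT_COORDS[4:9])
  sol <- decompose_frame(net, NULL, m)
  expect_equal(max(abs(sol$activations)), 0, tolerance = 1e-10)
  expect_equal(sol$objective, 0, tolerance = 1e-12)
})

test_that("doubling f_max halves activations and leaves forces unchanged", {
  m <- nw_model()
  net <- stats::setNames(c(-30, -25, -40, 10, 5, 8), GAIT_COORDS[4:9])
  s1 <- decompose_frame(net, NULL, m)
  m2 <- m
  for (i in seq_along(m2$muscles)) m2$muscles[[i]]$f_max <-
      2 * m2$muscles[[i]]$f_max
  s2 <- decompose_frame(net, NULL, m2)
  expect_equal(s2$activations, s1$activations / 2, tolerance = 1e-5)
  expect_equal(s2$forces, s1$forces, tolerance = 1e-3)
  # objective never increases when strength increases
  expect_lte(s2$objective, s1$objective + 1e-9)
})

test_that("grouping sums the conventional muscle lists", {
  ex <- ref_exact()
  g <- group_forces(ex$solution, side = "r",
                    groups = c("quadriceps", "hamstrings", "gastrocnemius"))
  expect_equal(g[, "quadriceps"],
               ex$solution$forces[, "rect_fem_r"] +
                 ex$solution$forces[, "vasti_r"])
  expect_equal(g[, "gastrocnemius"], ex$solution$forces[, "gastroc_r"])
  expect_error(group_forces(ex$solution, groups = "sartorius"), "unknown")
})
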