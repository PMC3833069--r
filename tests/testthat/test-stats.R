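test_that("t-test matches closed-form and stats::t.test oracle", {
  # hand-checkable pair: {1,2,3} vs {3,4,5} -> t = -2.449, p = 0.070, df 4
  r <- independent_t_test(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r$t, -2.449, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.0705, tolerance = 1e-3)
  # independent oracle
  o <- stats::t.test(c(1, 2, 3), c(3, 4, 5), var.equal = TRUE)
  expect_equal(r$t, unname(o$statistic), tolerance = 1e-12)
  expect_equal(r$p, o$p.value, tolerance = 1e-12)
  # Welch variant against the oracle
  set.seed(4)
  x <- rnorm(9); y <- rnorm(14, 1, 2)
  rw <- independent_t_test(x, y, var_equal = FALSE)
  ow <- stats::t.test(x, y)
  expect_equal(rw$p, ow$p.value, tolerance = 1e-12)
  expect_equal(rw$df, unname(ow$parameter), tolerance = 1e-9)
})

test_that("printed group-height summaries reproduce the reported p-value", {
  # stature 155.4 +/- 4.9 vs 150.6 +/- 6.0 cm, n = 8 per group -> p ~ 0.103
  r <- t_test_summary(155.4, 4.9, 8, 150.6, 6.0, 8)
  # rounded printed summaries reproduce the reported p to ~1e-3
  expect_lt(abs(r$p - 0.103), 0.005)
  expect_equal(r$df, 14)
})

test_that("degenerate t-test inputs are handled", {
  expect_equal(independent_t_test(c(2, 2), c(2, 2))$p, 1)
  d <- independent_t_test(c(2, 2), c(3, 3))
  expect_equal(d$p, 0)
  expect_true(d$degenerate)
  expect_error(t_test_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("speed-load regression recovers exact and noisy lines", {
  v <- seq(0.9, 1.4, length.out = 12)
  f <- 3.585 * v - 1.975
  r <- speed_load_regression(v, f)
  expect_equal(r$slope, 3.585, tolerance = 1e-10)
  expect_equal(r$intercept, -1.975, tolerance = 1e-10)
  expect_equal(r$r_squared, 1)
  # two points: R^2 = 1 and flagged underdetermined
  r2 <- speed_load_regression(v[1:2], f[1:2])
  expect_equal(r2$r_squared, 1)
  expect_true(r2$underdetermined)
  expect_error(speed_load_regression(rep(1.1, 5), f[1:5]), "degenerate")
  # noise sized for R^2 ~ 0.6 at n = 16: slope lands within its CI
  set.seed(9)
  reps <- replicate(20, {
    vv <- rnorm(16, 1.16, 0.09)
    ff <- 3.585 * vv - 1.975 + rnorm(16, 0, 0.26)
    fit <- speed_load_regression(vv, ff)
    se <- sqrt(sum((ff - fit$intercept - fit$slope * vv)^2) / 14 /
                 sum((vv - mean(vv))^2))
    c(r2 = fit$r_squared, covered = abs(fit$slope - 3.585) < 2.145 * se)
  })
  expect_gt(mean(reps["r2", ]), 0.4)
  expect_lt(mean(reps["r2", ]), 0.8)
  expect_gt(mean(reps["covered", ]), 0.85)
})

test_that("cohort summaries aggregate per-subject peaks", {
  fake <- function(id, group, mass, speed, ctf, q, h, g) {
    list(anthro = subject_anthropometry(id, mass, 1.5, 10, group, speed),
         peak_ctf_bw = ctf, peak_pct_gc = 12,
         peak_forces_bw = c(quadriceps = q, hamstrings = h,
                            gastrocnemius = g))
  }
  one <- summarize_cohort(list(fake("a", "normal", 40, 1.2, 2.5, 1.5, .6, .6)))
  expect_equal(unname(one$sds["peak_ctf_bw"]), 0)
  two <- summarize_cohort(list(
    fake("a", "normal", 40, 1.2, 2.4, 1.5, .6, .55),
    fake("b", "normal", 45, 1.3, 2.6, 1.6, .7, .65)))
  expect_equal(unname(two$means["peak_ctf_bw"]), 2.5)
  expect_equal(unname(two$sds["peak_ctf_bw"]), stats::sd(c(2.4, 2.6)))
  broken <- list(fake("a", "normal", 40, 1.2, NA, 1, 1, 1))
  expect_error(summarize_cohort(broken), "missing pipeline output")

  ob <- summarize_cohort(list(
    fake("o1", "obese", 70, 1.1, 1.8, 1.0, .45, .35),
    fake("o2", "obese", 80, 1.1, 1.9, 1.1, .5, .4)))
  tab <- compare_cohorts(ob, two)
  expect_equal(tab$measure, c("CTF", "Hamstring", "Quadriceps",
                              "Gastrocnemius"))
  expect_equal(tab$normal_mean[tab$measure == "CTF"], 2.5)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
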