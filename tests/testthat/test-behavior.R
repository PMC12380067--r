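circle_traj <- function(n = 400, r = 100, jitter = 0, seed = 1) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n)
  data.frame(t = seq_len(n) / 30,
             x = r * cos(th) + jitter * r * stats::rnorm(n),
             y = r * sin(th) + jitter * r * stats::rnorm(n))
}

test_that("heading series is unwrapped and holds through pauses", {
  line <- data.frame(t = 1:50 / 10, x = seq(0, 98, by = 2), y = 0)
  expect_equal(heading_series(line), rep(0, 50))
  # a full counterclockwise circle accumulates +360 exactly
  circ <- circle_traj()
  h <- heading_series(circ, min_step = 0.1)
  expect_equal(h[length(h)] - h[1], 360, tolerance = 1)
  # noisy circle (1% of radius) stays within a few degrees of +360 when the
  # per-step arc comfortably exceeds the jitter scale
  circ_n <- circle_traj(n = 100, jitter = 0.01, seed = 4)
  hn <- heading_series(circ_n, min_step = 0.1)
  expect_lt(abs((hn[length(hn)] - hn[1]) - 360), 5)
  expect_error(heading_series(line[1, ]), "2 trajectory points")
  bad <- line; bad$t[2] <- bad$t[1]
  expect_error(heading_series(bad), "strictly increasing")
})

test_that("angular displacement is signed, reflective and rotation invariant", {
  tr <- synth_trajectory(trajectory_spec("L", turn_rate = 25, jitter = 0,
                                         seed = 2))
  ph <- attr(tr, "phases")
  a <- angular_displacement(tr, ph$during)
  expect_lt(abs(a - 250), 1.5)
  # mirroring about the x axis flips the sign exactly
  mir <- tr; mir$y <- -mir$y
  expect_equal(angular_displacement(mir, ph$during), -a, tolerance = 1e-9)
  # rigid rotation changes nothing
  th <- 0.83
  rot <- tr
  rot$x <- cos(th) * tr$x - sin(th) * tr$y
  rot$y <- sin(th) * tr$x + cos(th) * tr$y
  expect_equal(angular_displacement(rot, ph$during), a, tolerance = 1e-9)
  expect_equal(linear_displacement(rot, ph$during),
               linear_displacement(tr, ph$during), tolerance = 1e-9)
  # stationary trajectory turns by zero
  still <- data.frame(t = 1:60 / 30, x = rep(0, 60), y = rep(0, 60))
  expect_equal(angular_displacement(still, c(0, 2)), 0)
  expect_error(angular_displacement(tr, c(100, 200)), "window")
})

test_that("linear displacement is path length, not net displacement", {
  line <- data.frame(t = 1:51 / 10, x = seq(0, 100, by = 2), y = 0)
  expect_equal(linear_displacement(line, c(0, 6)), 100)
  # out and back covers the path twice
  outback <- data.frame(t = 1:51 / 10,
                        x = c(seq(0, 50, by = 2), seq(48, 0, by = -2)), y = 0)
  expect_equal(linear_displacement(outback, c(0, 6)), 100)
  # circle circumference 2*pi*r per lap
  circ <- circle_traj(n = 1000)
  expect_equal(linear_displacement(circ, c(0, 40)), 2 * pi * 100,
               tolerance = 0.1)
  # path length always >= straight-line distance (superadditivity)
  tr <- synth_trajectory(trajectory_spec("L", seed = 6))
  ph <- attr(tr, "phases")
  idx <- tr$t >= ph$during[1] & tr$t <= ph$during[2]
  net <- sqrt(diff(range(tr$x[idx]))^2 + diff(range(tr$y[idx]))^2)
  expect_gte(linear_displacement(tr, ph$during), net)
})

test_that("max angular change takes the peak excursion per phase", {
  # heading ramps to +30 then returns to +5 within one phase
  n <- 90
  dth <- c(rep(0, 30), rep(2, 15), rep(-25 / 15, 15), rep(0, 30)) * pi / 180
  heading <- cumsum(dth)
  step <- 2
  tr <- data.frame(t = seq_len(n) / 30,
                   x = cumsum(step * cos(heading)),
                   y = cumsum(step * sin(heading)))
  ph <- phase_windows(c(0, 1), c(1, 2), c(2, 3))
  peak <- max_angular_change(tr, ph)
  expect_equal(unname(peak["during"]), 30, tolerance = 2)
  ep <- max_angular_change(tr, ph, endpoint = TRUE)
  expect_lt(unname(ep["during"]), 10)
  # monotone turning puts the peak at the endpoint
  trL <- synth_trajectory(trajectory_spec("L", jitter = 0, seed = 3))
  phL <- attr(trL, "phases")
  expect_equal(unname(max_angular_change(trL, phL)["during"]),
               unname(max_angular_change(trL, phL, endpoint = TRUE)["during"]))
  # all-stationary phases report zero everywhere
  still <- data.frame(t = 1:90 / 30, x = rep(0, 90), y = rep(0, 90))
  expect_equal(unname(max_angular_change(still, ph)), c(0, 0, 0))
})

test_that("valid turns require strictly more than 20 degrees", {
  expect_equal(classify_turn(25), "L")
  expect_equal(classify_turn(-25), "R")
  expect_equal(classify_turn(-19), "X")
  expect_equal(classify_turn(20), "X")       # boundary is strict
  expect_equal(classify_turn(-20), "X")
  expect_equal(classify_turn(c(21, -21, 0)), c("L", "R", "X"))
  expect_error(classify_turn(NaN), "finite")
})

test_that("behavior confusion registers the XX no-response pattern", {
  cmds <- target_table()$command
  true <- rep(cmds, each = 10)
  cm <- behavior_confusion(true, true)
  expect_equal(accuracy(cm), 1)
  expect_equal(dim(cm), c(8L, 9L))
  # 76 of 80 matched: the turning-control accuracy anchor
  obs <- true; obs[c(1, 21, 41, 61)] <- "XX"
  cm2 <- behavior_confusion(true, obs)
  expect_equal(accuracy(cm2), 0.95)
  # all XX scores zero
  cm3 <- behavior_confusion(true, rep("XX", 80))
  expect_equal(accuracy(cm3), 0)
  expect_equal(sum(cm3[, "XX"]), 80L)
  expect_error(behavior_confusion(true, c(rep("LL", 79), "QQ")), "outside")
})

test_that("phase comparisons use a two-tailed unpaired t-test with stars", {
  # identical groups: p = 1, not significant
  same <- compare_phases(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")
  # 5-sigma separation at n = 20 is overwhelmingly significant
  set.seed(9)
  strong <- compare_phases(stats::rnorm(20), stats::rnorm(20, 5))
  expect_lte(strong$p_value, 1e-4)
  expect_equal(strong$stars, "****")
  # star thresholds follow the printed map (p ~ 0.03 -> "*")
  a <- c(0.1, 1.1, 2.3, 0.9, 1.8, 0.4)
  b <- a + 1.3
  mid <- compare_phases(a, b)
  expect_gt(mid$p_value, 0.01)
  expect_lte(mid$p_value, 0.05)
  expect_equal(mid$stars, "*")
  # matches the classic pooled-variance t-test
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(mid$p_value, ref$p.value)
  expect_equal(mid$t_statistic, unname(ref$statistic))
  # Welch variant on request
  expect_equal(compare_phases(a, b, welch = TRUE)$p_value,
               stats::t.test(a, b)$p.value)
  # degenerate zero-variance case flagged with p = 1 by convention
  dg <- compare_phases(c(2, 2, 2), c(2, 2, 2))
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
  expect_error(compare_phases(1, c(1, 2)), "n >= 2")
})
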