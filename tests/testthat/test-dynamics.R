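test_that("min-max scaling maps to 0-10 and orientation controls inversion", {
  tt <- c(500, 600, 700)
  up <- scale_and_orient(tt, c(0.2, 0.35, 0.5), "greenness_positive")
  expect_equal(up$v, c(0, 5, 10))
  down <- scale_and_orient(tt, c(0.2, 0.35, 0.5), "senescence_positive")
  expect_equal(down$v, c(10, 5, 0))
  expect_true(down$inverted)
  expect_error(scale_and_orient(tt, c(0.3, 0.3, 0.3), "greenness_positive"),
               "degenerate")
})

test_that("scaling an already min-max 0-10 series is the identity", {
  tt <- seq(400, 900, by = 50)
  v <- c(10, 9.5, 9, 8, 6, 4, 2, 1, 0.5, 0, 0.2)
  # ensure 0 and 10 are attained
  sc <- scale_and_orient(tt, v, "greenness_positive")
  expect_equal(sc$v, v)
})

test_that("orientation inference follows the pooled trend and flags ambiguity", {
  t <- seq_len(20)
  expect_equal(infer_orientation(t * 0.01, t), "senescence_positive")
  expect_equal(infer_orientation(1 - t * 0.01, t), "greenness_positive")
  set.seed(41)
  expect_error(infer_orientation(rnorm(50), seq_len(50)), "ambiguous")
  expect_error(infer_orientation(1:5, 1:5), "at least 10")
})

test_that("the linear fit interpolates exactly and refuses extrapolation", {
  course <- time_course(c(600, 660, 720), c(9, 6, 1))
  fit <- fit_linear(course)
  expect_equal(predict_course(fit, 660), 6)
  expect_equal(predict_course(fit, 620), 8.0)
  expect_error(predict_course(fit, 500), "outside")
})

test_that("the Gompertz fit recovers noise-free parameters and its closed form", {
  t <- seq(400, 900, by = 10)
  course <- time_course(t, gompertz_greenness(t, -0.02, 700))
  fit <- fit_gompertz(course, n_starts = 50, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$b - (-0.02)), 1e-4)
  expect_lt(abs(fit$M - 700), 0.1)
  # at t = M the curve value is 10 / e
  expect_equal(predict_course(fit, fit$M), 10 / exp(1), tolerance = 1e-6)
  expect_error(fit_gompertz(time_course(c(1, 2, 3), c(10, 5, 0))),
               "at least 4")
})

test_that("rising senescence-degree courses fit with positive rate", {
  t <- seq(400, 900, by = 20)
  v <- 10 - gompertz_greenness(t, -0.025, 650)
  fit <- fit_gompertz(time_course(t, v), n_starts = 50, seed = 2)
  expect_true(fit$converged)
  expect_gt(fit$b, 0)
})

test_that("threshold extraction matches the closed-form inversion", {
  t <- seq(400, 900, by = 10)
  course <- time_course(t, gompertz_greenness(t, -0.02, 700))
  pars <- extract_parameters(fit_gompertz(course, 50, seed = 3))
  expect_equal(pars$on_sen_Cd, 625.00, tolerance = 0.01)
  expect_equal(pars$mid_sen_Cd, 681.67, tolerance = 0.01)
  expect_equal(pars$end_sen_Cd, 723.79, tolerance = 0.01)
  expect_equal(pars$t_sen_Cd, 98.79, tolerance = 0.01)
  expect_equal(pars$status, "ok")
})

test_that("linear threshold extraction finds the first downward crossing", {
  course <- time_course(c(600, 660, 720), c(9, 6, 1))
  pars <- extract_parameters(fit_linear(course))
  expect_equal(pars$on_sen_Cd, 620.0)
  # later re-rises are ignored: first crossing counts
  wob <- time_course(c(600, 660, 700, 740, 800), c(9, 7.5, 8.5, 6, 1))
  pars2 <- extract_parameters(fit_linear(wob))
  expect_equal(pars2$on_sen_Cd, 600 + 60 * (9 - 8) / (9 - 7.5))
})

test_that("parameters are ordered and translation-equivariant", {
  t <- seq(300, 1000, by = 25)
  course <- time_course(t, gompertz_greenness(t, -0.015, 640))
  p <- extract_parameters(fit_linear(course))
  expect_true(p$on_sen_Cd <= p$mid_sen_Cd)
  expect_true(p$mid_sen_Cd <= p$end_sen_Cd)
  expect_equal(p$t_sen_Cd, p$end_sen_Cd - p$on_sen_Cd)
  # shifting thermal time by delta shifts On/Mid/End and leaves T_sen alone
  delta <- 123.4
  p2 <- extract_parameters(fit_linear(time_course(t + delta, course$v)))
  expect_equal(p2$on_sen_Cd, p$on_sen_Cd + delta)
  expect_equal(p2$end_sen_Cd, p$end_sen_Cd + delta)
  expect_equal(p2$t_sen_Cd, p$t_sen_Cd)
})

test_that("unreached thresholds leave parameters missing with explicit status", {
  flat <- time_course(c(300, 400, 500), c(10, 9.8, 9.5))
  p <- extract_parameters(fit_linear(flat))
  expect_true(is.na(p$on_sen_Cd))
  expect_match(p$status, "threshold_not_reached")
  # partially reached: onset crossed, end never reached
  part <- time_course(c(300, 400, 500), c(10, 6, 5.5))
  p2 <- extract_parameters(fit_linear(part))
  expect_false(is.na(p2$on_sen_Cd))
  expect_true(is.na(p2$end_sen_Cd))
  expect_true(is.na(p2$t_sen_Cd))
})

test_that("linear parameters converge to closed form on dense noise-free courses", {
  t <- seq(400, 900, by = 10)
  course <- time_course(t, gompertz_greenness(t, -0.02, 700))
  p <- extract_parameters(fit_linear(course))
  truth <- closed_form_truth(-0.02, 700)
  expect_lt(abs(p$on_sen_Cd - truth$on_sen_Cd), 2)
  expect_lt(abs(p$mid_sen_Cd - truth$mid_sen_Cd), 2)
  expect_lt(abs(p$end_sen_Cd - truth$end_sen_Cd), 2)
  expect_lt(abs(p$t_sen_Cd - truth$t_sen_Cd), 2)
})

test_that("curve error is the exact area between piecewise-linear courses", {
  A <- time_course(seq(600, 900, by = 50), seq(10, 4, length.out = 7))
  expect_equal(curve_error(A, A), 0)
  # constant unit offset over a 300 degC-day overlap
  B <- A
  B$v <- pmin(10, A$v + 1)
  B$v <- A$v + 1  # allow >10 internally: curve_error works on raw t/v lists
  expect_equal(curve_error(A, B), 300)
  # diverging lines: A 10->0, B 10->5 over [600, 900]
  A2 <- list(t = c(600, 900), v = c(10, 0))
  B2 <- list(t = c(600, 900), v = c(10, 5))
  expect_equal(curve_error(A2, B2), 750)
  # symmetry and crossing curves handled via intersection points
  C1 <- list(t = c(0, 10), v = c(0, 10))
  C2 <- list(t = c(0, 10), v = c(10, 0))
  expect_equal(curve_error(C1, C2), curve_error(C2, C1))
  expect_equal(curve_error(C1, C2), 2 * (0.5 * 5 * 5 * 2) / 1)  # two triangles: 50
  expect_error(curve_error(list(t = c(0, 1), v = c(0, 1)),
                           list(t = c(5, 6), v = c(0, 1))), "overlap")
})
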