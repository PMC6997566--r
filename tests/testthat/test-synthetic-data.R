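test_that("endmembers carry the documented spectral contrasts", {
  em <- make_endmembers()
  at <- function(v, wl) v[match(wl, em$grid)]
  # red edge: green reflectance at 678 below the NIR plateau at 800
  expect_lt(at(em$green, 678), at(em$green, 800))
  # pigment loss: senescent VIS at 678 above green
  expect_gt(at(em$senescent, 678), at(em$green, 678))
  # PSRI of the green endmember below that of the senescent endmember
  g <- spectrum(em$grid, em$green)
  s <- spectrum(em$grid, em$senescent)
  expect_lt(compute_index(g, "PSRI"), compute_index(s, "PSRI"))
  # sign structure windows
  d <- em$green - em$senescent
  expect_true(all(d[em$grid >= 450 & em$grid <= 680] < 0))
  expect_true(all(d[em$grid >= 2000 & em$grid <= 2400] < 0))
  expect_true(all(d[em$grid >= 760 & em$grid <= 1300] > 0))
})

test_that("temperature simulation honours mean curve, seed and GDD arithmetic", {
  # zero amplitude, zero noise: daily midpoints equal the mean curve
  temps <- simulate_temperatures("2016-06-01", "2016-06-30", mean_curve = 18,
                                 diurnal_amplitude = 0, noise_sd = 0,
                                 max_min_spread = 0)
  expect_equal(unique((temps$t_max + temps$t_min) / 2), 18)
  # constant 18 degC over 30 days: 29 accumulating days after reference
  cal <- accumulate_gdd(temps)
  expect_equal(max(cal$days$cumulative_gdd), 29 * 18)
  # thermal time over the full month from the first day
  expect_equal(thermal_time_after_heading(cal, "2016-06-01", "2016-06-30"),
               522)
  # fixed seed reproduces the series exactly
  a <- simulate_temperatures("2016-06-01", "2016-06-10", 18, 5, 1.5, seed = 4)
  b <- simulate_temperatures("2016-06-01", "2016-06-10", 18, 5, 1.5, seed = 4)
  expect_identical(a, b)
})

test_that("closed-form truth inverts the Gompertz thresholds", {
  truth <- closed_form_truth(-0.02, 700)
  expect_equal(truth$on_sen_Cd, 625.00, tolerance = 0.005)
  expect_equal(truth$mid_sen_Cd, 681.67, tolerance = 0.005)
  expect_equal(truth$end_sen_Cd, 723.79, tolerance = 0.005)
  expect_equal(truth$t_sen_Cd, 98.79, tolerance = 0.005)
  # mid - M = log(-log(0.5)) / (-b) = 0.36651 / b: same sign as b
  # (decaying greenness, b < 0, crosses the midpoint before M)
  for (b in c(-0.03, -0.01, 0.02)) {
    tr <- closed_form_truth(b, 500)
    expect_equal(sign(tr$mid_sen_Cd - 500), sign(b))
    expect_equal(tr$mid_sen_Cd - 500, 0.3665129 / b, tolerance = 1e-6)
  }
  # duration does not depend on M
  t1 <- closed_form_truth(-0.02, 600)
  t2 <- closed_form_truth(-0.02, 800)
  expect_equal(t1$t_sen_Cd, t2$t_sen_Cd)
  expect_true(all(closed_form_truth(-0.015, 700)$on_sen_Cd <=
                    closed_form_truth(-0.015, 700)$mid_sen_Cd))
})

test_that("noise-free scorings are exactly the rounded greenness", {
  cfg <- simulation_config(n_genotypes = 6L, n_replicates = 1L,
                           scoring_noise_sd = 0, spectral_noise_sd = 0,
                           band_noise_sd = 0, confound_amplitude = 0,
                           temp_noise_sd = 0, seed = 5)
  tr <- simulate_trial(cfg)
  sc <- merge(tr$scorings, tr$truth[, .(plot_id, b_true, M_true,
                                        heading_date)], by = "plot_id")
  sc[, heading_date := as.Date(heading_date)]
  tt <- vapply(seq_len(nrow(sc)), function(i) {
    thermal_time_after_heading(tr$calendar, sc$heading_date[i], sc$date[i])
  }, numeric(1))
  g <- exp(-exp(-sc$b_true * (tt - sc$M_true)))
  expect_equal(sc$score, round(10 * g))
})

test_that("with all noise off, a fully green plot shows the green endmember", {
  cfg <- simulation_config(n_genotypes = 4L, n_replicates = 1L,
                           m_mean = 820, m_sd = 0, m_bounds = c(819, 881),
                           replicate_m_sd = 0, b_mean = 0.03, b_sd = 0,
                           scoring_noise_sd = 0, spectral_noise_sd = 0,
                           band_noise_sd = 0, confound_amplitude = 0,
                           temp_noise_sd = 0, heading_spread_days = 0,
                           seed = 6)
  tr <- simulate_trial(cfg)
  em <- make_endmembers(tr$spectra$wavelength)
  # earliest spectral date: far from M = 820, canopy still fully green
  first_date <- min(tr$spectra$meta$date)
  row <- which(tr$spectra$meta$date == first_date)[1]
  expect_equal(tr$spectra$reflectance[row, ], em$green, tolerance = 1e-3)
})

test_that("the trait generator hits the requested correlation", {
  # rho = 1 gives zero residual and sample correlation 1
  cfg1 <- simulation_config(n_genotypes = 20L, n_replicates = 1L,
                            rho_gy_onset = 0.999, seed = 7)
  tr1 <- simulate_trial(cfg1)
  expect_gt(cor(tr1$truth$GY_t_ha, tr1$truth$on_sen_Cd), 0.99)
  # default config: sample correlation within sampling error of 0.37
  tr <- simulate_trial(simulation_config(seed = 8))
  r <- cor(tr$truth$GY_t_ha, tr$truth$on_sen_Cd)
  expect_gt(r, 0.37 - 0.10)
  expect_lt(r, 0.37 + 0.10)
  # protein correlates negatively with duration as configured
  expect_lt(cor(tr$truth$GPC_pct, tr$truth$t_sen_Cd), -0.1)
})

test_that("degenerate scoring windows are rejected", {
  expect_error(simulate_trial(simulation_config(scoring_start_Cd = 300,
                                                scoring_end_Cd = 310,
                                                seed = 9)),
               "degenerate")
})

test_that("a trial writes byte-identical files under a fixed seed", {
  cfg <- simulation_config(n_genotypes = 5L, n_replicates = 2L, seed = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_trial(simulate_trial(cfg), d1)
  write_trial(simulate_trial(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # truth satisfies the ordering invariant
  tr <- simulate_trial(cfg)
  expect_true(all(tr$truth$on_sen_Cd <= tr$truth$mid_sen_Cd))
  expect_true(all(tr$truth$mid_sen_Cd <= tr$truth$end_sen_Cd))
})
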