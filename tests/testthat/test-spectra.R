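test_that("long and wide spectra files parse and round-trip", {
  # long: 3 rows, one plot/date
  long <- data.table::data.table(
    plot_id = "p1", date = "2016-06-15",
    wavelength_nm = c(500, 600, 700), reflectance = c(0.1, 0.2, 0.3)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(long, path)
  col <- read_spectra(path, layout = "long")
  expect_equal(n_spectra(col), 1L)
  expect_equal(length(col$wavelength), 3L)
  expect_equal(col$reflectance[1, ], c(0.1, 0.2, 0.3))

  # wide: full 2151-band grid, 2 rows
  grid <- 350:2500
  wide <- cbind(
    data.table::data.table(plot_id = c("p1", "p2"), date = "2016-06-15"),
    data.table::as.data.table(matrix(runif(2 * length(grid), 0.05, 0.5),
                                     nrow = 2,
                                     dimnames = list(NULL, paste0("W", grid))))
  )
  path2 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(wide, path2)
  col2 <- read_spectra(path2, layout = "wide")
  expect_equal(n_spectra(col2), 2L)
  expect_equal(length(col2$wavelength), 2151L)

  # writer re-emits the same dialect
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(col2, path3, layout = "wide")
  col3 <- read_spectra(path3, layout = "wide")
  expect_equal(col3$reflectance, col2$reflectance)
  path4 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(col, path4, layout = "long")
  expect_equal(read_spectra(path4, layout = "long")$reflectance,
               col$reflectance)
})

test_that("duplicate (plot, date, wavelength) rows are rejected", {
  long <- data.table::data.table(
    plot_id = "p1", date = "2016-06-15",
    wavelength_nm = c(500, 500, 700), reflectance = c(0.1, 0.2, 0.3)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(long, path)
  expect_error(read_spectra(path, layout = "long"), "duplicated")
})

test_that("replicate averaging is the per-wavelength mean and idempotent", {
  wl <- c(500, 600, 700)
  same_meta <- list(plot_ids = rep("p1", 5), dates = rep(as.Date("2016-06-15"), 5))
  # 5 spectra with constant values k/10
  col5 <- tiny_collection(wl, matrix(rep(1:5 / 10, each = 3), nrow = 5,
                                     byrow = TRUE),
                          plot_ids = same_meta$plot_ids, dates = same_meta$dates)
  avg <- average_replicates(col5)
  expect_equal(n_spectra(avg), 1L)
  expect_equal(avg$reflectance[1, ], rep(0.3, 3))
  # two identical spectra average to themselves
  col2 <- tiny_collection(wl, rbind(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4)),
                          plot_ids = c("p1", "p1"),
                          dates = rep(as.Date("2016-06-15"), 2))
  expect_equal(average_replicates(col2)$reflectance[1, ], c(0.2, 0.3, 0.4))
  # averaging is idempotent
  expect_equal(average_replicates(avg)$reflectance, avg$reflectance)
})

test_that("averaging commutes with window trimming", {
  grid <- 350:2500
  set.seed(11)
  vals <- matrix(runif(4 * length(grid), 0.05, 0.6), nrow = 4)
  col <- tiny_collection(grid, vals, plot_ids = c("p1", "p1", "p2", "p2"),
                         dates = rep(as.Date("2016-06-15"), 4))
  a <- trim_to_windows(average_replicates(col))
  b <- average_replicates(trim_to_windows(col))
  expect_equal(a$wavelength, b$wavelength)
  expect_equal(a$reflectance, b$reflectance)
})

test_that("default windows keep 1668 of the 2151 one-nm bands", {
  grid <- 350:2500
  s <- spectrum(grid, runif(length(grid), 0.05, 0.6))
  trimmed <- trim_to_windows(s)
  expect_equal(length(trimmed$wavelength), 951 + 307 + 410)
  # the full-range window is the identity
  full <- trim_to_windows(s, list(c(350, 2500)))
  expect_equal(full$reflectance, s$reflectance)
  expect_error(trim_to_windows(s, list(c(3000, 3100))), "no wavelengths")
})

test_that("grid resampling interpolates linearly without extrapolation", {
  s <- spectrum(c(500, 502), c(0.2, 0.4))
  expect_equal(resample_to_grid(s, grid = 501)$reflectance, 0.3)
  s2 <- spectrum(c(500, 504), c(0.2, 0.4))
  expect_equal(resample_to_grid(s2, grid = 501)$reflectance, 0.25)
  # identity on an existing 1-nm grid
  s3 <- spectrum(500:510, seq(0.2, 0.4, length.out = 11))
  expect_equal(resample_to_grid(s3, step_nm = 1)$reflectance, s3$reflectance)
  expect_error(resample_to_grid(s3, grid = c(499, 500)), "extrapolation")
  # exact on piecewise-linear input whose knots lie on the target grid
  s4 <- spectrum(c(500, 505, 510), c(0.1, 0.6, 0.2))
  rs <- resample_to_grid(s4, step_nm = 1)
  expect_equal(rs$reflectance[c(1, 6, 11)], c(0.1, 0.6, 0.2))
})

test_that("first derivative uses centered differences with one-sided ends", {
  # linear spectrum of slope 0.001 per nm
  s <- spectrum(400:500, 0.1 + 0.001 * (0:100))
  d <- first_derivative(s)
  expect_equal(d$reflectance, rep(0.001, 101))
  # constant spectrum
  expect_equal(first_derivative(spectrum(400:500, rep(0.3, 101)))$reflectance,
               rep(0, 101))
  # interior point: (0.4 - 0.1) / 2
  d3 <- first_derivative(spectrum(500:502, c(0.1, 0.2, 0.4)))
  expect_equal(d3$reflectance[2], 0.15)
  expect_error(first_derivative(spectrum(c(500, 501), c(0.1, 0.2))),
               "at least 3")
})

test_that("continuum removal divides by the upper convex hull", {
  cr <- continuum_removal(spectrum(c(400, 500, 600), c(0.5, 0.2, 0.5)))
  expect_equal(cr$reflectance, c(1, 0.4, 1))
  # a straight line is its own hull
  lin <- spectrum(400:450, seq(0.2, 0.45, length.out = 51))
  expect_equal(continuum_removal(lin)$reflectance, rep(1, 51))
  # endpoints are hull vertices, output never exceeds 1
  set.seed(21)
  s <- spectrum(400:600, runif(201, 0.1, 0.6))
  out <- continuum_removal(s)$reflectance
  expect_true(all(out <= 1 + 1e-12))
  expect_true(all(out > 0))
  expect_equal(out[c(1, 201)], c(1, 1))
  expect_error(continuum_removal(spectrum(400:402, c(0.1, 0, 0.2))), "positive")
})

test_that("standardization centers and scales with the sample sd", {
  m <- cbind(a = c(1, 3), b = c(2, 4))
  st <- standardize_columns(m)
  expect_equal(unname(st$values[, 1]), c(-1, 1) / sqrt(2))
  expect_equal(unname(st$center), c(2, 3))
  # idempotence on already standardized columns
  st2 <- standardize_columns(st$values)
  expect_lt(max(abs(st2$values - st$values)), 1e-12)
  # constant column: centered only, with warning, flagged
  m2 <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(st3 <- standardize_columns(m2), "zero-variance")
  expect_equal(unname(st3$values[, 2]), c(0, 0, 0))
  expect_true(st3$constant[["b"]])
  # stored transform applies unchanged to held-out data
  new <- apply_standardizer(st, cbind(c(5), c(6)))
  expect_equal(unname(new[1, ]), c((5 - 2) / sqrt(2), (6 - 3) / sqrt(2)))
})
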