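test_that("the registry carries the published index definitions", {
  psri <- get_index("PSRI")
  expect_setequal(psri$bands, c(500, 678, 750))
  expect_equal(psri$orientation, "senescence_positive")
  ndvi <- get_index("NDVI")
  expect_true(800 %in% ndvi$bands)
  expect_equal(ndvi$orientation, "greenness_positive")
  expect_error(get_index("NOSUCH"), "unknown spectral index")
  # every registry entry parses and stays within the instrument range
  for (def in index_registry()) {
    expect_true(all(def$bands >= 350 & def$bands <= 2500))
  }
})

test_that("band math rejects anything beyond R<nm>, arithmetic and sqrt", {
  expect_error(index_definition("bad", "system('ls')"), "disallowed")
  expect_error(index_definition("bad", "R800 + x"), "disallowed symbol")
  expect_error(index_definition("bad", "log(R800)"), "disallowed")
  expect_error(index_definition("bad", "R9999 / R800"), "outside")
  expect_error(index_definition("bad", "1 + 2"), "references no")
})

test_that("index evaluation matches hand arithmetic", {
  wl <- c(500, 670, 678, 750, 800)
  s <- spectrum(wl, c(0.04, 0.05, 0.05, 0.50, 0.50))
  expect_equal(compute_index(s, "PSRI"), (0.05 - 0.04) / 0.50)
  # NDVI symmetry: R800 = R670 gives 0
  s2 <- spectrum(wl, c(0.04, 0.3, 0.05, 0.50, 0.3))
  expect_equal(compute_index(s2, "NDVI"), 0)
  s3 <- spectrum(wl, c(0.04, 0.05, 0.05, 0.50, 0.50))
  expect_equal(compute_index(s3, "NDVI"), 0.45 / 0.55, tolerance = 1e-12)
})

test_that("band lookup respects the tolerance and flags division by zero", {
  s <- spectrum(c(500, 677, 749, 800), c(0.04, 0.05, 0.5, 0.5))
  # 678 and 750 resolve within the 2-nm default tolerance
  expect_equal(compute_index(s, "PSRI"), (0.05 - 0.04) / 0.5)
  expect_error(compute_index(s, "PSRI", band_tolerance_nm = 0.5),
               "R678")
  szero <- spectrum(c(500, 678, 750), c(0.04, 0.05, 0))
  expect_warning(v <- compute_index(szero, "PSRI"), "undefined")
  expect_true(is.na(v))
})

test_that("normalized-difference indices stay in [-1, 1] and flip under band swap", {
  set.seed(31)
  swapped <- index_definition("NDVI_swapped", "(R670 - R800) / (R670 + R800)")
  for (i in 1:25) {
    s <- spectrum(c(670, 800), runif(2, 0, 0.9))
    v <- compute_index(s, "NDVI")
    expect_true(v >= -1 && v <= 1)
    expect_equal(compute_index(s, swapped), -v)
  }
})

test_that("index values are invariant to resampling when bands are grid points", {
  grid <- seq(350, 900, by = 5)
  set.seed(32)
  s <- spectrum(grid, runif(length(grid), 0.05, 0.6))
  fine <- resample_to_grid(s, step_nm = 1)
  def <- index_definition("SR", "R800 / R670")
  expect_equal(compute_index(fine, def), compute_index(s, def))
})

test_that("index series are per plot, date-ordered, with errors flagged not dropped", {
  col <- mixing_collection(c(1, 0.6, 0.2))
  out <- compute_index_series(col, "PSRI")
  expect_equal(nrow(out), 3L)
  expect_false(is.unsorted(out$date))
  # the green -> senescent sweep makes PSRI strictly increasing
  expect_true(all(diff(out$value) > 0))
  # constant spectra give a constant series
  colc <- mixing_collection(c(0.5, 0.5, 0.5))
  expect_equal(var(compute_index_series(colc, "PSRI")$value), 0)
})

test_that("correlograms use senescence degree with the documented sign convention", {
  # reflectance at one band rising exactly linearly with senescence degree
  wl <- c(500, 700)
  vals <- cbind(c(0.1, 0.2, 0.3, 0.4), 0.5)
  col <- tiny_collection(wl, vals, plot_ids = rep("p1", 4),
                         dates = as.Date("2016-06-01") + 0:3)
  scorings <- data.frame(plot_id = "p1", date = as.Date("2016-06-01") + 0:3,
                         score = c(10, 7, 4, 1))  # degree 0, 3, 6, 9
  cg <- wavelength_correlogram(col, scorings)
  expect_equal(cg[cg$wavelength == 500, ]$r, 1)
  # constant band: undefined, flagged as NA
  expect_true(is.na(cg[cg$wavelength == 700, ]$r))
  expect_error(
    wavelength_correlogram(col, scorings[1:2, ]),
    "fewer than 3"
  )
})

test_that("phase-stratified correlograms honour user-supplied bins", {
  set.seed(33)
  col <- mixing_collection(seq(1, 0, length.out = 11))
  scorings <- data.frame(plot_id = "p1",
                         date = as.Date("2016-06-01") + 1:11,
                         score = round(seq(10, 0, length.out = 11)))
  cg <- wavelength_correlogram(col, scorings,
                               phase_bins = list(late = c(0, 3),
                                                 early = c(8, 10)))
  expect_setequal(unique(cg$bin), c("late", "early"))
  expect_equal(nrow(cg), 2L * length(col$wavelength))
})

test_that("the band sweep recovers a planted optimum and reduces to the template", {
  # random spectra so the planted band is uniquely identifiable (smooth
  # mixing spectra would leave neighbouring bands collinear)
  set.seed(34)
  grid <- 350:900
  col <- tiny_collection(grid, matrix(runif(30 * length(grid), 0.05, 0.6),
                                      nrow = 30),
                         plot_ids = rep("p1", 30),
                         dates = as.Date("2016-06-01") + 1:30)
  psri_vals <- compute_index_series(col, "PSRI")$value
  # scorings are an exact affine rescaling of PSRI (continuous scores)
  sc <- 10 - 10 * (psri_vals - min(psri_vals)) / diff(range(psri_vals))
  scorings <- data.frame(plot_id = "p1", date = col$meta$date, score = sc)
  sweep <- band_sweep(col, scorings, "(Rx - R500) / R750",
                      sweep_range = c(640, 720), step_nm = 2)
  expect_equal(sweep$wavelength[which.max(abs(sweep$r))], 678)
  expect_equal(max(abs(sweep$r)), 1, tolerance = 1e-12)
  # single-candidate sweep gives exactly one pair
  one <- band_sweep(col, scorings, "(Rx - R500) / R750",
                    sweep_range = c(678, 678))
  expect_equal(nrow(one), 1L)
  # at (678, 500, 750) the 3-band template equals the registry PSRI
  tmpl <- three_band_template(678, 500, 750)
  s1 <- spectrum(col$wavelength, col$reflectance[3, ])
  expect_equal(compute_index(s1, tmpl), compute_index(s1, "PSRI"))
})

test_that("sweep candidates without grid support are skipped with a warning", {
  col <- mixing_collection(seq(1, 0, length.out = 6), grid = 350:900)
  scorings <- data.frame(plot_id = "p1", date = col$meta$date,
                         score = seq(10, 0, length.out = 6))
  expect_warning(
    out <- band_sweep(col, scorings, "(Rx - R500) / R750",
                      sweep_range = c(890, 920), step_nm = 10),
    "skipped"
  )
  expect_true(all(out$wavelength <= 900))
})
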