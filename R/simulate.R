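# Synthetic wheat trial generator with retained ground truth.
#
# The generative model: per genotype a Gompertz greenness trajectory
# G(t) = exp(-exp(-b (t - M))) on thermal time after heading (b < 0,
# shared across replicates, plot-level jitter on M); visual scorings are
# rounded, clamped, noisy samples of 10 * G; reflectance is a linear
# mixture of a green and a senescent endmember weighted by G, with
# multiplicative noise and an optional NIR-only multiplicative confound
# active early in grain fill (emulating spike-orientation / canopy
# structure effects); grain yield is a linear function of the true onset
# of senescence with a configurable target correlation.

#' Simulation configuration
#'
#' Defaults emulate a single-season wheat variety trial: 150 genotypes x 2
#' replicates (300 plots), visual scorings every 3 days from early grain
#' fill to complete senescence, 9 spectral measurement dates, Gompertz
#' midpoint-of-rate M ~ 700 degC days (truncated normal), senescence rate
#' |b| ~ 0.02 per degC day, and a grain-yield model targeting a
#' correlation of 0.37 between yield and the true onset of senescence.
#'
#' @param n_genotypes,n_replicates trial dimensions.
#' @param m_mean,m_sd,m_bounds mean, sd and truncation bounds (degC days)
#'   of the genotype distribution of M.
#' @param b_mean,b_sd,b_min mean, sd and lower floor of |b| (per degC day).
#' @param replicate_m_sd plot-level jitter sd added to M per replicate
#'   (degC days).
#' @param heading_spread_days sd (days) of genotype heading dates around
#'   the season's base heading date.
#' @param scoring_interval_days days between visual scoring campaigns.
#' @param scoring_noise_sd sd of the additive scoring noise (score units)
#'   before rounding and clamping to 0..10.
#' @param scoring_start_Cd,scoring_end_Cd assessment window in degC days
#'   after the median heading date.
#' @param n_spectral_dates number of spectral campaigns (an evenly spaced
#'   subset of the scoring dates).
#' @param spectral_noise_sd sd of the spectrally correlated (common-mode)
#'   multiplicative reflectance noise per spectrum, emulating illumination
#'   and calibration drift between records.
#' @param band_noise_sd sd of the independent per-band multiplicative
#'   noise component (detector noise).
#' @param confound_amplitude depth of the NIR-only multiplicative
#'   confound (fraction of reflectance; 0 disables it).
#' @param confound_window wavelength window (nm) the confound affects.
#' @param confound_onset_Cd,confound_scale_Cd logistic thermal-time
#'   profile of the confound: it sets in during early grain fill (around
#'   `confound_onset_Cd` degC days after heading, transition width
#'   `confound_scale_Cd`) and persists, emulating spike orientation
#'   effects that increasingly dominate the sensor's view.
#' @param gy_mean,gy_sd grain yield mean and sd (t/ha).
#' @param rho_gy_onset target correlation between grain yield and the true
#'   onset of senescence.
#' @param gpc_mean,gpc_sd grain protein concentration mean and sd (%).
#' @param rho_gpc_tsen target correlation between protein and the true
#'   senescence duration.
#' @param season_start,base_heading_date,season_end season calendar dates.
#' @param temp_start_C,temp_end_C daily mean air temperature at season
#'   start/end (linear ramp between them).
#' @param diurnal_amplitude_C,temp_noise_sd diurnal half-range and hourly
#'   noise of the simulated temperatures (degC).
#' @param grid_step_nm wavelength grid step (nm).
#' @param seed integer seed; the whole trial is reproducible from it.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genotypes = 150L,
                              n_replicates = 2L,
                              m_mean = 700, m_sd = 60,
                              m_bounds = c(520, 880),
                              b_mean = 0.02, b_sd = 0.004, b_min = 0.008,
                              replicate_m_sd = 15,
                              heading_spread_days = 3,
                              scoring_interval_days = 3L,
                              scoring_noise_sd = 0.5,
                              scoring_start_Cd = 300,
                              scoring_end_Cd = 1150,
                              n_spectral_dates = 9L,
                              spectral_noise_sd = 0.02,
                              band_noise_sd = 0.005,
                              confound_amplitude = 0.15,
                              confound_window = c(750, 1350),
                              confound_onset_Cd = 450,
                              confound_scale_Cd = 80,
                              gy_mean = 4.7, gy_sd = 0.8,
                              rho_gy_onset = 0.37,
                              gpc_mean = 12.7, gpc_sd = 1.0,
                              rho_gpc_tsen = -0.30,
                              season_start = "2016-05-01",
                              base_heading_date = "2016-06-01",
                              season_end = "2016-09-15",
                              temp_start_C = 14, temp_end_C = 22,
                              diurnal_amplitude_C = 5,
                              temp_noise_sd = 1.5,
                              grid_step_nm = 1,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genotypes >= 1L, cfg$n_replicates >= 1L)
  stopifnot(cfg$m_sd >= 0, cfg$b_sd >= 0, cfg$scoring_noise_sd >= 0,
            cfg$spectral_noise_sd >= 0, cfg$replicate_m_sd >= 0)
  stopifnot(cfg$m_bounds[1] < cfg$m_bounds[2])
  stopifnot(abs(cfg$rho_gy_onset) <= 1, abs(cfg$rho_gpc_tsen) <= 1)
  stopifnot(cfg$confound_amplitude >= 0, cfg$confound_amplitude < 1)
  stopifnot(cfg$scoring_start_Cd < cfg$scoring_end_Cd)
  stopifnot(cfg$scoring_interval_days >= 1L, cfg$n_spectral_dates >= 2L)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> ", x$n_genotypes, " genotypes x ",
      x$n_replicates, " replicates | M ~ ", x$m_mean, " (", x$m_sd,
      ") degC days | |b| ~ ", x$b_mean, " | seed ", x$seed, "\n", sep = "")
  invisible(x)
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Green and senescent canopy endmember spectra
#'
#' Smooth parametric endmembers on the given grid: the green canopy shows
#' chlorophyll absorption wells around 500 and 678 nm with a small green
#' peak at 550 nm, a logistic red edge rising to the NIR plateau, and
#' water absorption dips near 1450 and 1940 nm; the senescent canopy shows
#' elevated sloping VIS reflectance, a reduced NIR plateau and elevated
#' SWIR reflectance (pigment and water loss). By construction
#' green < senescent on 450--680 nm and 2000--2400 nm and
#' green > senescent on 760--1300 nm.
#'
#' @param grid wavelength grid in nm within \[350, 2500\].
#' @return list of class `endmember_set`: `grid`, `green`, `senescent`.
#' @export
make_endmembers <- function(grid = 350:2500) {
  check_wavelength_grid(grid)
  lam <- as.numeric(grid)
  # green canopy: chlorophyll absorption wells (green peak at 550),
  # steep red edge to the NIR plateau, leaf water absorption near
  # 1450/1940 nm and a gentle dry-matter decline beyond 900 nm
  vis <- 0.04 + 0.06 * exp(-((lam - 550) / 40)^2)
  red_edge <- 0.44 * logistic((lam - 718) / 15)
  dry_decline <- 1 - 3.5e-4 * pmax(0, lam - 900)
  water <- (1 - 0.45 * exp(-((lam - 1450) / 40)^2)) *
    (1 - 0.65 * exp(-((lam - 1940) / 55)^2))
  green <- vis + red_edge * dry_decline * water
  # senescent canopy: pigment loss raises and flattens the VIS, a muted
  # red-edge remnant leads to a reduced but substantial NIR plateau
  # (dead tissue still scatters) that slopes down beyond 900 nm, and
  # water loss elevates the SWIR relative to the green canopy
  senescent <- 0.12 +
    0.30 * logistic((lam - 700) / 28) * (1 - 3e-4 * pmax(0, lam - 900)) +
    0.06 * logistic((lam - 1450) / 120)
  out <- structure(list(grid = lam, green = green, senescent = senescent),
                   class = "endmember_set")
  validate_endmembers(out)
  out
}

validate_endmembers <- function(em) {
  in_win <- function(lo, hi) em$grid >= lo & em$grid <= hi
  diff_gs <- em$green - em$senescent
  if (!all(diff_gs[in_win(450, 680)] < 0)) {
    stop("endmember invariant violated: green >= senescent in 450-680 nm")
  }
  if (!all(diff_gs[in_win(2000, 2400)] < 0)) {
    stop("endmember invariant violated: green >= senescent in 2000-2400 nm")
  }
  if (!all(diff_gs[in_win(760, 1300)] > 0)) {
    stop("endmember invariant violated: green <= senescent in 760-1300 nm")
  }
  invisible(em)
}

#' Simulate hourly temperature records
#'
#' Seasonal linear trend in the daily mean plus a sinusoidal diurnal cycle
#' and Gaussian noise; hourly max/min pairs straddle the hourly mean.
#'
#' @param start_date,end_date calendar span.
#' @param mean_curve either a constant daily mean (degC) or a function of
#'   the date returning the daily mean.
#' @param diurnal_amplitude half-range of the diurnal cycle (degC).
#' @param noise_sd hourly noise sd (degC).
#' @param max_min_spread half-distance between the hourly max and min
#'   (degC).
#' @param seed optional integer seed.
#' @return hourly `data.table` (`date`, `hour`, `t_max`, `t_min`).
#' @export
simulate_temperatures <- function(start_date, end_date, mean_curve = 18,
                                  diurnal_amplitude = 5, noise_sd = 0,
                                  max_min_spread = 0.5, seed = NULL) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (end_date < start_date) stop("end_date before start_date")
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(start_date, end_date, by = "day")
  mfun <- if (is.function(mean_curve)) mean_curve else function(d) {
    rep(mean_curve, length(d))
  }
  daily_mean <- mfun(dates)
  hours <- 0:23
  n <- length(dates) * 24L
  hour_v <- rep(hours, times = length(dates))
  mean_v <- rep(daily_mean, each = 24L)
  # diurnal cycle with zero daily mean: coolest ~ 4 h, warmest ~ 16 h
  cyc <- diurnal_amplitude * sin(2 * pi * (hour_v - 10) / 24)
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  t_mid <- mean_v + cyc + noise
  data.table::data.table(
    date = rep(dates, each = 24L), hour = hour_v,
    t_max = t_mid + max_min_spread, t_min = t_mid - max_min_spread
  )
}

#' Closed-form senescence dynamics of a Gompertz trajectory
#'
#' Threshold crossings `t* = M - log(-log(S*/10)) / b` of
#' `S(t) = 10 exp(-exp(-b (t - M)))` at the 8/5/2 thresholds.
#'
#' @param b,M Gompertz parameters, vectorised; `b != 0`.
#' @param thresholds scaled thresholds, default `c(8, 5, 2)`.
#' @return `data.table` `on_sen_Cd, mid_sen_Cd, end_sen_Cd, t_sen_Cd`.
#' @export
closed_form_truth <- function(b, M, thresholds = c(8, 5, 2)) {
  stopifnot(all(b != 0), length(b) == length(M))
  on <- M - log(-log(thresholds[1] / 10)) / b
  mid <- M - log(-log(thresholds[2] / 10)) / b
  end <- M - log(-log(thresholds[3] / 10)) / b
  data.table::data.table(on_sen_Cd = on, mid_sen_Cd = mid,
                         end_sen_Cd = end, t_sen_Cd = end - on)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Simulate a complete synthetic wheat trial
#'
#' Generates hourly temperatures, plot metadata with heading dates, visual
#' greenness scorings, mixed-endmember reflectance spectra (with
#' multiplicative noise and the optional early-season NIR confound),
#' agronomic traits, and the per-plot generative truth.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_trial` with elements `temperatures`
#'   (hourly `data.table`), `calendar` (`thermal_calendar`), `metadata`
#'   (`plot_id, genotype, replicate, heading_date`), `scorings`
#'   (`plot_id, date, score`), `spectra` (`spectra_collection`), `traits`
#'   (`plot_id, GY_t_ha, GPC_pct`), `truth` (per-plot generative
#'   parameters and closed-form dynamics), and `config`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_plots <- config$n_genotypes * config$n_replicates

  # --- temperatures and thermal calendar -------------------------------
  ramp <- function(d) {
    frac <- as.numeric(d - as.Date(config$season_start)) /
      as.numeric(as.Date(config$season_end) - as.Date(config$season_start))
    config$temp_start_C + frac * (config$temp_end_C - config$temp_start_C)
  }
  temps <- simulate_temperatures(
    config$season_start, config$season_end, mean_curve = ramp,
    diurnal_amplitude = config$diurnal_amplitude_C,
    noise_sd = config$temp_noise_sd
  )
  calendar <- accumulate_gdd(temps, reference_date = config$season_start)

  # --- genotypes and plots --------------------------------------------
  geno_m <- rtruncnorm1(config$n_genotypes, config$m_mean, config$m_sd,
                        config$m_bounds[1], config$m_bounds[2])
  geno_b <- -pmax(config$b_min,
                  stats::rnorm(config$n_genotypes, config$b_mean, config$b_sd))
  # clamp at +-3 sd so every plot has headed well before the first
  # scoring campaign
  geno_head_offset <- round(pmin(pmax(
    stats::rnorm(config$n_genotypes, 0, config$heading_spread_days),
    -3 * config$heading_spread_days), 3 * config$heading_spread_days))
  geno_confound <- rep(config$confound_amplitude, config$n_genotypes)

  metadata <- data.table::data.table(
    plot_id = sprintf("plot_%04d", seq_len(n_plots)),
    genotype = rep(sprintf("geno_%03d", seq_len(config$n_genotypes)),
                   times = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), each = config$n_genotypes)
  )
  g_idx <- rep(seq_len(config$n_genotypes), times = config$n_replicates)
  metadata[, heading_date := as.Date(config$base_heading_date) +
             geno_head_offset[g_idx]]

  plot_m <- geno_m[g_idx] + stats::rnorm(n_plots, 0, config$replicate_m_sd)
  plot_b <- geno_b[g_idx]
  plot_conf <- geno_confound[g_idx]

  truth <- cbind(
    metadata[, .(plot_id, genotype, replicate,
                 heading_date = as.character(heading_date))],
    data.table::data.table(b_true = plot_b, M_true = plot_m,
                           confound_amp = plot_conf),
    closed_form_truth(plot_b, plot_m)
  )

  # --- campaign dates --------------------------------------------------
  median_heading <- stats::median(metadata$heading_date)
  cal_days <- calendar$days
  tt_from <- function(h, d) {
    thermal_time_after_heading(calendar, h, d)
  }
  tt_median <- cal_days$cumulative_gdd -
    cal_days$cumulative_gdd[match(median_heading, cal_days$date)]
  ok_dates <- cal_days$date[tt_median >= config$scoring_start_Cd &
                              tt_median <= config$scoring_end_Cd]
  if (length(ok_dates) < 4L) {
    stop("degenerate config: scoring window misses the senescence decline")
  }
  scoring_dates <- ok_dates[seq(1L, length(ok_dates),
                                by = config$scoring_interval_days)]
  if (length(scoring_dates) < 4L) {
    stop("degenerate config: fewer than 4 scoring dates")
  }
  n_spec <- min(config$n_spectral_dates, length(scoring_dates))
  spectral_dates <- scoring_dates[unique(round(seq(1L, length(scoring_dates),
                                                   length.out = n_spec)))]

  # --- greenness, scorings --------------------------------------------
  # per-plot thermal times of the campaign dates
  tt_mat <- vapply(seq_len(n_plots), function(i) {
    tt_from(metadata$heading_date[i], scoring_dates)
  }, numeric(length(scoring_dates)))  # dates x plots
  g_mat <- vapply(seq_len(n_plots), function(i) {
    exp(-exp(-plot_b[i] * (tt_mat[, i] - plot_m[i])))
  }, numeric(length(scoring_dates)))
  noise <- matrix(stats::rnorm(length(g_mat), 0, config$scoring_noise_sd),
                  nrow = nrow(g_mat))
  score_mat <- pmin(10, pmax(0, round(10 * g_mat + noise)))
  scorings <- data.table::data.table(
    plot_id = rep(metadata$plot_id, each = length(scoring_dates)),
    date = rep(scoring_dates, times = n_plots),
    score = as.vector(score_mat)
  )

  # --- spectra ---------------------------------------------------------
  grid <- seq(350, 2500, by = config$grid_step_nm)
  em <- make_endmembers(grid)
  spec_idx <- match(spectral_dates, scoring_dates)
  n_spectra <- n_plots * length(spectral_dates)
  refl <- matrix(NA_real_, nrow = n_spectra, ncol = length(grid))
  meta_rows <- vector("list", n_plots)
  conf_cols <- em$grid >= config$confound_window[1] &
    em$grid <= config$confound_window[2]
  row <- 0L
  for (i in seq_len(n_plots)) {
    g_i <- g_mat[spec_idx, i]
    tt_i <- tt_mat[spec_idx, i]
    for (k in seq_along(spectral_dates)) {
      row <- row + 1L
      base <- g_i[k] * em$green + (1 - g_i[k]) * em$senescent
      if (config$spectral_noise_sd > 0) {
        # common-mode drift: one factor for the whole spectrum
        base <- base * (1 + stats::rnorm(1L, 0, config$spectral_noise_sd))
      }
      if (config$band_noise_sd > 0) {
        base <- base * (1 + stats::rnorm(length(grid), 0,
                                         config$band_noise_sd))
      }
      if (config$confound_amplitude > 0) {
        # spike-orientation effect: sets in during early grain fill and
        # persists, progressively depressing NIR reflectance
        profile <- logistic((tt_i[k] - config$confound_onset_Cd) /
                              config$confound_scale_Cd)
        base[conf_cols] <- base[conf_cols] *
          (1 - plot_conf[i] * profile)
      }
      refl[row, ] <- pmax(base, 1e-6)
    }
    meta_rows[[i]] <- data.table::data.table(
      plot_id = metadata$plot_id[i], date = spectral_dates
    )
  }
  spectra <- spectra_collection(data.table::rbindlist(meta_rows), grid, refl)

  # --- traits ----------------------------------------------------------
  on_true <- truth$on_sen_Cd
  t_sen_true <- truth$t_sen_Cd
  gy <- trait_from_driver(on_true, config$rho_gy_onset,
                          config$gy_mean, config$gy_sd)
  gpc <- trait_from_driver(t_sen_true, config$rho_gpc_tsen,
                           config$gpc_mean, config$gpc_sd)
  traits <- data.table::data.table(plot_id = metadata$plot_id,
                                   GY_t_ha = gy, GPC_pct = gpc)
  truth[, `:=`(GY_t_ha = gy, GPC_pct = gpc)]

  structure(
    list(temperatures = temps, calendar = calendar, metadata = metadata,
         scorings = scorings, spectra = spectra, traits = traits,
         truth = truth, scoring_dates = scoring_dates,
         spectral_dates = spectral_dates, config = config),
    class = "synthetic_trial"
  )
}

# trait = beta0 + beta1 * driver + e with sd(e) chosen so that
# corr(trait, driver) = rho in expectation and sd(trait) = trait_sd.
trait_from_driver <- function(driver, rho, trait_mean, trait_sd) {
  n <- length(driver)
  s_driver <- stats::sd(driver)
  if (rho == 0 || !is.finite(s_driver) || s_driver == 0) {
    # no (expressible) association: pure noise around the trait mean
    return(stats::rnorm(n, trait_mean, trait_sd))
  }
  beta1 <- rho * trait_sd / s_driver
  resid_sd <- abs(beta1) * s_driver * sqrt(1 / rho^2 - 1)
  e <- if (resid_sd > 0) stats::rnorm(n, 0, resid_sd) else numeric(n)
  trait_mean + beta1 * (driver - mean(driver)) + e
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial> ", nrow(x$metadata), " plots (",
      x$config$n_genotypes, " genotypes x ", x$config$n_replicates,
      " reps) | ", length(x$scoring_dates), " scoring dates | ",
      length(x$spectral_dates), " spectral dates | seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic trial to the CSV dialects consumed by the pipeline
#'
#' Writes `temperatures.csv`, `metadata.csv`, `scorings.csv`,
#' `spectra.csv` (wide layout), `traits.csv`, `truth.csv` and
#' `manifest.json` (config + seed) into `dir`.
#'
#' @param trial a [simulate_trial()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  temps <- trial$temperatures
  data.table::fwrite(data.table::data.table(
    timestamp = sprintf("%sT%02d:00:00Z", as.character(temps$date), temps$hour),
    t_max_C = temps$t_max, t_min_C = temps$t_min
  ), file.path(dir, "temperatures.csv"), nThread = 1L)
  meta <- data.table::copy(trial$metadata)
  meta[, heading_date := as.character(heading_date)]
  data.table::fwrite(meta, file.path(dir, "metadata.csv"), nThread = 1L)
  sc <- data.table::copy(trial$scorings)
  sc[, date := as.character(date)]
  data.table::fwrite(sc, file.path(dir, "scorings.csv"), nThread = 1L)
  write_spectra(trial$spectra, file.path(dir, "spectra.csv"), layout = "wide")
  data.table::fwrite(trial$traits, file.path(dir, "traits.csv"), nThread = 1L)
  data.table::fwrite(trial$truth, file.path(dir, "truth.csv"), nThread = 1L)
  cfg <- unclass(trial$config)
  cfg$season_start <- as.character(cfg$season_start)
  cfg$base_heading_date <- as.character(cfg$base_heading_date)
  cfg$season_end <- as.character(cfg$season_end)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
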