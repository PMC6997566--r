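# Config-driven orchestration: simulate -> preprocess -> indices ->
# dynamics -> compare -> traits -> rfe, with seeding, plot-count
# accounting and tidy CSV outputs. Each stage is also an exported
# function, so real data can enter at any point via the same CSV
# dialects.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(),          # simulation_config() overrides; NULL = use paths
    paths = list(spectra = NULL, scorings = NULL, temperatures = NULL,
                 metadata = NULL, traits = NULL),
    preprocessing = list(average_replicates = TRUE,
                         windows = default_windows()),
    indices = c("PSRI", "NDVI"),
    dynamics = list(method = "linear", thresholds = c(8, 5, 2),
                    n_starts = 50L, match_window_days = 0),
    evaluation = list(reference = "scoring", n_resamples = 30L,
                      subset_sizes = NULL, train_fraction = 0.75,
                      run_traits = TRUE, run_rfe = TRUE),
    verbose = TRUE
  )
}

#' Validate and complete a pipeline configuration
#'
#' Fills defaults, rejects contradictions (thresholds must be strictly
#' decreasing within (0, 10)) and, in strict mode, unknown keys.
#'
#' @param config named list (e.g. parsed from a YAML file) or a path to a
#'   YAML file.
#' @param strict error on unknown top-level keys (default `TRUE`).
#' @return validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list(), strict = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (strict && length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  th <- as.numeric(cfg$dynamics$thresholds)
  if (length(th) != 3L || any(diff(th) >= 0) || any(th <= 0 | th >= 10)) {
    stop("dynamics thresholds must be 3 strictly decreasing values in (0, 10)")
  }
  cfg$dynamics$thresholds <- th
  if (!cfg$dynamics$method %in% c("linear", "gompertz")) {
    stop("dynamics method must be 'linear' or 'gompertz'")
  }
  if (length(cfg$indices) > 0L) {
    reg <- index_registry()
    bad <- setdiff(cfg$indices, names(reg))
    if (length(bad) > 0L) stop("unknown index name(s): ",
                               paste(bad, collapse = ", "))
  }
  if (is.null(cfg$simulate)) {
    need <- c("spectra", "scorings", "temperatures", "metadata")
    missing <- need[vapply(cfg$paths[need], is.null, logical(1))]
    if (length(missing) > 0L) {
      stop("no simulate block: paths must provide ",
           paste(missing, collapse = ", "))
    }
    for (p in c(need, if (cfg$evaluation$run_traits) "traits")) {
      if (!is.null(cfg$paths[[p]]) && !file.exists(cfg$paths[[p]])) {
        stop("input file does not exist: ", cfg$paths[[p]])
      }
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

pipe_log <- function(verbose, ...) {
  if (verbose) message("[senodyn] ", ...)
}

#' Derive per-plot senescence dynamics from scorings and index series
#'
#' Converts each plot's calendar dates to thermal time after heading,
#' min-max scales and orients the series (scorings are greenness-positive;
#' index orientation comes from the registry), fits the requested curve
#' and extracts the threshold parameters. Degenerate plots (constant
#' series, too few points, failed fits) are excluded and reported.
#'
#' @param series `data.table` with `plot_id`, `date`, `value`, `source`
#'   (scorings enter with `source = "scoring"`).
#' @param metadata `data.table` with `plot_id`, `heading_date`.
#' @param calendar a `thermal_calendar` covering all dates.
#' @param orientations named character vector mapping each non-scoring
#'   source to its orientation.
#' @param method `"linear"` or `"gompertz"`.
#' @param thresholds scaled thresholds, default `c(8, 5, 2)`.
#' @param n_starts Gompertz multistart count.
#' @return list: `parameters` (`data.table`), `courses` (nested list
#'   source -> plot_id -> `time_course`), `excluded` (`data.table`
#'   `plot_id, source, reason`).
#' @export
derive_dynamics <- function(series, metadata, calendar, orientations,
                            method = "linear", thresholds = c(8, 5, 2),
                            n_starts = 50L) {
  series <- data.table::as.data.table(series)
  stopifnot(all(c("plot_id", "date", "value", "source") %in% names(series)))
  metadata <- data.table::as.data.table(metadata)
  series <- merge(series, metadata[, .(plot_id, heading_date)],
                  by = "plot_id")
  series[, date := as.Date(date)]
  series[, heading_date := as.Date(heading_date)]
  data.table::setorder(series, source, plot_id, date)
  params <- list()
  courses <- list()
  excluded <- list()
  for (src in unique(series$source)) {
    sub <- series[source == src]
    orient <- if (src == "scoring") "greenness_positive" else {
      if (!src %in% names(orientations)) {
        stop("no orientation declared for source ", src)
      }
      orientations[[src]]
    }
    courses[[src]] <- list()
    for (pid in unique(sub$plot_id)) {
      rows <- sub[plot_id == pid]
      res <- tryCatch({
        tt <- thermal_time_after_heading(calendar, rows$heading_date[1],
                                         rows$date)
        ok <- is.finite(rows$value)
        course <- if (src == "scoring") {
          # scorings are already on the 0-10 greenness scale
          time_course(tt[ok], rows$value[ok], plot_id = pid, source = src)
        } else {
          scale_and_orient(tt[ok], rows$value[ok], orient,
                           plot_id = pid, source = src)
        }
        fit <- if (method == "gompertz") {
          fit_gompertz(course, n_starts = n_starts)
        } else {
          fit_linear(course)
        }
        list(course = course, pars = extract_parameters(fit, thresholds))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        excluded[[length(excluded) + 1L]] <- data.table::data.table(
          plot_id = pid, source = src, reason = conditionMessage(res))
        next
      }
      courses[[src]][[pid]] <- res$course
      params[[length(params) + 1L]] <- res$pars
    }
  }
  list(
    parameters = data.table::rbindlist(params),
    courses = courses,
    excluded = if (length(excluded) > 0L) data.table::rbindlist(excluded)
               else data.table::data.table(plot_id = character(0),
                                           source = character(0),
                                           reason = character(0))
  )
}

#' Build a plot-level feature table from dynamics parameters
#'
#' One row per plot, one column per (parameter, source, method)
#' combination named like `onsen_PSRI_lin`; missing parameters stay `NA`.
#'
#' @param parameters `data.table` from [derive_dynamics()].
#' @return `data.table` keyed by `plot_id`.
#' @export
dynamics_feature_table <- function(parameters) {
  parameters <- data.table::as.data.table(parameters)
  long <- data.table::melt(
    parameters,
    id.vars = c("plot_id", "source", "method"),
    measure.vars = c("on_sen_Cd", "mid_sen_Cd", "end_sen_Cd", "t_sen_Cd"),
    variable.name = "parameter", value.name = "value"
  )
  pname <- c(on_sen_Cd = "onsen", mid_sen_Cd = "midsen",
             end_sen_Cd = "endsen", t_sen_Cd = "tsen")
  mname <- c(linear = "lin", gompertz = "gom")
  long[, feature := paste(pname[as.character(parameter)], source,
                          mname[method], sep = "_")]
  data.table::dcast(long, plot_id ~ feature, value.var = "value")
}

#' Run the full senescence-dynamics pipeline
#'
#' Executes the configured stage chain and writes tidy CSVs plus a JSON
#' run report into `out_dir`. With a `simulate` block the synthetic trial
#' is generated (and written under `out_dir/simulated/`); otherwise the
#' inputs are read from `config$paths`. Identical config + seed give
#' byte-identical outputs.
#'
#' @param config a [validate_config()] result or raw list / YAML path.
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return the run report (list), invisibly; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  verbose <- isTRUE(config$verbose)
  set.seed(config$seed)
  report <- list(seed = config$seed, stages = list(), outputs = character(0))

  # --- stage: simulate or load ----------------------------------------
  if (!is.null(config$simulate)) {
    pipe_log(verbose, "simulating synthetic trial (seed ", config$seed, ")")
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim_cfg <- do.call(simulation_config, sim_args)
    trial <- simulate_trial(sim_cfg)
    sim_dir <- file.path(out_dir, "simulated")
    write_trial(trial, sim_dir)
    report$outputs <- c(report$outputs, file.path("simulated", c(
      "temperatures.csv", "metadata.csv", "scorings.csv", "spectra.csv",
      "traits.csv", "truth.csv", "manifest.json")))
    temps <- trial$temperatures
    metadata <- trial$metadata
    scorings <- trial$scorings
    spectra <- trial$spectra
    traits <- trial$traits
  } else {
    pipe_log(verbose, "loading inputs from configured paths")
    temps <- read_temperature_csv(config$paths$temperatures)
    metadata <- data.table::fread(config$paths$metadata)
    scorings <- data.table::fread(config$paths$scorings)
    layout <- if (!is.null(config$paths$spectra_layout))
      config$paths$spectra_layout else "wide"
    spectra <- read_spectra(config$paths$spectra, layout = layout)
    traits <- if (!is.null(config$paths$traits))
      data.table::fread(config$paths$traits) else NULL
  }
  metadata <- data.table::as.data.table(metadata)
  metadata[, heading_date := as.Date(heading_date)]
  scorings <- data.table::as.data.table(scorings)
  scorings[, date := as.Date(date)]
  report$stages$input <- list(n_plots = nrow(metadata),
                              n_spectra = n_spectra(spectra),
                              n_scorings = nrow(scorings))

  # --- stage: preprocess ----------------------------------------------
  pipe_log(verbose, "preprocessing spectra")
  if (isTRUE(config$preprocessing$average_replicates)) {
    spectra <- average_replicates(spectra)
  }
  windows <- lapply(config$preprocessing$windows, as.numeric)
  spectra <- trim_to_windows(spectra, windows)
  report$stages$preprocess <- list(n_spectra = n_spectra(spectra),
                                   n_bands = length(spectra$wavelength))

  # --- stage: indices --------------------------------------------------
  pipe_log(verbose, "computing spectral indices: ",
           paste(config$indices, collapse = ", "))
  reg <- index_registry()
  index_series <- data.table::rbindlist(lapply(config$indices, function(nm) {
    compute_index_series(spectra, reg[[nm]])
  }))
  data.table::fwrite(
    index_series[, .(plot_id, date = as.character(date), index_name, value)],
    file.path(out_dir, "indices.csv"), nThread = 1L)
  report$outputs <- c(report$outputs, "indices.csv")
  report$stages$indices <- list(n_values = nrow(index_series),
                                n_undefined = sum(is.na(index_series$value)))

  # --- stage: dynamics -------------------------------------------------
  pipe_log(verbose, "deriving senescence dynamics (",
           config$dynamics$method, ")")
  calendar <- accumulate_gdd(temps)
  series <- rbind(
    scorings[, .(plot_id, date, value = as.numeric(score),
                 source = "scoring")],
    index_series[, .(plot_id, date, value, source = index_name)]
  )
  orientations <- vapply(config$indices, function(nm) reg[[nm]]$orientation,
                         character(1))
  dyn <- derive_dynamics(series, metadata, calendar, orientations,
                         method = config$dynamics$method,
                         thresholds = config$dynamics$thresholds,
                         n_starts = config$dynamics$n_starts)
  data.table::fwrite(dyn$parameters, file.path(out_dir, "dynamics.csv"),
                     nThread = 1L)
  data.table::fwrite(dyn$excluded, file.path(out_dir, "excluded_plots.csv"),
                     nThread = 1L)
  report$outputs <- c(report$outputs, "dynamics.csv", "excluded_plots.csv")
  report$stages$dynamics <- list(
    n_parameter_sets = nrow(dyn$parameters),
    n_excluded = nrow(dyn$excluded),
    exclusion_reasons = unique(dyn$excluded$reason)
  )

  # --- stage: compare (index vs scoring) -------------------------------
  ref_src <- config$evaluation$reference
  comp_rows <- list()
  for (nm in config$indices) {
    cand <- dyn$parameters[source == nm]
    ref <- dyn$parameters[source == ref_src]
    if (nrow(cand) == 0L || nrow(ref) == 0L) next
    rep_nm <- compare_parameters(cand, ref,
                                 curves_candidate = dyn$courses[[nm]],
                                 curves_reference = dyn$courses[[ref_src]])
    row <- data.table::copy(rep_nm$by_parameter)
    row[, `:=`(index = nm, mean_error = rep_nm$mean_error,
               n_error_pairs = rep_nm$n_error_pairs)]
    comp_rows[[nm]] <- row
  }
  comparison <- data.table::rbindlist(comp_rows)
  data.table::fwrite(comparison, file.path(out_dir, "comparison.csv"),
                     nThread = 1L)
  report$outputs <- c(report$outputs, "comparison.csv")
  report$stages$compare <- list(n_rows = nrow(comparison))

  # --- stage: traits + rfe --------------------------------------------
  features <- dynamics_feature_table(dyn$parameters)
  data.table::fwrite(features, file.path(out_dir, "features.csv"),
                     nThread = 1L)
  report$outputs <- c(report$outputs, "features.csv")
  if (isTRUE(config$evaluation$run_traits) && !is.null(traits)) {
    pipe_log(verbose, "trait correlations")
    traits <- data.table::as.data.table(traits)
    ft <- merge(features, traits, by = "plot_id")
    feat_cols <- setdiff(names(features), "plot_id")
    tc <- data.table::rbindlist(lapply(
      intersect(c("GY_t_ha", "GPC_pct"), names(ft)),
      function(tr) {
        out <- trait_correlations(ft[, feat_cols, with = FALSE], ft[[tr]])
        out[, trait := tr]
        out
      }))
    data.table::fwrite(tc, file.path(out_dir, "trait_correlations.csv"),
                       nThread = 1L)
    report$outputs <- c(report$outputs, "trait_correlations.csv")
    report$stages$traits <- list(n_rows = nrow(tc))

    if (isTRUE(config$evaluation$run_rfe)) {
      pipe_log(verbose, "recursive feature elimination")
      rfe_ranks <- list()
      rfe_profile <- list()
      for (tr in intersect(c("GY_t_ha", "GPC_pct"), names(ft))) {
        cc <- stats::complete.cases(ft[, c(feat_cols, tr), with = FALSE])
        rfe <- recursive_feature_elimination(
          as.data.frame(ft[cc, feat_cols, with = FALSE]),
          ft[[tr]][cc],
          n_resamples = config$evaluation$n_resamples,
          subset_sizes = config$evaluation$subset_sizes,
          train_fraction = config$evaluation$train_fraction,
          seed = config$seed + 1L
        )
        r1 <- data.table::copy(rfe$ranks); r1[, trait := tr]
        p1 <- data.table::copy(rfe$profile); p1[, trait := tr]
        rfe_ranks[[tr]] <- r1
        rfe_profile[[tr]] <- p1
      }
      data.table::fwrite(data.table::rbindlist(rfe_ranks),
                         file.path(out_dir, "rfe_ranks.csv"), nThread = 1L)
      data.table::fwrite(data.table::rbindlist(rfe_profile),
                         file.path(out_dir, "rfe_profile.csv"), nThread = 1L)
      report$outputs <- c(report$outputs, "rfe_ranks.csv", "rfe_profile.csv")
    }
  }

  # --- run report ------------------------------------------------------
  report$config_digest <- config_digest(config)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(verbose, "done: ", length(report$outputs), " output files in ",
           out_dir)
  invisible(report)
}

# md5 digest of the canonicalized config (via a temp file; tools is base R)
config_digest <- function(config) {
  cfg <- unclass(config)
  cfg <- rapply(cfg, function(x) {
    if (inherits(x, "Date")) as.character(x) else x
  }, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
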