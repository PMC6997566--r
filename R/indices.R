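# Spectral vegetation indices: band-math registry, evaluation on spectra,
# per-wavelength correlograms against visual senescence, and
# correlation-based band sweeps.
#
# Index expressions are band math over terms R<nm> with + - * / sqrt and
# parentheses, e.g. "(R800 - R670) / (R800 + R670)". Bands resolve to the
# nearest grid wavelength within a tolerance (default 2 nm); a band
# farther away is a hard error so indices never drift silently.

#' Define a spectral index
#'
#' @param name index name.
#' @param expression band-math string over `R<nm>` terms with `+ - * /`,
#'   `sqrt` and parentheses.
#' @param orientation `"greenness_positive"` (value falls as the canopy
#'   senesces, e.g. NDVI) or `"senescence_positive"` (value rises, e.g.
#'   PSRI).
#' @param reference free-text provenance of the formula.
#' @return object of class `index_definition`.
#' @export
index_definition <- function(name, expression,
                             orientation = c("greenness_positive",
                                             "senescence_positive"),
                             reference = "") {
  orientation <- match.arg(orientation)
  parsed <- parse_band_math(expression)
  structure(
    list(name = name, expression = expression, orientation = orientation,
         reference = reference, bands = parsed$bands, expr = parsed$expr),
    class = "index_definition"
  )
}

#' @export
print.index_definition <- function(x, ...) {
  cat("<index_definition> ", x$name, " = ", x$expression,
      " [", x$orientation, "]\n", sep = "")
  invisible(x)
}

# Parse and validate a band-math expression. Only R<nm> symbols, numeric
# literals, + - * / sqrt and parentheses are allowed.
parse_band_math <- function(expression) {
  expr <- tryCatch(str2lang(expression),
                   error = function(e) stop("unparseable band math: ", expression))
  bands <- integer(0)
  walk <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.name(e)) {
      s <- as.character(e)
      if (!grepl("^R[0-9]+$", s)) {
        stop("disallowed symbol in band math: ", s)
      }
      bands <<- c(bands, as.integer(sub("^R", "", s)))
      return(invisible())
    }
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% c("+", "-", "*", "/", "sqrt", "(")) {
        stop("disallowed operation in band math: ", op)
      }
      for (i in seq_along(e)[-1]) walk(e[[i]])
      return(invisible())
    }
    stop("disallowed element in band math expression")
  }
  walk(expr)
  bands <- sort(unique(bands))
  if (length(bands) == 0L) stop("band math references no R<nm> band")
  if (any(bands < 350 | bands > 2500)) {
    stop("band math references wavelengths outside [350, 2500] nm")
  }
  list(expr = expr, bands = bands)
}

#' Built-in spectral index registry
#'
#' Named indices with formulas from their original publications:
#' NDVI, PSRI, NDRE, mND705, PSND1, VARIgreen, PRInorm. A generic simple
#' ratio `SR(a, b) = Ra / Rb` and a 3-band template `(Rx - Ry) / Rz` are
#' available through [simple_ratio()] and [three_band_template()].
#'
#' @return named list of [index_definition()] objects.
#' @export
index_registry <- function() {
  defs <- list(
    index_definition("NDVI", "(R800 - R670) / (R800 + R670)",
                     "greenness_positive", "Rouse et al. 1974"),
    index_definition("PSRI", "(R678 - R500) / R750",
                     "senescence_positive", "Merzlyak et al. 1999"),
    index_definition("NDRE", "(R790 - R720) / (R790 + R720)",
                     "greenness_positive", "Barnes et al. 2000"),
    index_definition("mND705", "(R750 - R705) / (R750 + R705 - 2 * R445)",
                     "greenness_positive", "Sims & Gamon 2002"),
    index_definition("PSND1", "(R800 - R675) / (R800 + R675)",
                     "greenness_positive", "Blackburn 1998"),
    index_definition("VARIgreen", "(R550 - R670) / (R550 + R670 - R480)",
                     "greenness_positive", "Gitelson et al. 2002"),
    index_definition(
      "PRInorm",
      "((R531 - R570) / (R531 + R570)) / (((R800 - R670) / sqrt(R800 + R670)) * (R700 / R670))",
      "greenness_positive", "Zarco-Tejada et al. 2013")
  )
  stats::setNames(defs, vapply(defs, `[[`, character(1), "name"))
}

#' Look up an index definition by name
#'
#' @param name registry name (case sensitive).
#' @return an `index_definition`.
#' @export
get_index <- function(name) {
  reg <- index_registry()
  if (!name %in% names(reg)) {
    stop("unknown spectral index: ", name, " (registry has: ",
         paste(names(reg), collapse = ", "), ")")
  }
  reg[[name]]
}

#' Generic simple-ratio index Ra / Rb
#' @param a,b wavelengths in nm.
#' @param orientation see [index_definition()].
#' @return an `index_definition` named `SR_<a>_<b>`.
#' @export
simple_ratio <- function(a, b, orientation = "greenness_positive") {
  index_definition(sprintf("SR_%d_%d", a, b), sprintf("R%d / R%d", a, b),
                   orientation, "generic simple ratio")
}

#' Three-band template (Rx - Ry) / Rz
#'
#' At (x, y, z) = (678, 500, 750) this is the PSRI.
#'
#' @param x,y,z wavelengths in nm.
#' @param orientation see [index_definition()].
#' @return an `index_definition`.
#' @export
three_band_template <- function(x, y, z, orientation = "senescence_positive") {
  index_definition(sprintf("TB_%d_%d_%d", x, y, z),
                   sprintf("(R%d - R%d) / R%d", x, y, z),
                   orientation, "3-band template")
}

# Resolve requested bands to grid columns within tolerance.
resolve_bands <- function(wavelength, bands, band_tolerance_nm = 2) {
  idx <- vapply(bands, function(b) {
    j <- which.min(abs(wavelength - b))
    if (abs(wavelength[j] - b) > band_tolerance_nm) {
      stop("band R", b, " not available within ", band_tolerance_nm,
           " nm of the grid (nearest: ", wavelength[j], " nm)")
    }
    j
  }, integer(1))
  stats::setNames(idx, paste0("R", bands))
}

# Evaluate band math for a matrix of spectra; returns one value per row.
eval_band_math <- function(definition, wavelength, values,
                           band_tolerance_nm = 2) {
  idx <- resolve_bands(wavelength, definition$bands, band_tolerance_nm)
  env <- new.env(parent = baseenv())
  for (nm in names(idx)) assign(nm, values[, idx[[nm]]], envir = env)
  out <- eval(definition$expr, envir = env)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Compute a spectral index on a spectrum or collection
#'
#' Each `R<nm>` term resolves to the reflectance at the nearest grid
#' wavelength within `band_tolerance_nm`; a missing band is an error.
#' Division by zero yields `NA` with a warning.
#'
#' @param x a `spectrum` or `spectra_collection`.
#' @param definition an [index_definition()] or a registry name.
#' @param band_tolerance_nm band matching tolerance (default 2 nm).
#' @return for a `spectrum`, one value; for a collection, a `data.table`
#'   `plot_id, date, index_name, value`.
#' @export
compute_index <- function(x, definition, band_tolerance_nm = 2) {
  if (is.character(definition)) definition <- get_index(definition)
  stopifnot(inherits(definition, "index_definition"))
  if (inherits(x, "spectrum")) {
    v <- eval_band_math(definition, x$wavelength,
                        matrix(x$reflectance, nrow = 1L), band_tolerance_nm)
    if (is.na(v)) warning("index ", definition$name, " undefined (division by zero?)")
    return(as.numeric(v))
  }
  stopifnot(inherits(x, "spectra_collection"))
  v <- eval_band_math(definition, x$wavelength, x$reflectance,
                      band_tolerance_nm)
  if (anyNA(v)) {
    warning(sum(is.na(v)), " undefined index value(s) flagged as NA")
  }
  data.table::data.table(plot_id = x$meta$plot_id, date = x$meta$date,
                         index_name = definition$name, value = v)
}

#' Compute per-plot index time series
#'
#' The collection should hold one (averaged) spectrum per plot and date.
#'
#' @inheritParams compute_index
#' @return `data.table` `plot_id, date, index_name, value`, ordered by
#'   plot and date; undefined values are kept as `NA`, not dropped.
#' @export
compute_index_series <- function(x, definition, band_tolerance_nm = 2) {
  out <- compute_index(x, definition, band_tolerance_nm)
  data.table::setorder(out, plot_id, date)
  out[]
}

# Match each spectrum row to a scoring of the same plot within a date
# window; returns row indices and matched scores.
match_scorings <- function(meta, scorings, match_window_days = 0) {
  scorings <- data.table::as.data.table(scorings)
  stopifnot(all(c("plot_id", "date", "score") %in% names(scorings)))
  scorings <- data.table::copy(scorings)[, date := as.Date(date)]
  sc_by_plot <- split(scorings, by = "plot_id")
  matched <- rep(NA_real_, nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sc <- sc_by_plot[[as.character(meta$plot_id[i])]]
    if (is.null(sc)) next
    dd <- abs(as.numeric(sc$date - meta$date[i]))
    j <- which.min(dd)
    if (dd[j] <= match_window_days) matched[i] <- sc$score[j]
  }
  matched
}

#' Per-wavelength correlogram of reflectance against senescence degree
#'
#' Pearson correlation at each wavelength between reflectance and the
#' senescence degree (10 - greenness score), pooled over all matched
#' plot x date pairs. Positive r means reflectance rises as senescence
#' progresses. Optional stratification into scoring-range bins.
#'
#' @param x a `spectra_collection` (one spectrum per plot x date).
#' @param scorings `data.frame` with `plot_id`, `date`, `score` (0--10,
#'   10 = fully green).
#' @param phase_bins optional named list of `c(lo, hi)` score ranges; the
#'   correlogram is then computed separately per bin.
#' @param match_window_days match spectra to scorings of the same plot
#'   within this many days (default 0 = exact date match).
#' @return `data.table` with `wavelength`, `r`, `n` (and `bin` when
#'   stratified). Wavelengths with zero reflectance variance get `NA` r.
#' @export
wavelength_correlogram <- function(x, scorings, phase_bins = NULL,
                                   match_window_days = 0) {
  stopifnot(inherits(x, "spectra_collection"))
  score <- match_scorings(x$meta, scorings, match_window_days)
  ok <- !is.na(score)
  if (sum(ok) < 3L) stop("fewer than 3 matched spectrum/scoring pairs")
  degree <- 10 - score[ok]
  vals <- x$reflectance[ok, , drop = FALSE]
  one <- function(mask, bin = NULL) {
    v <- vals[mask, , drop = FALSE]
    d <- degree[mask]
    if (length(d) < 3L || stats::sd(d) == 0) {
      r <- rep(NA_real_, ncol(v))
    } else {
      sds <- apply(v, 2L, stats::sd)
      r <- suppressWarnings(as.numeric(stats::cor(v, d)))
      r[sds == 0] <- NA_real_
    }
    out <- data.table::data.table(wavelength = x$wavelength, r = r,
                                  n = length(d))
    if (!is.null(bin)) out[, bin := bin]
    out
  }
  if (is.null(phase_bins)) {
    return(one(rep(TRUE, length(degree))))
  }
  if (is.null(names(phase_bins))) {
    names(phase_bins) <- vapply(phase_bins, function(b)
      paste0("[", b[1], ",", b[2], "]"), character(1))
  }
  data.table::rbindlist(lapply(names(phase_bins), function(nm) {
    b <- phase_bins[[nm]]
    one(score[ok] >= b[1] & score[ok] <= b[2], bin = nm)
  }))
}

#' Correlation-based band sweep of an index template
#'
#' The template expression carries exactly one free band written `Rx`
#' (e.g. `"(Rx - R500) / R750"`). For each candidate wavelength the index
#' is computed on all matched observations and its Pearson correlation
#' with the senescence degree (10 - score) recorded.
#'
#' @param x a `spectra_collection`.
#' @param scorings as in [wavelength_correlogram()].
#' @param template band-math string with one free band `Rx`.
#' @param sweep_range `c(lo, hi)` in nm.
#' @param step_nm candidate spacing (default 1).
#' @param band_tolerance_nm band matching tolerance.
#' @param match_window_days see [wavelength_correlogram()].
#' @return `data.table` `wavelength, r, n`; candidates without a grid band
#'   within tolerance are skipped with a warning.
#' @export
band_sweep <- function(x, scorings, template, sweep_range, step_nm = 1,
                       band_tolerance_nm = 2, match_window_days = 0) {
  stopifnot(inherits(x, "spectra_collection"))
  if (length(gregexpr("Rx", template, fixed = TRUE)[[1]]) < 1L ||
      gregexpr("Rx", template, fixed = TRUE)[[1]][1] == -1L) {
    stop("template must contain the free band 'Rx'")
  }
  score <- match_scorings(x$meta, scorings, match_window_days)
  ok <- !is.na(score)
  if (sum(ok) < 3L) stop("fewer than 3 matched spectrum/scoring pairs")
  degree <- 10 - score[ok]
  vals <- x$reflectance[ok, , drop = FALSE]
  candidates <- seq(sweep_range[1], sweep_range[2], by = step_nm)
  res <- lapply(candidates, function(lam) {
    expr <- gsub("Rx", sprintf("R%d", as.integer(lam)), template, fixed = TRUE)
    def <- tryCatch(index_definition("sweep", expr), error = function(e) NULL)
    if (is.null(def)) return(NULL)
    v <- tryCatch(
      eval_band_math(def, x$wavelength, vals, band_tolerance_nm),
      error = function(e) NULL
    )
    if (is.null(v)) return(NULL)
    use <- is.finite(v)
    r <- if (sum(use) >= 3L && stats::sd(v[use]) > 0) {
      stats::cor(v[use], degree[use])
    } else NA_real_
    data.table::data.table(wavelength = lam, r = r, n = sum(use))
  })
  skipped <- vapply(res, is.null, logical(1))
  if (any(skipped)) {
    warning(sum(skipped), " sweep candidate(s) outside the available grid skipped")
  }
  out <- data.table::rbindlist(res[!skipped])
  if (nrow(out) == 0L) stop("no sweep candidate could be evaluated")
  out[]
}
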