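# Plot-level reflectance spectra: containers, CSV I/O and pre-processing.
#
# A collection holds all spectra of a campaign on one common wavelength
# grid (matrix-backed, one row per plot x date). Field spectroradiometer
# exports that mix grids must be resampled on read.

#' Construct a spectra collection
#'
#' @param meta `data.frame` with one row per spectrum; must contain
#'   `plot_id` and `date`.
#' @param wavelength strictly increasing wavelength grid in nm within
#'   \[350, 2500\].
#' @param reflectance numeric matrix, `nrow(meta)` rows by
#'   `length(wavelength)` columns.
#' @return object of class `spectra_collection`.
#' @export
spectra_collection <- function(meta, wavelength, reflectance) {
  meta <- data.table::as.data.table(meta)
  stopifnot(all(c("plot_id", "date") %in% names(meta)))
  reflectance <- as.matrix(reflectance)
  if (nrow(meta) != nrow(reflectance)) {
    stop("meta rows and reflectance rows differ")
  }
  check_wavelength_grid(wavelength)
  if (length(wavelength) != ncol(reflectance)) {
    stop("wavelength grid and reflectance columns differ in length")
  }
  if (!all(is.finite(reflectance))) stop("non-finite reflectance values")
  meta[, date := as.Date(date)]
  structure(
    list(meta = meta, wavelength = as.numeric(wavelength),
         reflectance = unname(reflectance), grid_common = TRUE),
    class = "spectra_collection"
  )
}

check_wavelength_grid <- function(wavelength) {
  if (length(wavelength) == 0L) stop("empty wavelength grid")
  if (anyNA(wavelength)) stop("NA in wavelength grid")
  if (any(diff(wavelength) <= 0)) stop("wavelength grid not strictly increasing")
  if (min(wavelength) < 350 || max(wavelength) > 2500) {
    stop("wavelengths outside [350, 2500] nm")
  }
  invisible(wavelength)
}

#' Construct a single spectrum
#'
#' @param wavelength,reflectance aligned numeric vectors.
#' @param plot_id,date identifiers (optional).
#' @return object of class `spectrum`.
#' @export
spectrum <- function(wavelength, reflectance, plot_id = NA_character_,
                     date = NA) {
  check_wavelength_grid(wavelength)
  if (length(wavelength) != length(reflectance)) {
    stop("wavelength and reflectance lengths differ")
  }
  if (!all(is.finite(reflectance))) stop("non-finite reflectance values")
  structure(
    list(plot_id = plot_id, date = date,
         wavelength = as.numeric(wavelength),
         reflectance = as.numeric(reflectance)),
    class = "spectrum"
  )
}

#' @export
print.spectra_collection <- function(x, ...) {
  cat("<spectra_collection> ", nrow(x$meta), " spectra | ",
      length(x$wavelength), " bands ", min(x$wavelength), "-",
      max(x$wavelength), " nm | ",
      data.table::uniqueN(x$meta$plot_id), " plots\n", sep = "")
  invisible(x)
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> plot ", x$plot_id, " ", as.character(x$date), " | ",
      length(x$wavelength), " bands\n", sep = "")
  invisible(x)
}

#' Number of spectra in a collection
#' @param x a `spectra_collection`.
#' @export
n_spectra <- function(x) nrow(x$meta)

#' Read spectra from a delimited file
#'
#' Long layout: columns `plot_id`, `date`, `wavelength_nm`, `reflectance`.
#' Wide layout: `plot_id`, `date` and one column per band named `W<nm>`
#' (e.g. `W678`). All spectra must share one wavelength grid; duplicated
#' (plot, date, wavelength) rows are rejected.
#'
#' @param path CSV path.
#' @param layout `"long"` or `"wide"`.
#' @return a [spectra_collection()].
#' @export
read_spectra <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  dt <- data.table::fread(path)
  if (nrow(dt) == 0L) stop("empty spectra file: ", path)
  if (layout == "long") {
    need <- c("plot_id", "date", "wavelength_nm", "reflectance")
    if (!all(need %in% names(dt))) {
      stop("long layout needs columns ", paste(need, collapse = ", "))
    }
    if (!is.numeric(dt$reflectance)) stop("non-numeric reflectance")
    dup <- dt[, .N, by = .(plot_id, date, wavelength_nm)][N > 1L]
    if (nrow(dup) > 0L) {
      stop("duplicated (plot_id, date, wavelength) rows, first: ",
           dup$plot_id[1], " ", dup$date[1], " ", dup$wavelength_nm[1])
    }
    data.table::setorder(dt, plot_id, date, wavelength_nm)
    grids <- dt[, .(g = list(wavelength_nm)), by = .(plot_id, date)]
    grid <- grids$g[[1]]
    same <- vapply(grids$g, function(g) identical(as.numeric(g), as.numeric(grid)),
                   logical(1))
    if (!all(same)) {
      stop("spectra do not share a common wavelength grid; ",
           "resample before building a collection")
    }
    meta <- grids[, .(plot_id, date)]
    values <- matrix(dt$reflectance, nrow = nrow(meta), ncol = length(grid),
                     byrow = TRUE)
    spectra_collection(meta, grid, values)
  } else {
    wcols <- grep("^W[0-9]+$", names(dt), value = TRUE)
    if (length(wcols) == 0L) stop("wide layout needs W<nm> columns")
    if (!all(c("plot_id", "date") %in% names(dt))) {
      stop("wide layout needs plot_id and date columns")
    }
    grid <- as.numeric(sub("^W", "", wcols))
    ord <- order(grid)
    values <- as.matrix(dt[, wcols[ord], with = FALSE])
    if (!is.numeric(values)) stop("non-numeric reflectance")
    spectra_collection(dt[, .(plot_id, date)], grid[ord], values)
  }
}

#' Write spectra to CSV
#'
#' @param x a `spectra_collection`.
#' @param path output path.
#' @param layout `"wide"` (default; columns `W<nm>`) or `"long"`.
#' @return the path, invisibly.
#' @export
write_spectra <- function(x, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "spectra_collection"))
  if (layout == "wide") {
    out <- data.table::data.table(plot_id = x$meta$plot_id,
                                  date = as.character(x$meta$date))
    vals <- data.table::as.data.table(x$reflectance)
    data.table::setnames(vals, paste0("W", format(x$wavelength, trim = TRUE,
                                                  scientific = FALSE)))
    out <- cbind(out, vals)
  } else {
    out <- data.table::data.table(
      plot_id = rep(x$meta$plot_id, each = length(x$wavelength)),
      date = rep(as.character(x$meta$date), each = length(x$wavelength)),
      wavelength_nm = rep(x$wavelength, times = nrow(x$meta)),
      reflectance = as.vector(t(x$reflectance))
    )
  }
  data.table::fwrite(out, path, nThread = 1L)
  invisible(path)
}

#' Average replicate spectra per plot and date
#'
#' Field protocols record several spectra per plot visit; the working
#' spectrum is their per-wavelength arithmetic mean.
#'
#' @param x a `spectra_collection`.
#' @return a `spectra_collection` with one spectrum per plot x date.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "spectra_collection"))
  key <- paste(x$meta$plot_id, x$meta$date, sep = "\r")
  groups <- split(seq_len(nrow(x$meta)), key)
  first <- vapply(groups, `[`, integer(1), 1L)
  ord <- order(first)
  groups <- groups[ord]
  values <- do.call(rbind, lapply(groups, function(i) {
    colMeans(x$reflectance[i, , drop = FALSE])
  }))
  meta <- x$meta[vapply(groups, `[`, integer(1), 1L), .(plot_id, date)]
  spectra_collection(meta, x$wavelength, values)
}

#' Default retained wavelength windows
#'
#' VIS+NIR plus the two short-wave infrared windows outside the
#' atmospheric water absorption bands; 350--399 nm (noisy detector edge)
#' is dropped.
#'
#' @return list of `c(lo, hi)` windows in nm.
#' @export
default_windows <- function() {
  list(c(400, 1350), c(1475, 1781), c(1991, 2400))
}

windows_keep_mask <- function(wavelength, windows) {
  lo <- vapply(windows, `[`, numeric(1), 1L)
  hi <- vapply(windows, `[`, numeric(1), 2L)
  if (any(hi < lo)) stop("window with hi < lo")
  if (length(windows) > 1L) {
    o <- order(lo)
    if (any(lo[o][-1] <= hi[o][-length(hi)])) stop("overlapping windows")
  }
  keep <- rep(FALSE, length(wavelength))
  for (w in windows) keep <- keep | (wavelength >= w[1] & wavelength <= w[2])
  keep
}

#' Trim a spectrum or collection to retained wavelength windows
#'
#' @param x a `spectrum` or `spectra_collection`.
#' @param windows list of closed `c(lo, hi)` intervals in nm,
#'   non-overlapping; defaults to [default_windows()].
#' @return same class as `x`, restricted to the retained wavelengths.
#' @export
trim_to_windows <- function(x, windows = default_windows()) {
  UseMethod("trim_to_windows")
}

#' @export
trim_to_windows.spectrum <- function(x, windows = default_windows()) {
  keep <- windows_keep_mask(x$wavelength, windows)
  if (!any(keep)) stop("no wavelengths survive the trim windows")
  spectrum(x$wavelength[keep], x$reflectance[keep], x$plot_id, x$date)
}

#' @export
trim_to_windows.spectra_collection <- function(x, windows = default_windows()) {
  keep <- windows_keep_mask(x$wavelength, windows)
  if (!any(keep)) stop("no wavelengths survive the trim windows")
  spectra_collection(x$meta, x$wavelength[keep],
                     x$reflectance[, keep, drop = FALSE])
}

#' Resample onto a regular wavelength grid by linear interpolation
#'
#' No extrapolation: the target grid must lie inside the source span.
#'
#' @param x a `spectrum` or `spectra_collection`.
#' @param step_nm grid step in nm (default 1).
#' @param grid explicit target grid overriding `step_nm`.
#' @return same class as `x` on the new grid.
#' @export
resample_to_grid <- function(x, step_nm = 1, grid = NULL) {
  UseMethod("resample_to_grid")
}

make_target_grid <- function(wavelength, step_nm, grid) {
  if (is.null(grid)) {
    grid <- seq(ceiling(min(wavelength)), floor(max(wavelength)), by = step_nm)
  }
  if (min(grid) < min(wavelength) || max(grid) > max(wavelength)) {
    stop("target grid outside source span; extrapolation refused")
  }
  grid
}

#' @export
resample_to_grid.spectrum <- function(x, step_nm = 1, grid = NULL) {
  grid <- make_target_grid(x$wavelength, step_nm, grid)
  vals <- stats::approx(x$wavelength, x$reflectance, xout = grid)$y
  spectrum(grid, vals, x$plot_id, x$date)
}

#' @export
resample_to_grid.spectra_collection <- function(x, step_nm = 1, grid = NULL) {
  grid <- make_target_grid(x$wavelength, step_nm, grid)
  vals <- t(apply(x$reflectance, 1L, function(v) {
    stats::approx(x$wavelength, v, xout = grid)$y
  }))
  spectra_collection(x$meta, grid, vals)
}

#' First derivative of reflectance with respect to wavelength
#'
#' Centered finite differences on a regular grid, one-sided at the ends;
#' units reflectance per nm.
#'
#' @param x a `spectrum` or `spectra_collection` on a regular grid with at
#'   least 3 points.
#' @return same class as `x` holding derivative values.
#' @export
first_derivative <- function(x) {
  UseMethod("first_derivative")
}

check_regular_grid <- function(wavelength) {
  if (length(wavelength) < 3L) stop("need at least 3 points for a derivative")
  steps <- diff(wavelength)
  if (max(steps) - min(steps) > 1e-8 * max(steps)) {
    stop("first_derivative requires a regular wavelength grid")
  }
  steps[1]
}

deriv_matrix <- function(values, h) {
  p <- ncol(values)
  d <- values
  d[, 2:(p - 1)] <- (values[, 3:p, drop = FALSE] -
                       values[, 1:(p - 2), drop = FALSE]) / (2 * h)
  d[, 1] <- (values[, 2] - values[, 1]) / h
  d[, p] <- (values[, p] - values[, p - 1]) / h
  d
}

#' @export
first_derivative.spectrum <- function(x) {
  h <- check_regular_grid(x$wavelength)
  d <- deriv_matrix(matrix(x$reflectance, nrow = 1L), h)
  out <- x
  out$reflectance <- as.numeric(d)
  out
}

#' @export
first_derivative.spectra_collection <- function(x) {
  h <- check_regular_grid(x$wavelength)
  out <- x
  out$reflectance <- deriv_matrix(x$reflectance, h)
  out
}

# Upper convex hull of (x, y) evaluated at every x (Andrew monotone chain).
upper_hull_values <- function(x, y) {
  n <- length(x)
  idx <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      a <- idx[k - 1L]; b <- idx[k]
      # drop b if it lies below the chord a--i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) >= 0) {
        k <- k - 1L
      } else break
    }
    k <- k + 1L
    idx[k] <- i
  }
  hull <- idx[seq_len(k)]
  stats::approx(x[hull], y[hull], xout = x)$y
}

#' Continuum removal
#'
#' Divides each spectrum by its upper convex hull (the "continuum")
#' evaluated at every wavelength. Output lies in (0, 1], equals 1 at hull
#' vertices, and the endpoints map exactly to 1.
#'
#' @param x a `spectrum` or `spectra_collection` with positive reflectance
#'   and at least 3 points.
#' @return same class as `x`, continuum-removed.
#' @export
continuum_removal <- function(x) {
  UseMethod("continuum_removal")
}

#' @export
continuum_removal.spectrum <- function(x) {
  if (length(x$wavelength) < 3L) stop("need at least 3 points")
  if (any(x$reflectance <= 0)) stop("continuum removal needs positive reflectance")
  hull <- upper_hull_values(x$wavelength, x$reflectance)
  out <- x
  out$reflectance <- pmin(x$reflectance / hull, 1)
  out
}

#' @export
continuum_removal.spectra_collection <- function(x) {
  if (length(x$wavelength) < 3L) stop("need at least 3 points")
  if (any(x$reflectance <= 0)) stop("continuum removal needs positive reflectance")
  out <- x
  out$reflectance <- t(apply(x$reflectance, 1L, function(v) {
    pmin(v / upper_hull_values(x$wavelength, v), 1)
  }))
  out
}

#' Mean-center and scale a sample x wavelength matrix to unit variance
#'
#' Column-wise standardization with the sample (n-1) standard deviation.
#' Zero-variance columns are left centered only, with a warning, and
#' flagged in the returned transform. The transform can be re-applied to
#' held-out data without re-fitting.
#'
#' @param m numeric matrix, samples in rows (>= 2).
#' @return list of class `column_standardizer` with elements `values`
#'   (transformed matrix), `center`, `scale` and `constant` (logical mask
#'   of zero-variance columns).
#' @export
standardize_columns <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 samples to standardize")
  center <- colMeans(m)
  sds <- apply(m, 2L, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warning(sum(constant), " zero-variance column(s) left centered only")
  }
  scale <- ifelse(constant, 1, sds)
  values <- sweep(sweep(m, 2L, center, "-"), 2L, scale, "/")
  structure(list(values = values, center = center, scale = scale,
                 constant = constant),
            class = "column_standardizer")
}

#' Apply a stored standardization to new data
#'
#' @param transform a `column_standardizer`.
#' @param m matrix with the same columns as the training matrix.
#' @return transformed matrix.
#' @export
apply_standardizer <- function(transform, m) {
  stopifnot(inherits(transform, "column_standardizer"))
  m <- as.matrix(m)
  if (ncol(m) != length(transform$center)) {
    stop("column count differs from the fitted transform")
  }
  sweep(sweep(m, 2L, transform$center, "-"), 2L, transform$scale, "/")
}
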