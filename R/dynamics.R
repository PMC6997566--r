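# Per-plot senescence time courses: scaling and orientation, linear and
# Gompertz fits against thermal time, extraction of onset / midpoint /
# end / duration, and the area-between-curves error.
#
# All courses are scaled per plot to 0..10 over the assessment period and
# oriented so that 10 always means the greenest state. The Gompertz model
# with asymptotes fixed at 0 and 10 is
#     S(t) = 10 * exp(-exp(-b * (t - M)))
# where M is the thermal time of maximum senescence rate and b the rate
# parameter; for a greenness course decaying from 10 to 0, b < 0.

#' Construct a time course from values already on the 0--10 greenness scale
#'
#' Visual scorings (and externally pre-scaled series) enter the dynamics
#' fits directly, without min-max rescaling; index series should go
#' through [scale_and_orient()] instead.
#'
#' @param t thermal time after heading (degC days), strictly increasing.
#' @param v values on the 0--10 scale (10 = fully green).
#' @param plot_id,source identifiers carried along.
#' @return object of class `time_course`.
#' @export
time_course <- function(t, v, plot_id = NA_character_, source = "scoring") {
  if (length(t) != length(v)) stop("t and v lengths differ")
  if (length(t) < 3L) stop("need at least 3 points in a time course")
  if (any(diff(t) <= 0)) stop("thermal time must be strictly increasing")
  if (anyNA(t) || anyNA(v)) stop("NA in time course")
  if (any(v < 0 | v > 10)) stop("values outside the 0-10 scale")
  if (max(v) <= min(v)) {
    stop("degenerate time course for plot ", plot_id, ": constant values")
  }
  structure(
    list(plot_id = plot_id, t = as.numeric(t), v = as.numeric(v),
         source = source, raw_min = min(v), raw_max = max(v),
         inverted = FALSE),
    class = "time_course"
  )
}

#' Min-max scale a raw series to 0--10 and orient it as greenness
#'
#' `v = 10 * (raw - min) / (max - min)`; if the source rises as the canopy
#' senesces (e.g. PSRI), the scaled values are inverted (`10 - v`) so 10
#' always denotes the greenest state observed in the assessment period.
#'
#' @param t thermal time after heading (degC days), strictly increasing.
#' @param value raw values (scoring, index, or external prediction).
#' @param orientation `"greenness_positive"` or `"senescence_positive"`.
#' @param plot_id,source identifiers carried along.
#' @return object of class `time_course`: list with `plot_id`, `t`, `v`,
#'   `source`, `raw_min`, `raw_max`, `inverted`.
#' @export
scale_and_orient <- function(t, value,
                             orientation = c("greenness_positive",
                                             "senescence_positive"),
                             plot_id = NA_character_, source = "unknown") {
  orientation <- match.arg(orientation)
  if (length(t) != length(value)) stop("t and value lengths differ")
  if (length(t) < 3L) stop("need at least 3 points in a time course")
  if (any(diff(t) <= 0)) stop("thermal time must be strictly increasing")
  if (anyNA(t) || anyNA(value)) stop("NA in time course")
  raw_min <- min(value)
  raw_max <- max(value)
  if (raw_max <= raw_min) {
    stop("degenerate time course for plot ", plot_id,
         ": constant values, cannot scale")
  }
  v <- 10 * (value - raw_min) / (raw_max - raw_min)
  inverted <- orientation == "senescence_positive"
  if (inverted) v <- 10 - v
  structure(
    list(plot_id = plot_id, t = as.numeric(t), v = as.numeric(v),
         source = source, raw_min = raw_min, raw_max = raw_max,
         inverted = inverted),
    class = "time_course"
  )
}

#' @export
print.time_course <- function(x, ...) {
  cat("<time_course> plot ", x$plot_id, " [", x$source, "] ",
      length(x$t), " points, t ", round(min(x$t)), "..", round(max(x$t)),
      " degC days", if (x$inverted) " (inverted)", "\n", sep = "")
  invisible(x)
}

#' Infer the orientation of an index from pooled raw series
#'
#' A source whose raw values rise with thermal time across the trial is
#' senescence-positive; one that falls is greenness-positive. Used only
#' when the index registry does not already declare an orientation.
#'
#' @param value raw values pooled over plots.
#' @param t matching thermal times.
#' @param min_abs_r ambiguity threshold on the pooled Pearson r
#'   (default 0.2).
#' @return `"senescence_positive"` or `"greenness_positive"`.
#' @export
infer_orientation <- function(value, t, min_abs_r = 0.2) {
  ok <- is.finite(value) & is.finite(t)
  if (sum(ok) < 10L) stop("need at least 10 pooled observations")
  r <- stats::cor(value[ok], t[ok])
  if (!is.finite(r) || abs(r) < min_abs_r) {
    stop("orientation ambiguous (pooled |r| = ",
         if (is.finite(r)) round(abs(r), 3) else "NA",
         " < ", min_abs_r, "); supply it explicitly")
  }
  if (r > 0) "senescence_positive" else "greenness_positive"
}

#' Piecewise-linear interpolant through a time course
#'
#' @param course a [scale_and_orient()] result (or any list with `t`, `v`).
#' @return object of class `linear_course_fit`: the exact interpolant,
#'   evaluable on `[min(t), max(t)]` via [predict_course()].
#' @export
fit_linear <- function(course) {
  if (length(course$t) < 2L) stop("need at least 2 points")
  structure(
    list(t = course$t, v = course$v,
         plot_id = course$plot_id, source = course$source),
    class = "linear_course_fit"
  )
}

gompertz_value <- function(t, b, M) 10 * exp(-exp(-b * (t - M)))

#' Gompertz greenness model
#'
#' `S(t) = 10 * exp(-exp(-b * (t - M)))` with asymptotes fixed at 0 and
#' 10. At `t = M` the value is `10 / e`.
#'
#' @param t thermal time (degC days).
#' @param b rate parameter per degC day (negative for decaying greenness).
#' @param M thermal time of maximum senescence rate (degC days).
#' @return model values.
#' @export
gompertz_greenness <- function(t, b, M) gompertz_value(t, b, M)

#' Fit the Gompertz senescence model by multistart least squares
#'
#' Damped (Levenberg-Marquardt) least squares from a seeded grid of
#' starting values spanning both signs of `b` and the observed thermal
#' span for `M`; the best converged start by residual sum of squares is
#' returned.
#'
#' @param course a `time_course` with at least 4 points.
#' @param n_starts number of starting values (default 50).
#' @param seed optional integer seed for the start draw (local RNG).
#' @return object of class `gompertz_fit`: `b`, `M`, `rss`,
#'   `n_starts_tried`, `converged`.
#' @export
fit_gompertz <- function(course, n_starts = 50L, seed = NULL) {
  t <- course$t
  v <- course$v
  if (length(t) < 4L) stop("need at least 4 points for a Gompertz fit")
  starts <- gompertz_starts(t, n_starts, seed)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(b = starts$b[k], M = starts$M[k]),
        fn = function(par) v - gompertz_value(t, par$b, par$M),
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                             maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(b = fit$par$b, M = fit$par$M, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(b = NA_real_, M = NA_real_, rss = NA_real_,
           n_starts_tried = nrow(starts), converged = FALSE,
           plot_id = course$plot_id, source = course$source),
      class = "gompertz_fit"
    ))
  }
  structure(
    list(b = best$b, M = best$M, rss = best$rss,
         n_starts_tried = nrow(starts), converged = TRUE,
         plot_id = course$plot_id, source = course$source),
    class = "gompertz_fit"
  )
}

# Start grid: |b| log-spaced in [0.001, 0.1], both signs; M spanning the
# observed thermal window. Half the starts are deterministic grid points,
# half uniform random (seeded) to escape awkward geometry.
gompertz_starts <- function(t, n_starts, seed = NULL) {
  n_starts <- max(4L, as.integer(n_starts))
  n_grid <- ceiling(n_starts / 2)
  bs_mag <- exp(seq(log(0.001), log(0.1), length.out = ceiling(n_grid / 2)))
  grid <- expand.grid(
    b = c(-bs_mag, bs_mag),
    M = seq(min(t), max(t), length.out = 4)
  )
  grid <- grid[seq_len(min(nrow(grid), n_grid)), ]
  n_rand <- n_starts - nrow(grid)
  rand <- NULL
  if (n_rand > 0L) {
    if (!is.null(seed)) set.seed(seed)
    rand <- data.frame(
      b = sample(c(-1, 1), n_rand, replace = TRUE) *
        exp(stats::runif(n_rand, log(0.001), log(0.1))),
      M = stats::runif(n_rand, min(t), max(t))
    )
  }
  rbind(grid, rand)
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (x$converged) {
    cat("<gompertz_fit> b = ", signif(x$b, 5), " per degC day, M = ",
        round(x$M, 2), " degC days, RSS = ", signif(x$rss, 4), " (",
        x$n_starts_tried, " starts)\n", sep = "")
  } else {
    cat("<gompertz_fit> not converged (", x$n_starts_tried, " starts)\n",
        sep = "")
  }
  invisible(x)
}

#' Evaluate a fitted course at new thermal times
#'
#' @param fit a `linear_course_fit` or `gompertz_fit`.
#' @param t thermal times; for the linear fit these must lie inside the
#'   observed span (no extrapolation).
#' @return fitted values on the 0--10 scale.
#' @export
predict_course <- function(fit, t) {
  if (inherits(fit, "linear_course_fit")) {
    if (any(t < min(fit$t) - 1e-9 | t > max(fit$t) + 1e-9)) {
      stop("evaluation outside the observed thermal-time span")
    }
    return(stats::approx(fit$t, fit$v, xout = t)$y)
  }
  if (inherits(fit, "gompertz_fit")) {
    if (!fit$converged) stop("cannot evaluate a non-converged Gompertz fit")
    return(gompertz_value(t, fit$b, fit$M))
  }
  stop("unsupported fit class")
}

# First downward crossing of `threshold` for a piecewise-linear course;
# NA when never crossed within the span.
first_downward_crossing <- function(t, v, threshold) {
  n <- length(t)
  if (v[1] < threshold) return(t[1])
  for (i in seq_len(n - 1L)) {
    if (v[i] >= threshold && v[i + 1L] < threshold) {
      # exact segment crossing
      return(t[i] + (v[i] - threshold) / (v[i] - v[i + 1L]) * (t[i + 1L] - t[i]))
    }
  }
  NA_real_
}

#' Closed-form threshold crossings of the Gompertz greenness model
#'
#' `t* = M - log(-log(S*/10)) / b` for scaled thresholds `S*`.
#'
#' @param b,M Gompertz parameters (`b != 0`).
#' @param thresholds scaled thresholds, default `c(8, 5, 2)` (80/50/20
#'   percent of the scaled maximum).
#' @return named vector `on_sen, mid_sen, end_sen, t_sen` (degC days).
#' @export
gompertz_thresholds <- function(b, M, thresholds = c(8, 5, 2)) {
  stopifnot(length(thresholds) == 3L, b != 0)
  tt <- M - log(-log(thresholds / 10)) / b
  c(on_sen = tt[1], mid_sen = tt[2], end_sen = tt[3], t_sen = tt[3] - tt[1])
}

#' Extract senescence dynamics parameters from a fitted course
#'
#' Onset, midpoint and end of senescence are the earliest thermal times at
#' which the fitted course falls below 80, 50 and 20 percent of the scaled
#' maximum (absolute thresholds 8, 5, 2 on the 0--10 scale); the duration
#' is `end - onset`. Linear fits use the exact first downward segment
#' crossing; Gompertz fits use the closed-form inversion. A threshold
#' never reached leaves that parameter `NA` and flags the plot.
#'
#' @param fit a `linear_course_fit` or converged `gompertz_fit`.
#' @param thresholds strictly decreasing scaled thresholds in (0, 10),
#'   default `c(8, 5, 2)`.
#' @return one-row `data.table`: `plot_id, source, method, on_sen_Cd,
#'   mid_sen_Cd, end_sen_Cd, t_sen_Cd, status`.
#' @export
extract_parameters <- function(fit, thresholds = c(8, 5, 2)) {
  stopifnot(length(thresholds) == 3L)
  if (any(diff(thresholds) >= 0) || any(thresholds <= 0 | thresholds >= 10)) {
    stop("thresholds must be strictly decreasing within (0, 10)")
  }
  if (inherits(fit, "linear_course_fit")) {
    method <- "linear"
    cr <- vapply(thresholds, function(th)
      first_downward_crossing(fit$t, fit$v, th), numeric(1))
  } else if (inherits(fit, "gompertz_fit")) {
    method <- "gompertz"
    if (!fit$converged) {
      cr <- rep(NA_real_, 3L)
    } else if (fit$b < 0) {
      cr <- fit$M - log(-log(thresholds / 10)) / fit$b
    } else {
      # rising curve never crosses downward
      cr <- rep(NA_real_, 3L)
    }
  } else {
    stop("unsupported fit class")
  }
  t_sen <- if (is.na(cr[1]) || is.na(cr[3])) NA_real_ else cr[3] - cr[1]
  status <- if (anyNA(cr)) {
    paste0("threshold_not_reached:",
           paste(thresholds[is.na(cr)], collapse = ","))
  } else "ok"
  data.table::data.table(
    plot_id = fit$plot_id, source = fit$source, method = method,
    on_sen_Cd = cr[1], mid_sen_Cd = cr[2], end_sen_Cd = cr[3],
    t_sen_Cd = t_sen, status = status
  )
}

# Intersection abscissae of two piecewise-linear curves on a common knot
# union (both evaluated at the union already).
segment_intersections <- function(t, a, b) {
  d <- a - b
  out <- numeric(0)
  for (i in seq_len(length(t) - 1L)) {
    if ((d[i] > 0 && d[i + 1L] < 0) || (d[i] < 0 && d[i + 1L] > 0)) {
      out <- c(out, t[i] + d[i] / (d[i] - d[i + 1L]) * (t[i + 1L] - t[i]))
    }
  }
  out
}

#' Area between two time courses over their thermal-time overlap
#'
#' `integral |A(t) - B(t)| dt`, computed exactly for piecewise-linear
#' courses by trapezoid on the union of both knot sets plus the
#' intersection points of the two curves. Units: degC days x score units.
#'
#' @param course_a,course_b `time_course` or `linear_course_fit` objects
#'   (anything with `t` and `v`).
#' @return the absolute area between the curves over the overlap.
#' @export
curve_error <- function(course_a, course_b) {
  ta <- course_a$t; va <- course_a$v
  tb <- course_b$t; vb <- course_b$v
  lo <- max(min(ta), min(tb))
  hi <- min(max(ta), max(tb))
  if (hi <= lo) stop("time courses do not overlap in thermal time")
  knots <- sort(unique(c(ta[ta >= lo & ta <= hi], tb[tb >= lo & tb <= hi],
                         lo, hi)))
  a <- stats::approx(ta, va, xout = knots)$y
  b <- stats::approx(tb, vb, xout = knots)$y
  cross <- segment_intersections(knots, a, b)
  if (length(cross) > 0L) {
    knots <- sort(unique(c(knots, cross)))
    a <- stats::approx(ta, va, xout = knots)$y
    b <- stats::approx(tb, vb, xout = knots)$y
  }
  d <- abs(a - b)
  sum((d[-1] + d[-length(d)]) / 2 * diff(knots))
}
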