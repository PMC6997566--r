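# Evaluation machinery: candidate-vs-reference comparison of dynamics
# parameters (Pearson r, bias, area-between-curves error), trait
# correlations, and resampled recursive feature elimination.

PARAM_COLS <- c(on = "on_sen_Cd", mid = "mid_sen_Cd",
                end = "end_sen_Cd", t_sen = "t_sen_Cd")

#' Compare candidate with reference senescence dynamics parameters
#'
#' For each parameter (onset, midpoint, end, duration) the Pearson
#' correlation and two-sided p-value across plots with both values
#' defined, and the bias `mean(candidate - reference)` in degC days.
#' When paired fitted courses are supplied, the mean area-between-curves
#' error is reported as well.
#'
#' @param candidate,reference `data.table`s as produced by
#'   [extract_parameters()] (rows = plots; columns `plot_id`,
#'   `on_sen_Cd`, `mid_sen_Cd`, `end_sen_Cd`, `t_sen_Cd`).
#' @param curves_candidate,curves_reference optional named lists (by
#'   `plot_id`) of time courses / linear fits for the error integral.
#' @return object of class `comparison_report`: `data.table` `by_parameter`
#'   (`parameter, n, r, p, bias`) plus `mean_error` and `n_error_pairs`.
#' @export
compare_parameters <- function(candidate, reference,
                               curves_candidate = NULL,
                               curves_reference = NULL) {
  candidate <- data.table::as.data.table(candidate)
  reference <- data.table::as.data.table(reference)
  merged <- merge(candidate, reference, by = "plot_id",
                  suffixes = c("_cand", "_ref"))
  rows <- lapply(names(PARAM_COLS), function(p) {
    cc <- merged[[paste0(PARAM_COLS[[p]], "_cand")]]
    rr <- merged[[paste0(PARAM_COLS[[p]], "_ref")]]
    ok <- is.finite(cc) & is.finite(rr)
    n <- sum(ok)
    if (n < 3L) {
      return(data.table::data.table(parameter = p, n = n, r = NA_real_,
                                    p = NA_real_, bias = NA_real_))
    }
    if (stats::sd(cc[ok]) == 0 || stats::sd(rr[ok]) == 0) {
      r <- NA_real_; pv <- NA_real_
    } else {
      ct <- stats::cor.test(cc[ok], rr[ok])
      r <- unname(ct$estimate); pv <- ct$p.value
    }
    data.table::data.table(parameter = p, n = n, r = r, p = pv,
                           bias = mean(cc[ok] - rr[ok]))
  })
  mean_error <- NA_real_
  n_error_pairs <- 0L
  if (!is.null(curves_candidate) && !is.null(curves_reference)) {
    shared <- intersect(names(curves_candidate), names(curves_reference))
    errs <- vapply(shared, function(id) {
      tryCatch(curve_error(curves_candidate[[id]], curves_reference[[id]]),
               error = function(e) NA_real_)
    }, numeric(1))
    n_error_pairs <- sum(is.finite(errs))
    if (n_error_pairs > 0L) mean_error <- mean(errs, na.rm = TRUE)
  }
  structure(
    list(by_parameter = data.table::rbindlist(rows),
         mean_error = mean_error, n_error_pairs = n_error_pairs),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$by_parameter)
  if (is.finite(x$mean_error)) {
    cat("mean curve error:", round(x$mean_error, 1), "degC days x score,",
        x$n_error_pairs, "plots\n")
  }
  invisible(x)
}

#' Correlate dynamics features with an agronomic trait
#'
#' Pearson correlation of every feature column against the trait, ranked
#' by decreasing absolute r, with descriptive two-sided p-values
#' (t approximation, no multiple-testing correction by default).
#'
#' @param features `data.frame` of named feature columns (rows = plots or
#'   genotypes).
#' @param trait numeric response vector aligned to `features` rows.
#' @param min_n minimum complete observations per feature (default 10).
#' @param bonferroni apply a Bonferroni correction to the p-values
#'   (default `FALSE`).
#' @return `data.table` `feature, n, r, p` sorted by `|r|` descending;
#'   constant or too-sparse features are excluded with a warning.
#' @export
trait_correlations <- function(features, trait, min_n = 10L,
                               bonferroni = FALSE) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(trait))
  if (anyDuplicated(names(features))) stop("duplicated feature names")
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    ok <- is.finite(x) & is.finite(trait)
    n <- sum(ok)
    if (n < min_n) return(NULL)
    if (stats::sd(x[ok]) == 0) return(NULL)
    ct <- stats::cor.test(x[ok], trait[ok])
    data.table::data.table(feature = f, n = n, r = unname(ct$estimate),
                           p = ct$p.value)
  })
  dropped <- names(features)[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0L) {
    warning("excluded constant or too-sparse feature(s): ",
            paste(dropped, collapse = ", "))
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0L) stop("no usable feature")
  if (bonferroni) out[, p := pmin(1, p * .N)]
  out[order(-abs(r))][]
}

#' Random-forest learner for recursive feature elimination
#'
#' Ensemble of regression trees with permutation importance (via
#' \pkg{ranger}), robust to non-informative and collinear predictors.
#' The returned contract (`fit`, `predict`, `importance`) is what
#' [recursive_feature_elimination()] expects, so any regressor honouring
#' it can substitute.
#'
#' @param num_trees trees per forest (default 200).
#' @param min_node_size minimum node size (default 5).
#' @return list with functions `fit(X, y) -> model`,
#'   `predict(model, X) -> numeric`, `importance(model) -> named
#'   non-negative scores`.
#' @export
rf_learner <- function(num_trees = 200L, min_node_size = 5L) {
  list(
    fit = function(X, y) {
      d <- as.data.frame(X)
      d$.response <- y
      ranger::ranger(
        dependent.variable.name = ".response", data = d,
        num.trees = num_trees, min.node.size = min_node_size,
        importance = "permutation", num.threads = 1L,
        seed = sample.int(.Machine$integer.max, 1L)
      )
    },
    predict = function(model, X) {
      stats::predict(model, data = as.data.frame(X),
                     num.threads = 1L)$predictions
    },
    importance = function(model) {
      imp <- ranger::importance(model)
      pmax(imp, 0)
    }
  )
}

#' Recursive feature elimination with resampling
#'
#' Per resample: random train/held-out split, fit on all current features,
#' record held-out RMSE, drop the feature with the lowest importance, and
#' refit down through the requested subset sizes. A feature's rank within
#' a resample is the size of the smallest subset still containing it
#' (rank 1 = last survivor). Ranks and RMSE profiles are aggregated as
#' mean and standard deviation over resamples.
#'
#' @param features `data.frame` of predictors (no missing values).
#' @param response numeric response aligned to rows.
#' @param learner a fit/predict/importance contract, see [rf_learner()].
#' @param n_resamples number of resamples (default 30).
#' @param subset_sizes decreasing subset sizes to evaluate; default
#'   `ncol(features) .. 1`.
#' @param train_fraction fraction of rows in each training split
#'   (default 0.75).
#' @param seed integer seed making the whole procedure reproducible.
#' @return object of class `rfe_result`: `ranks` (`feature, mean_rank,
#'   sd_rank`), `profile` (`subset_size, rmse_mean, rmse_sd`),
#'   `n_resamples_effective`.
#' @export
recursive_feature_elimination <- function(features, response,
                                          learner = rf_learner(),
                                          n_resamples = 30L,
                                          subset_sizes = NULL,
                                          train_fraction = 0.75,
                                          seed = NULL) {
  features <- as.data.frame(features)
  p <- ncol(features)
  n <- nrow(features)
  stopifnot(length(response) == n, p >= 1L)
  if (anyNA(features) || anyNA(response)) {
    stop("missing values in features or response; complete cases required")
  }
  if (is.null(subset_sizes)) subset_sizes <- seq(p, 1L)
  subset_sizes <- sort(unique(as.integer(subset_sizes)), decreasing = TRUE)
  if (max(subset_sizes) > p) stop("subset size exceeds feature count")
  if (!is.null(seed)) set.seed(seed)
  rank_mat <- matrix(NA_real_, nrow = n_resamples, ncol = p,
                     dimnames = list(NULL, names(features)))
  rmse_mat <- matrix(NA_real_, nrow = n_resamples,
                     ncol = length(subset_sizes),
                     dimnames = list(NULL, subset_sizes))
  failures <- 0L
  for (rs in seq_len(n_resamples)) {
    idx <- sample.int(n, size = max(2L, floor(train_fraction * n)))
    res <- tryCatch(
      rfe_one_resample(features, response, learner, idx, subset_sizes, p),
      error = function(e) NULL
    )
    if (is.null(res)) {
      failures <- failures + 1L
      next
    }
    rank_mat[rs, names(res$rank)] <- res$rank
    rmse_mat[rs, ] <- res$rmse
  }
  eff <- n_resamples - failures
  if (eff == 0L) stop("every RFE resample failed")
  ranks <- data.table::data.table(
    feature = names(features),
    mean_rank = colMeans(rank_mat, na.rm = TRUE),
    sd_rank = apply(rank_mat, 2L, stats::sd, na.rm = TRUE)
  )[order(mean_rank)]
  profile <- data.table::data.table(
    subset_size = subset_sizes,
    rmse_mean = colMeans(rmse_mat, na.rm = TRUE),
    rmse_sd = apply(rmse_mat, 2L, stats::sd, na.rm = TRUE)
  )
  structure(
    list(ranks = ranks, profile = profile, n_resamples_effective = eff),
    class = "rfe_result"
  )
}

rfe_one_resample <- function(features, response, learner, train_idx,
                             subset_sizes, p) {
  X_tr <- features[train_idx, , drop = FALSE]
  y_tr <- response[train_idx]
  X_ho <- features[-train_idx, , drop = FALSE]
  y_ho <- response[-train_idx]
  current <- names(features)
  # a feature eliminated while the active set has size s gets rank s;
  # survivors of the smallest subset get ranked by final importance
  rank_out <- stats::setNames(rep(NA_real_, p), names(features))
  rmse_out <- stats::setNames(rep(NA_real_, length(subset_sizes)),
                              as.character(subset_sizes))
  model <- learner$fit(X_tr[, current, drop = FALSE], y_tr)
  for (si in seq_along(subset_sizes)) {
    s <- subset_sizes[si]
    while (length(current) > s) {
      imp <- learner$importance(model)[current]
      drop_f <- current[which.min(imp)]
      rank_out[drop_f] <- length(current)
      current <- setdiff(current, drop_f)
      model <- learner$fit(X_tr[, current, drop = FALSE], y_tr)
    }
    pred <- learner$predict(model, X_ho[, current, drop = FALSE])
    rmse_out[si] <- sqrt(mean((pred - y_ho)^2))
  }
  # remaining survivors: rank by decreasing importance in the final model
  imp <- learner$importance(model)[current]
  rank_out[current[order(-imp)]] <- seq_along(current)
  list(rank = rank_out, rmse = rmse_out)
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("<rfe_result> ", x$n_resamples_effective, " effective resamples\n",
      sep = "")
  print(utils::head(x$ranks, 10L))
  invisible(x)
}
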