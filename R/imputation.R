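#' Impute a univariate series with a Gaussian process
#'
#' Fits an SE-kernel GP to the observed `(timestamp, value)` pairs of the
#' series (missing entries are `NA`) and fills every missing entry — and any
#' additional query timestamp — with the posterior mean. Observed values are
#' never overwritten.
#'
#' @param timestamps numeric vector of observation times (hours).
#' @param values numeric vector, `NA` where the measurement is missing.
#' @param query_timestamps optional extra timestamps to predict at; appended
#'   (sorted) after the original timestamps in the result.
#' @param params optional fixed [se_kernel_params()]; when `NULL` the
#'   hyperparameters are fitted by [fit_hyperparameters()].
#' @param n_starts,max_iter forwarded to [fit_hyperparameters()].
#' @param seed seed for the hyperparameter multi-start.
#' @return data.frame of class `imputation_result` with columns `time`,
#'   `mean`, `var`, `observed`; attribute `model` holds the fitted
#'   [gp_fit()] object.
#' @examples
#' r <- impute_series(c(0, 1, 2, 3), c(0, NA, 2, NA))
#' r$mean
#' @export
impute_series <- function(timestamps, values, query_timestamps = NULL,
                          params = NULL, n_starts = 3, max_iter = 100,
                          seed = 1) {
  if (length(timestamps) != length(values)) stopf("timestamps/values lengths differ")
  obs <- !is.na(values)
  if (!any(obs)) stopf("impute_series needs at least one observed value; use a cohort-level fallback for empty series")
  xo <- timestamps[obs]; yo <- values[obs]
  if (is.null(params)) {
    params <- suppressWarnings(
      fit_hyperparameters(xo, yo, n_starts = n_starts, max_iter = max_iter,
                          seed = seed))
  }
  model <- gp_fit(xo, yo, params)
  extra <- sort(setdiff(query_timestamps %||% numeric(0), timestamps))
  all_t <- c(timestamps, extra)
  post <- gp_posterior(model, all_t)
  mean_out <- post$mean
  mean_out[seq_along(values)][obs] <- yo  # observed values pass through
  out <- data.frame(time = all_t, mean = mean_out, var = post$var,
                    observed = c(obs, rep(FALSE, length(extra))))
  attr(out, "model") <- model
  class(out) <- c("imputation_result", "data.frame")
  out
}

#' Resample a series onto a regular grid via the GP posterior
#'
#' Evaluates the GP posterior mean on the grid `{0, step, 2 step, ...}`
#' covering `[0, horizon]`, turning an irregularly sampled series into a
#' regularly sampled one (the last grid point is `>= horizon`).
#'
#' @inheritParams impute_series
#' @param step_hours positive grid step (hours).
#' @param horizon upper end of the grid; defaults to the last timestamp.
#' @return data.frame with columns `time`, `value`.
#' @export
resample_regular <- function(timestamps, values, step_hours, horizon = NULL,
                             params = NULL, n_starts = 3, max_iter = 100,
                             seed = 1) {
  if (!is.numeric(step_hours) || step_hours <= 0) stopf("step_hours must be > 0")
  horizon <- horizon %||% max(timestamps)
  grid <- seq(0, horizon, by = step_hours)
  if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
  obs <- !is.na(values)
  if (!any(obs)) stopf("resample_regular needs at least one observed value")
  xo <- timestamps[obs]; yo <- values[obs]
  if (is.null(params)) {
    params <- suppressWarnings(
      fit_hyperparameters(xo, yo, n_starts = n_starts, max_iter = max_iter,
                          seed = seed))
  }
  model <- gp_fit(xo, yo, params)
  data.frame(time = grid, value = gp_posterior(model, grid)$mean)
}

#' Simple imputation baselines
#'
#' Reference imputers for comparison with the GP: `mean_substitution` fills
#' gaps with the series mean; `locf` carries the last observed value forward
#' (gaps before the first observation take the first observed value); `linear`
#' interpolates between neighbouring observations and extrapolates flat.
#'
#' @inheritParams impute_series
#' @param method one of `"mean_substitution"`, `"locf"`, `"linear"`.
#' @return data.frame of class `imputation_result` (columns `time`, `mean`,
#'   `var` — always `NA` for baselines — and `observed`).
#' @examples
#' baseline_impute(1:3, c(1, NA, 3), method = "mean_substitution")$mean
#' @export
baseline_impute <- function(timestamps, values, method, query_timestamps = NULL) {
  method <- match.arg(method, c("mean_substitution", "locf", "linear"))
  if (length(timestamps) != length(values)) stopf("timestamps/values lengths differ")
  obs <- !is.na(values)
  if (!any(obs)) stopf("baseline_impute needs at least one observed value")
  xo <- timestamps[obs]; yo <- values[obs]
  ord <- order(xo); xo <- xo[ord]; yo <- yo[ord]
  extra <- sort(setdiff(query_timestamps %||% numeric(0), timestamps))
  all_t <- c(timestamps, extra)
  fill <- switch(method,
    mean_substitution = rep(mean(yo), length(all_t)),
    locf = {
      idx <- findInterval(all_t, xo)   # last observation at or before t
      yo[pmax(idx, 1L)]
    },
    linear = stats::approx(xo, yo, xout = all_t, method = "linear",
                           rule = 2, ties = "ordered")$y)
  mean_out <- fill
  mean_out[seq_along(values)][obs] <- values[obs]
  out <- data.frame(time = all_t, mean = mean_out, var = NA_real_,
                    observed = c(obs, rep(FALSE, length(extra))))
  class(out) <- c("imputation_result", "data.frame")
  out
}

# All numeric channels of one patient as (timestamps, values) series.
# Events contribute the rate and totalamount channels (indexed by starttime);
# each vitals channel contributes its own irregular series.
patient_series <- function(patient) {
  ev <- patient$events
  out <- list()
  if (nrow(ev) > 0) {
    out$rate <- list(time = ev$starttime, value = ev$rate)
    out$totalamount <- list(time = ev$starttime, value = ev$totalamount)
  }
  for (ch in names(patient$vitals)) {
    v <- patient$vitals[[ch]]
    out[[ch]] <- list(time = v$time, value = v$value)
  }
  out
}

impute_one_series <- function(time, value, method, query = NULL,
                              gp_starts = 1, gp_max_iter = 50, seed = 1) {
  if (method == "gp") {
    impute_series(time, value, query_timestamps = query, n_starts = gp_starts,
                  max_iter = gp_max_iter, seed = seed)
  } else {
    baseline_impute(time, value, method = method, query_timestamps = query)
  }
}

#' Impute every numeric channel of a cohort
#'
#' Runs one imputer per patient per numeric channel (`rate`, `totalamount`,
#' and each vitals channel — channels are never pooled across patients),
#' filling missing values in place and, for the vitals channels, producing a
#' regularly resampled series on the grid `{0, step, ...}` over the
#' observation window. Series with zero observed values fall back to the
#' cohort-level channel mean.
#'
#' @param cohort an [simulate_cohort()] cohort (or one read back by
#'   [read_cohort_tables()]).
#' @param method `"gp"` or one of the [baseline_impute()] methods.
#' @param step_hours grid step for the resampled vitals; defaults to the
#'   cohort's `vitals_step_hours` (2 h if unknown).
#' @param gp_starts,gp_max_iter GP fitting effort per series (the cohort-scale
#'   default uses a single start, which is accurate enough for imputation and
#'   considerably faster than a full multi-start).
#' @param seed seed for the GP multi-start jitter.
#' @return the cohort with missing `rate`/`totalamount` filled (plus logical
#'   columns `rate_imputed`, `totalamount_imputed`), each patient gaining a
#'   `vitals_grid` list of regular per-channel series, and an `imputation`
#'   element recording method and settings.
#' @export
impute_cohort <- function(cohort, method = c("gp", "mean_substitution", "locf",
                                             "linear"),
                          step_hours = NULL, gp_starts = 1, gp_max_iter = 50,
                          seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "icu_cohort"))
  step_hours <- step_hours %||% cohort$config$vitals_step_hours %||% 2
  horizon <- cohort$config$horizon_hours %||%
    max(1, vapply(cohort$patients, function(p)
      suppressWarnings(max(0, p$events$endtime,
                           unlist(lapply(p$vitals, `[[`, "time")))), 0))
  ch_means <- cohort_channel_means(cohort)
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    sseed <- derive_seed(seed, paste0("impute", p$patient_id))
    # event-level channels
    for (ch in c("rate", "totalamount")) {
      if (nrow(p$events) == 0) next
      v <- p$events[[ch]]
      flag <- is.na(v)
      if (any(flag)) {
        if (all(flag)) {
          v[flag] <- ch_means[[ch]]
        } else {
          r <- impute_one_series(p$events$starttime, v, method,
                                 gp_starts = gp_starts,
                                 gp_max_iter = gp_max_iter, seed = sseed)
          v <- r$mean[seq_len(nrow(p$events))]
        }
        p$events[[ch]] <- v
      }
      p$events[[paste0(ch, "_imputed")]] <- flag
    }
    # vitals channels: fill + regular resampling
    p$vitals_grid <- list()
    grid <- seq(0, horizon, by = step_hours)
    if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
    for (ch in names(p$vitals)) {
      s <- p$vitals[[ch]]
      if (nrow(s) == 0 || all(is.na(s$value))) {
        p$vitals_grid[[ch]] <- data.frame(time = grid,
                                          value = rep(ch_means[[ch]], length(grid)))
        if (nrow(s) > 0) p$vitals[[ch]]$value[is.na(s$value)] <- ch_means[[ch]]
        next
      }
      if (method == "gp") {
        pr <- suppressWarnings(
          fit_hyperparameters(s$time[!is.na(s$value)], s$value[!is.na(s$value)],
                              n_starts = gp_starts, max_iter = gp_max_iter,
                              seed = sseed))
        r <- impute_series(s$time, s$value, params = pr)
        p$vitals[[ch]]$value <- r$mean[seq_len(nrow(s))]
        p$vitals_grid[[ch]] <- resample_regular(s$time, s$value, step_hours,
                                                horizon = horizon, params = pr)
      } else {
        r <- baseline_impute(s$time, s$value, method = method,
                             query_timestamps = grid)
        p$vitals[[ch]]$value <- r$mean[seq_len(nrow(s))]
        gv <- r$mean[match(grid, r$time)]
        p$vitals_grid[[ch]] <- data.frame(time = grid, value = gv)
      }
    }
    cohort$patients[[i]] <- p
  }
  cohort$imputation <- list(method = method, step_hours = step_hours,
                            gp_starts = gp_starts, seed = seed)
  cohort
}

cohort_channel_means <- function(cohort) {
  acc <- list()
  for (p in cohort$patients) {
    if (nrow(p$events) > 0) {
      acc$rate <- c(acc$rate, p$events$rate)
      acc$totalamount <- c(acc$totalamount, p$events$totalamount)
    }
    for (ch in names(p$vitals)) acc[[ch]] <- c(acc[[ch]], p$vitals[[ch]]$value)
  }
  lapply(acc, function(v) if (all(is.na(v))) 0 else mean(v, na.rm = TRUE))
}

#' Score imputers against the generator's ground truth
#'
#' For every value masked by the missingness mechanism, imputes it with each
#' requested method and scores the reconstruction against the stored true
#' value. Because the channels live on very different scales, errors are
#' standardised by the per-series truth standard deviation before pooling;
#' `rmse` is the root mean square of those standardised errors and
#' `precision` is the fraction of imputed points within `delta` of the truth,
#' with `delta = delta_factor` times the per-series standard deviation.
#'
#' @param cohort a synthetic cohort carrying `ground_truth` (see
#'   [simulate_cohort()]).
#' @param methods character vector of imputers to score.
#' @param delta_factor multiple of the per-series sd defining a "precise"
#'   reconstruction; `Inf` makes every imputation count as precise.
#' @param gp_starts,gp_max_iter,seed GP fitting effort, as in [impute_cohort()].
#' @return data.frame with one row per method (`method`, `rmse`, `precision`,
#'   `n_points`), sorted by decreasing precision.
#' @export
compare_imputers <- function(cohort,
                             methods = c("gp", "mean_substitution", "locf",
                                         "linear"),
                             delta_factor = 0.1, gp_starts = 1,
                             gp_max_iter = 50, seed = 1) {
  stopifnot(inherits(cohort, "icu_cohort"))
  if (is.null(cohort$ground_truth)) stopf("compare_imputers needs a cohort with ground truth")
  methods <- vapply(methods, function(m)
    match.arg(m, c("gp", "mean_substitution", "locf", "linear")), "")
  tasks <- list()
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    truth <- cohort$ground_truth$patients[[i]]
    ser <- patient_series(p)
    for (ch in names(ser)) {
      tv <- if (ch %in% c("rate", "totalamount")) truth$events_true[[ch]]
            else truth$vitals_true[[ch]]
      ov <- ser[[ch]]$value
      masked <- is.na(ov) & !is.na(tv)
      if (!any(masked) || sum(!is.na(ov)) == 0) next
      sdv <- stats::sd(tv[is.finite(tv)])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      tasks[[length(tasks) + 1L]] <- list(
        time = ser[[ch]]$time, value = ov, truth = tv, masked = masked,
        scale = sdv, id = p$patient_id)
    }
  }
  if (length(tasks) == 0) stopf("no masked points to score (missing_rate = 0?)")
  rows <- lapply(methods, function(m) {
    err <- c(); hit <- c()
    for (tk in tasks) {
      r <- impute_one_series(tk$time, tk$value, m, gp_starts = gp_starts,
                             gp_max_iter = gp_max_iter,
                             seed = derive_seed(seed, paste0(m, tk$id)))
      imp <- r$mean[seq_along(tk$value)][tk$masked]
      tru <- tk$truth[tk$masked]
      err <- c(err, (imp - tru) / tk$scale)
      hit <- c(hit, abs(imp - tru) <= delta_factor * tk$scale)
    }
    data.frame(method = m, rmse = sqrt(mean(err^2)), precision = mean(hit),
               n_points = length(err))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$precision), , drop = FALSE]
  rownames(out) <- NULL
  out
}
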