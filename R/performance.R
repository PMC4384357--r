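# Kaplan-Meier survival evaluated at time points t (right-continuous),
# vectorized over t. Small dedicated evaluator used inside the
# time-dependent ROC estimator, where many stratum-wise KM curves are
# needed per call.
km_at <- function(time, event, t) {
  if (!length(time)) return(rep(NA_real_, length(t)))
  et <- sort(unique(time[event == 1]))
  if (!length(et)) return(rep(1, length(t)))
  surv <- cumprod(vapply(et, function(tj) {
    1 - sum(time == tj & event == 1) / sum(time >= tj)
  }, numeric(1)))
  idx <- findInterval(t, et)
  c(1, surv)[idx + 1]
}

# Reverse Kaplan-Meier of the censoring distribution: G(t) = P(C > t),
# treating censorings as events. Used for IPCW weights.
censoring_km <- function(time, event) {
  function(t) km_at(time, 1 - event, t)
}

#' Graf IPCW estimate of the expected Brier score at time t
#'
#' Estimates \eqn{BS(t) = E[(I(T>t) - \hat\pi(t|Z))^2]} under right
#' censoring: patients observed to die by `t` contribute
#' \eqn{\hat\pi(t|Z)^2 / \hat G(T_i^-)}, patients under follow-up past `t`
#' contribute \eqn{(1-\hat\pi(t|Z))^2 / \hat G(t)}, and patients censored
#' before `t` contribute 0, where \eqn{\hat G} is the reverse Kaplan-Meier
#' estimate of the censoring survival function on the evaluation set.
#' Without censoring this reduces to the plain mean squared error between
#' \eqn{I(T>t)} and \eqn{\hat\pi(t|Z)}.
#'
#' @param predicted_survival Per-patient \eqn{\hat\pi(t|Z)} in \[0, 1\].
#' @param time,event Observed follow-up and event indicators.
#' @param t Evaluation time (days).
#' @return The Brier score estimate; `NA` with a warning when
#'   \eqn{\hat G(t) = 0} (no follow-up information at `t`).
#' @export
brier_score <- function(predicted_survival, time, event, t) {
  stopifnot(length(predicted_survival) == length(time),
            all(predicted_survival >= 0 & predicted_survival <= 1))
  G <- censoring_km(time, event)
  Gt <- G(t)
  if (Gt <= 0) {
    warning("censoring survival is 0 at t = ", t,
            "; Brier score undefined")
    return(NA_real_)
  }
  dead <- time <= t & event == 1
  alive <- time > t
  # G(T_i^-): left limit just before the observed death time
  Gm <- G(pmax(time - 1e-10, 0))
  contrib <- numeric(length(time))
  contrib[dead] <- predicted_survival[dead]^2 / Gm[dead]
  contrib[alive] <- (1 - predicted_survival[alive])^2 / Gt
  mean(contrib)
}

#' Harrell's concordance index
#'
#' The probability that of two patients, the one dying earlier carries the
#' larger risk marker (e.g. Cox linear predictor). Usable pairs are those
#' where the smaller observed time is an event time; pairs with tied event
#' times, or where the earlier time is censored, are excluded. Tied
#' markers in a usable pair count 1/2.
#'
#' @param marker Per-patient risk score (larger = worse prognosis).
#' @param time,event Observed follow-up and event indicators.
#' @return Concordance in \[0, 1\]; errors if no usable pair exists.
#' @export
c_index <- function(marker, time, event) {
  n <- length(marker)
  stopifnot(length(time) == n, length(event) == n)
  conc <- 0; usable <- 0
  ev_idx <- which(event == 1)
  for (i in ev_idx) {
    # pairs (i, j) where i dies strictly first: j still under observation
    later <- which(time > time[i])
    usable <- usable + length(later)
    conc <- conc + sum(marker[i] > marker[later]) +
      0.5 * sum(marker[i] == marker[later])
  }
  if (usable == 0) stop("no usable pairs for the concordance index")
  conc / usable
}

#' Cumulative/dynamic time-dependent sensitivity and specificity
#'
#' At horizon `t`, cases are patients with \eqn{T \le t} and controls those
#' with \eqn{T > t}:
#' \eqn{sens(c;t) = P(M > c | T \le t)}, \eqn{spec(c;t) = P(M \le c | T > t)}.
#' Under censoring these are estimated by Bayes inversion with
#' Kaplan-Meier survival within marker strata:
#' \eqn{sens(c;t) = [1 - \hat S(t|M>c)]\hat P(M>c) / [1 - \hat S(t)]} and
#' \eqn{spec(c;t) = \hat S(t|M \le c)\hat P(M \le c) / \hat S(t)}, clipped
#' to \[0, 1\]. With no censoring before `t` this reduces exactly to the
#' empirical fractions among the dead-by-t and alive-after-t groups.
#'
#' @param marker Per-patient risk score.
#' @param time,event Observed follow-up and event indicators.
#' @param c Marker threshold(s).
#' @param t Evaluation time.
#' @return A data.frame with columns `c`, `sens`, `spec`; `NA` sensitivity
#'   when no deaths by `t`, `NA` specificity when no survivors past `t`.
#' @export
td_sens_spec <- function(marker, time, event, c, t) {
  St <- km_at(time, event, t)
  out <- data.frame(c = c, sens = NA_real_, spec = NA_real_)
  for (i in seq_along(c)) {
    hi <- marker > c[i]
    p_hi <- mean(hi)
    S_hi <- if (any(hi)) km_at(time[hi], event[hi], t) else NA_real_
    S_lo <- if (any(!hi)) km_at(time[!hi], event[!hi], t) else NA_real_
    if (St < 1)
      out$sens[i] <- if (p_hi == 0) 0 else
        min(max((1 - S_hi) * p_hi / (1 - St), 0), 1)
    if (St > 0)
      out$spec[i] <- if (p_hi == 1) 0 else
        min(max(S_lo * (1 - p_hi) / St, 0), 1)
  }
  out
}

#' Time-dependent AUC of the cumulative/dynamic ROC
#'
#' Trapezoidal integration of sensitivity against 1 - specificity over all
#' unique marker values (plus the two extreme endpoints). With no
#' censoring this equals the Mann-Whitney statistic comparing the markers
#' of patients dead by `t` against those alive after `t`.
#'
#' @param marker Per-patient risk score.
#' @param time,event Observed follow-up and event indicators.
#' @param t Evaluation time.
#' @return AUC in \[0, 1\]; `NA` when either group is empty at `t`.
#' @export
td_auc <- function(marker, time, event, t) {
  cuts <- sort(unique(marker))
  ss <- td_sens_spec(marker, time, event, cuts, t)
  if (anyNA(ss$sens) || anyNA(ss$spec)) return(NA_real_)
  # traverse the ROC in curve order (threshold descending from +inf to
  # -inf) rather than re-sorting by fpr: numerical jitter in tied fpr
  # values must not scramble the staircase corners
  fpr <- c(0, rev(1 - ss$spec), 1)
  tpr <- c(0, rev(ss$sens), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Indicator dispatch for one evaluation set; marker is "larger = worse";
# surv is a patients x times matrix aligned with time_grid.
eval_indicator <- function(indicator, marker, surv, time, event, time_grid,
                           t_col = NULL) {
  switch(indicator,
    c_index = c_index(marker, time, event),
    td_auc = vapply(seq_along(time_grid), function(j) {
      m <- if (is.null(marker)) -surv[, j] else marker
      td_auc(m, time, event, time_grid[j])
    }, numeric(1)),
    brier = vapply(seq_along(time_grid), function(j) {
      suppressWarnings(brier_score(surv[, j], time, event, time_grid[j]))
    }, numeric(1)),
    stop("unknown indicator: ", indicator))
}

#' Aggregate cross-validated performance: pooling vs averaging
#'
#' The pooling method concatenates the test-fold scores of one repetition
#' and computes the indicator once per repetition; the averaging method
#' computes the indicator per fold and averages over folds. Both are then
#' averaged over repetitions, with per-repetition values retained for
#' dispersion. The ranking score is either the Cox linear predictor
#' (comparable across folds, so pooling is safe under any resampling
#' strategy) or the predicted survival \eqn{\hat\pi(t|Z)} (fold-specific
#' baseline hazards make pooled survival scores incomparable across folds
#' when batch event rates are unbalanced; a bias warning is attached in
#' that situation rather than refusing the computation).
#'
#' @param cv A `cv_result` from [run_cv()].
#' @param indicator `"td_auc"`, `"c_index"` or `"brier"`.
#' @param score_type `"linear_predictor"` or `"predicted_survival"`.
#' @param aggregation `"pooled"` or `"averaged"`.
#' @param time_grid Evaluation times; defaults to the grid stored in `cv`.
#' @return A list of class `performance_estimate` with `values` (per time,
#'   or scalar for the C-index), `per_repetition` matrix, and metadata.
#' @export
aggregate_cv <- function(cv, indicator = c("td_auc", "c_index", "brier"),
                         score_type = c("linear_predictor",
                                        "predicted_survival"),
                         aggregation = c("pooled", "averaged"),
                         time_grid = NULL) {
  indicator <- match.arg(indicator)
  score_type <- match.arg(score_type)
  aggregation <- match.arg(aggregation)
  if (is.null(time_grid)) time_grid <- cv$time_grid
  stopifnot(all(time_grid %in% cv$time_grid))
  tcols <- match(time_grid, cv$time_grid)
  rec <- cv$records
  if (is.null(rec) || nrow(rec) == 0)
    stop("cv_result holds no scored records (all folds skipped)")
  biased <- cv$plan$strategy == "B" && score_type == "predicted_survival" &&
    aggregation == "pooled"
  if (biased)
    warning("pooled predicted-survival scores under batch-level resampling ",
            "are incomparable across folds when batch event rates are ",
            "unbalanced; estimate may be biased downward")
  reps <- sort(unique(rec$repetition))
  one_set <- function(idx) {
    marker <- if (score_type == "linear_predictor") rec$lp[idx] else NULL
    surv <- cv$surv[idx, tcols, drop = FALSE]
    if (score_type == "predicted_survival" && indicator == "c_index")
      marker <- -surv[, 1]
    eval_indicator(indicator, marker, surv, rec$time[idx], rec$event[idx],
                   time_grid)
  }
  per_rep <- lapply(reps, function(r) {
    ridx <- which(rec$repetition == r)
    if (aggregation == "pooled") {
      one_set(ridx)
    } else {
      folds <- sort(unique(rec$fold[ridx]))
      vals <- lapply(folds, function(f)
        tryCatch(one_set(ridx[rec$fold[ridx] == f]),
                 error = function(e) NA_real_))
      v <- do.call(rbind, vals)
      colMeans(v, na.rm = TRUE)
    }
  })
  per_rep <- do.call(rbind, per_rep)
  colnames(per_rep) <- if (indicator == "c_index") "c_index"
                       else paste0("t", time_grid)
  structure(list(indicator = indicator, score_type = score_type,
                 aggregation = aggregation, time_grid = time_grid,
                 values = colMeans(per_rep, na.rm = TRUE),
                 per_repetition = per_rep,
                 bias_warning = biased),
            class = "performance_estimate")
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("performance_estimate: %s (%s, %s)\n", x$indicator,
              x$aggregation, x$score_type))
  print(round(x$values, 4))
  invisible(x)
}

#' Cross-validated optimism (validation surprise)
#'
#' Apparent performance (computed on the training fold that also built the
#' model) minus test-fold performance, averaged over folds and
#' repetitions, per evaluation time. Complex, overfitted models show large
#' positive optimism; the null model shows none.
#'
#' @param cv A `cv_result` from [run_cv()] (apparent indicators are
#'   recorded during the run).
#' @param indicator `"td_auc"` or `"c_index"`.
#' @param time_grid Evaluation times (subset of the grid stored in `cv`).
#' @return A list with `optimism` (per time), `apparent` and `validated`
#'   components.
#' @export
optimism <- function(cv, indicator = c("td_auc", "c_index"),
                     time_grid = NULL) {
  indicator <- match.arg(indicator)
  if (is.null(time_grid)) time_grid <- cv$time_grid
  tcols <- match(time_grid, cv$time_grid)
  app <- cv$apparent[cv$apparent$indicator == indicator, , drop = FALSE]
  rec <- cv$records
  keys <- unique(rec[, c("repetition", "fold")])
  val <- lapply(seq_len(nrow(keys)), function(i) {
    idx <- which(rec$repetition == keys$repetition[i] &
                   rec$fold == keys$fold[i])
    tryCatch(
      eval_indicator(indicator, rec$lp[idx], cv$surv[idx, tcols, drop = FALSE],
                     rec$time[idx], rec$event[idx], time_grid),
      error = function(e) rep(NA_real_,
                              if (indicator == "c_index") 1
                              else length(time_grid)))
  })
  val <- do.call(rbind, val)
  vcols <- if (indicator == "c_index") "c_index" else paste0("t", time_grid)
  app_m <- as.matrix(app[, vcols, drop = FALSE])
  # align apparent rows with (repetition, fold) keys
  ord <- match(paste(keys$repetition, keys$fold),
               paste(app$repetition, app$fold))
  app_m <- app_m[ord, , drop = FALSE]
  list(indicator = indicator, time_grid = time_grid,
       apparent = colMeans(app_m, na.rm = TRUE),
       validated = stats::setNames(colMeans(val, na.rm = TRUE), vcols),
       optimism = stats::setNames(
         colMeans(app_m - val, na.rm = TRUE), vcols))
}

#' Calibration at a fixed time point
#'
#' Groups patients by predicted-survival quantiles and compares the mean
#' predicted survival with the group's Kaplan-Meier estimate at `t`.
#'
#' @param predicted_survival Per-patient \eqn{\hat\pi(t|Z)}.
#' @param time,event Observed follow-up and event indicators.
#' @param t Evaluation time.
#' @param n_groups Number of quantile groups (>= 2); collapses to fewer
#'   groups when predictions are heavily tied.
#' @return A data.frame with one row per group: `group`, `n`,
#'   `mean_predicted`, `km_observed`, and `km_time` (the time at which KM
#'   was evaluated; earlier than `t`, with `truncated = TRUE`, for groups
#'   with no follow-up reaching `t`).
#' @export
calibration_at <- function(predicted_survival, time, event, t,
                           n_groups = 4) {
  stopifnot(n_groups >= 2)
  qs <- stats::quantile(predicted_survival,
                        probs = seq(0, 1, length.out = n_groups + 1))
  qs <- unique(qs)
  grp <- if (length(qs) <= 2) rep(1L, length(predicted_survival))
         else cut(predicted_survival, qs, include.lowest = TRUE,
                  labels = FALSE)
  out <- lapply(sort(unique(grp)), function(g) {
    idx <- grp == g
    tmax <- max(time[idx])
    truncated <- tmax < t
    km_t <- min(t, tmax)
    data.frame(group = g, n = sum(idx),
               mean_predicted = mean(predicted_survival[idx]),
               km_observed = km_at(time[idx], event[idx], km_t),
               km_time = km_t, truncated = truncated)
  })
  do.call(rbind, out)
}
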