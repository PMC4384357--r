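#' Required number of events from the Schoenfeld formula
#'
#' Number of death events needed to test \eqn{H_0: \Delta = 1} against
#' \eqn{H_1: \Delta = \Delta_0} between two prognostic groups at one-sided
#' level \eqn{\alpha} with power \eqn{\beta}:
#' \deqn{d = \lceil (z_\beta + z_{1-\alpha})^2 / (p_A p_B (\ln \Delta_0)^2) \rceil}
#' with \eqn{p_A, p_B} the group proportions. Symmetric in
#' \eqn{(p_A, p_B)} and in \eqn{\Delta_0 \leftrightarrow 1/\Delta_0}. For
#' a two-sided design pass `alpha/2`.
#'
#' @param alpha One-sided significance level.
#' @param power Desired power (the normal quantile \eqn{z_\beta} uses this
#'   probability).
#' @param hr_alt Hazard ratio \eqn{\Delta_0} under the alternative; must
#'   differ from 1.
#' @param p_a,p_b Proportions of patients in the two prognostic groups
#'   (must sum to 1).
#' @return Integer number of required events.
#' @export
schoenfeld_events <- function(alpha = 0.05, power = 0.80, hr_alt,
                              p_a = 0.5, p_b = 1 - p_a) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, hr_alt > 0,
            abs(p_a + p_b - 1) < 1e-8)
  if (hr_alt == 1) stop("hr_alt = 1: log hazard ratio is 0")
  z <- stats::qnorm(power) + stats::qnorm(1 - alpha)
  ceiling(z^2 / (p_a * p_b * log(hr_alt)^2))
}

#' Final model fit on the full training set
#'
#' Runs the chosen strategy once on all train-role patients and reports
#' the hazard-ratio table (HR = \eqn{e^{\hat\beta}} with Wald p-values per
#' selected covariate). The selected set on the full data may differ from
#' the modal cross-validation selection; it is reported as found.
#'
#' @param train A `survival_cohort` (its train-role patients are used).
#' @param strategy A [model_strategy()].
#' @return A list of class `final_fit`: `fit` (the `fitted_cox` used for
#'   prediction), `hr_table` (data.frame covariate, coefficient, HR, SE,
#'   p), `forms` (fractional-polynomial forms, if any), `strategy`.
#' @export
final_fit <- function(train, strategy) {
  tr <- train$role == "train"
  time <- train$time[tr]; event <- train$event[tr]
  Z <- train$covariates[tr, , drop = FALSE]
  sfit <- fit_strategy(strategy, time, event, Z)
  fit <- sfit$fit
  # Wald table: penalized fits carry no SEs; report an unpenalized refit
  # alongside for inference while predictions stay with `fit`
  inf_fit <- fit
  if (is.null(fit$se) && length(fit$selected)) {
    D <- if (is.null(sfit$forms)) Z else fp_design(Z, sfit$forms)
    inf_fit <- refit_selected(time, event, D, fit$selected)
  }
  hr <- if (length(inf_fit$selected))
    data.frame(covariate = inf_fit$selected,
               coefficient = unname(inf_fit$coefficients[inf_fit$selected]),
               HR = unname(exp(inf_fit$coefficients[inf_fit$selected])),
               SE = if (is.null(inf_fit$se)) NA_real_
                    else unname(inf_fit$se[inf_fit$selected]),
               p = if (is.null(inf_fit$pvalues)) NA_real_
                   else unname(inf_fit$pvalues[inf_fit$selected]),
               stringsAsFactors = FALSE)
  else data.frame(covariate = character(0), coefficient = numeric(0),
                  HR = numeric(0), SE = numeric(0), p = numeric(0))
  structure(list(fit = fit, hr_table = hr, forms = sfit$forms,
                 selected = sfit$selected_original, strategy = strategy),
            class = "final_fit")
}

#' @export
print.final_fit <- function(x, ...) {
  cat(sprintf("final_fit (%s): %d covariate(s) selected\n",
              x$strategy$name, nrow(x$hr_table)))
  if (nrow(x$hr_table)) {
    tab <- x$hr_table
    tab$HR <- round(tab$HR, 3); tab$p <- signif(tab$p, 2)
    print(tab[, c("covariate", "HR", "p")], row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate a frozen model on the independent test set
#'
#' Computes linear predictors and predicted survivals for test-role
#' patients from the final fit (never refitted) and evaluates the
#' requested performance indicators on the test set only. Deterministic:
#' repeated calls are identical.
#'
#' @param ffit A `final_fit` (or a bare `fitted_cox` for linear designs).
#' @param test A `survival_cohort` (its test-role patients are used).
#' @param indicators Subset of `c("td_auc", "c_index", "brier")`.
#' @param time_grid Evaluation days.
#' @return A list of class `validation_report`: `estimates` (named list),
#'   `lp`, `surv`, `time_grid`.
#' @export
validate_on_test <- function(ffit, test,
                             indicators = c("td_auc", "c_index", "brier"),
                             time_grid = c(7, 14)) {
  te <- test$role == "test"
  time <- test$time[te]; event <- test$event[te]
  Z <- test$covariates[te, , drop = FALSE]
  if (inherits(ffit, "final_fit")) {
    sfit <- list(fit = ffit$fit, forms = ffit$forms)
  } else {
    sfit <- list(fit = ffit, forms = NULL)
  }
  pred <- strategy_predict(sfit, Z, time_grid)
  est <- list()
  for (ind in indicators) {
    est[[ind]] <- if (ind == "c_index") {
      tryCatch(c_index(pred$lp, time, event), error = function(e) NA_real_)
    } else {
      stats::setNames(
        eval_indicator(ind, pred$lp, pred$surv, time, event, time_grid),
        paste0("t", time_grid))
    }
  }
  structure(list(estimates = est, lp = pred$lp, surv = pred$surv,
                 time = time, event = event, time_grid = time_grid),
            class = "validation_report")
}

#' Bootstrap percentile confidence intervals on the test set
#'
#' Resamples test-set patients with replacement (the fitted model is
#' frozen, never refit), recomputes the indicator per resample, and
#' reports the percentile interval (2.5th/97.5th percentiles at
#' `level = 0.95`). Resamples where the indicator is undefined (no usable
#' pairs or events at `t`) are skipped and counted; more than 20% skips
#' flag the interval unstable.
#'
#' @param ffit A `final_fit` or `fitted_cox`.
#' @param test A `survival_cohort`.
#' @param indicator `"td_auc"`, `"c_index"` or `"brier"`.
#' @param time_grid Evaluation days (ignored for the C-index).
#' @param B Number of bootstrap resamples (>= 100 recommended).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param unit `"patient"` (default) or `"batch"` for batch-level
#'   resampling of the test set.
#' @return A data.frame with one row per time point (single row for the
#'   C-index): `time`, `estimate`, `lower`, `upper`, `n_skipped`,
#'   `unstable`.
#' @export
bootstrap_ci <- function(ffit, test, indicator = "td_auc",
                         time_grid = c(7, 14), B = 1000, seed = 1L,
                         level = 0.95, unit = c("patient", "batch")) {
  unit <- match.arg(unit)
  vr <- validate_on_test(ffit, test, indicators = indicator,
                         time_grid = time_grid)
  n <- length(vr$time)
  te_batch <- test$batch[test$role == "test"]
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, B,
                  if (indicator == "c_index") 1 else length(time_grid))
  for (b in seq_len(B)) {
    idx <- if (unit == "patient") sample.int(n, n, replace = TRUE)
           else {
             ub <- unique(te_batch)
             bs <- sample(ub, length(ub), replace = TRUE)
             unlist(lapply(bs, function(x) which(te_batch == x)))
           }
    draws[b, ] <- tryCatch({
      if (indicator == "c_index")
        c_index(vr$lp[idx], vr$time[idx], vr$event[idx])
      else
        eval_indicator(indicator, vr$lp[idx], vr$surv[idx, , drop = FALSE],
                       vr$time[idx], vr$event[idx], time_grid)
    }, error = function(e) rep(NA_real_, ncol(draws)))
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  est <- if (indicator == "c_index") vr$estimates[[indicator]]
         else as.numeric(vr$estimates[[indicator]])
  out <- data.frame(
    time = if (indicator == "c_index") NA_real_ else time_grid,
    estimate = est,
    lower = apply(draws, 2, stats::quantile, qs[1], na.rm = TRUE),
    upper = apply(draws, 2, stats::quantile, qs[2], na.rm = TRUE),
    n_skipped = apply(draws, 2, function(v) sum(is.na(v))))
  out$unstable <- out$n_skipped > 0.2 * B
  out
}
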