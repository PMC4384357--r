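#' Outcome-stratified patient-level fold plan (strategy A)
#'
#' N-times k-fold cross-validation where test-fold patients are sampled
#' across batches so that the proportion of events is the same in every
#' fold (up to integer rounding): events and non-events are shuffled
#' separately and dealt round-robin into the k folds, independently per
#' repetition.
#'
#' @param cohort A `survival_cohort`; only train-role patients are folded.
#' @param k Folds per repetition (>= 2).
#' @param n_rep Number of repetitions.
#' @param seed Integer seed; the plan is a pure function of
#'   (cohort, k, n_rep, seed).
#' @return A `fold_plan`: list with `strategy = "A"`, `k`, `n_rep`, `seed`
#'   and `assignment`, a data.frame (`repetition`, `patient_id`, `fold`).
#' @export
make_folds_stratified <- function(cohort, k, n_rep, seed) {
  stopifnot(k >= 2, n_rep >= 1)
  tr <- cohort$role == "train"
  ids <- cohort$patient_id[tr]
  ev <- cohort$event[tr]
  if (sum(ev == 1) < k || sum(ev == 0) < k)
    stop("need at least k events and k non-events to stratify")
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_rep), function(r) {
    fold <- integer(length(ids))
    for (grp in c(1, 0)) {
      idx <- which(ev == grp)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    data.frame(repetition = r, patient_id = ids, fold = fold,
               stringsAsFactors = FALSE)
  })
  structure(list(strategy = "A", k = k, n_rep = n_rep, seed = seed,
                 assignment = do.call(rbind, rows)),
            class = "fold_plan")
}

#' PCR-batch-level fold plan (strategy B)
#'
#' N-times k-fold cross-validation where entire batches are sampled into
#' test folds, so the between-batch technical variability separates the
#' training fold from the test fold just as it separates the training set
#' from an external test set. Folds are balanced on total patient count by
#' a greedy rule: batches are taken largest-first (ties broken by a
#' per-repetition shuffle) and each is placed into the currently smallest
#' fold. Event proportions are deliberately not balanced.
#'
#' @inheritParams make_folds_stratified
#' @return A `fold_plan` with `strategy = "B"`; within every repetition all
#'   patients of a batch share one test-fold index.
#' @export
make_folds_batchwise <- function(cohort, k, n_rep, seed) {
  stopifnot(k >= 2, n_rep >= 1)
  tr <- cohort$role == "train"
  ids <- cohort$patient_id[tr]
  batches <- cohort$batch[tr]
  ub <- unique(batches)
  if (length(ub) < k)
    stop("fewer train batches (", length(ub), ") than folds (", k, ")")
  sizes <- table(batches)
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_rep), function(r) {
    shuffled <- sample(ub)
    ord <- shuffled[order(-as.numeric(sizes[shuffled]))]
    totals <- numeric(k)
    bfold <- stats::setNames(integer(length(ub)), ord)
    for (b in ord) {
      f <- which.min(totals)
      bfold[b] <- f
      totals[f] <- totals[f] + sizes[[b]]
    }
    data.frame(repetition = r, patient_id = ids,
               fold = as.integer(bfold[batches]),
               stringsAsFactors = FALSE)
  })
  structure(list(strategy = "B", k = k, n_rep = n_rep, seed = seed,
                 assignment = do.call(rbind, rows)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: strategy %s, %d-times %d-fold, %d patients\n",
              x$strategy, x$n_rep, x$k,
              length(unique(x$assignment$patient_id))))
  invisible(x)
}

#' Run cross-validation for one model strategy
#'
#' For every (repetition, fold) of the plan, the entire model-building
#' strategy — variable selection, functional-form choice, fitting and
#' shrinkage — is re-run on the training fold only. Test-fold patients
#' receive linear predictors and predicted survival curves from the
#' training-fold model; apparent indicators (time-dependent AUC, C-index,
#' Brier) are computed on the training fold itself. Nothing from a test
#' fold ever influences a fit. Training folds with zero events are skipped
#' and logged, never imputed.
#'
#' Normalization of the gene covariates (sample-wise delta-Ct) is assumed
#' to have been applied upstream; being sample-by-sample it carries no
#' cross-fold information, so it is not repeated inside folds.
#'
#' @param cohort A `survival_cohort` (train-role patients must match the
#'   plan).
#' @param plan A `fold_plan`.
#' @param strategy A [model_strategy()].
#' @param time_grid Evaluation days for predicted survival and apparent
#'   indicators.
#' @return A `cv_result`: list with `records` (one row per scored
#'   patient-repetition: repetition, fold, patient_id, time, event, batch,
#'   lp), `surv` (matrix aligned with `records`, one column per grid
#'   time), `fits` (per repetition x fold: selected set and coefficients),
#'   `apparent` (per repetition x fold indicator table), `residuals`
#'   (training-fold Martingale residuals, long format), `skipped`,
#'   `time_grid`, `plan`, `strategy`.
#' @export
run_cv <- function(cohort, plan, strategy, time_grid = c(7, 14)) {
  tr <- cohort$role == "train"
  ids <- cohort$patient_id[tr]
  if (!setequal(ids, unique(plan$assignment$patient_id)))
    stop("plan does not cover the cohort's train-role patients")
  time <- cohort$time[tr]; event <- cohort$event[tr]
  batch <- cohort$batch[tr]
  Z <- cohort$covariates[tr, , drop = FALSE]
  records <- list(); survs <- list(); fits <- list()
  apparent <- list(); resids <- list(); skipped <- list()
  for (r in seq_len(plan$n_rep)) {
    a <- plan$assignment[plan$assignment$repetition == r, ]
    fold_of <- stats::setNames(a$fold, a$patient_id)[ids]
    for (f in sort(unique(a$fold))) {
      test_i <- which(fold_of == f)
      train_i <- which(fold_of != f)
      if (sum(event[train_i]) == 0) {
        skipped[[length(skipped) + 1]] <-
          data.frame(repetition = r, fold = f,
                     reason = "no events in training fold")
        next
      }
      sfit <- tryCatch(
        fit_strategy(strategy, time[train_i], event[train_i],
                     Z[train_i, , drop = FALSE]),
        error = function(e) e)
      if (inherits(sfit, "error")) {
        skipped[[length(skipped) + 1]] <-
          data.frame(repetition = r, fold = f,
                     reason = paste("fit error:", conditionMessage(sfit)))
        next
      }
      pred_te <- strategy_predict(sfit, Z[test_i, , drop = FALSE], time_grid)
      pred_tr <- strategy_predict(sfit, Z[train_i, , drop = FALSE], time_grid)
      records[[length(records) + 1]] <- data.frame(
        repetition = r, fold = f, patient_id = ids[test_i],
        time = time[test_i], event = event[test_i], batch = batch[test_i],
        lp = pred_te$lp, stringsAsFactors = FALSE)
      survs[[length(survs) + 1]] <- pred_te$surv
      fits[[paste0("r", r, "f", f)]] <-
        list(repetition = r, fold = f,
             selected = sfit$selected_original,
             coefficients = sfit$fit$coefficients)
      # apparent indicators on the training fold
      auc_app <- vapply(seq_along(time_grid), function(j)
        td_auc(pred_tr$lp, time[train_i], event[train_i], time_grid[j]),
        numeric(1))
      ci_app <- tryCatch(c_index(pred_tr$lp, time[train_i], event[train_i]),
                         error = function(e) NA_real_)
      br_app <- vapply(seq_along(time_grid), function(j)
        suppressWarnings(brier_score(pred_tr$surv[, j], time[train_i],
                                     event[train_i], time_grid[j])),
        numeric(1))
      mk_row <- function(ind, ci_val, vals) {
        row <- data.frame(repetition = r, fold = f, indicator = ind,
                          c_index = ci_val)
        for (j in seq_along(time_grid))
          row[[paste0("t", time_grid[j])]] <- vals[j]
        row
      }
      apparent[[length(apparent) + 1]] <- rbind(
        mk_row("td_auc", NA_real_, auc_app),
        mk_row("c_index", ci_app, rep(NA_real_, length(time_grid))),
        mk_row("brier", NA_real_, br_app))
      # Martingale residuals of the training-fold fit, for the
      # omitted-covariate analysis
      H0 <- cumhaz_at(sfit$fit$baseline, time[train_i])
      resids[[length(resids) + 1]] <- data.frame(
        repetition = r, fold = f, patient_id = ids[train_i],
        residual = event[train_i] - H0 * exp(pred_tr$lp + sfit$fit$center),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, records)
  structure(list(records = records,
                 surv = do.call(rbind, survs),
                 fits = fits,
                 apparent = do.call(rbind, apparent),
                 residuals = do.call(rbind, resids),
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else NULL,
                 time_grid = time_grid, plan = plan, strategy = strategy),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: strategy '%s', plan %s (%d x %d), %d scored rows\n",
              x$strategy$name, x$plan$strategy, x$plan$n_rep, x$plan$k,
              nrow(x$records)))
  if (!is.null(x$skipped))
    cat(sprintf("  %d fold(s) skipped\n", nrow(x$skipped)))
  invisible(x)
}
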