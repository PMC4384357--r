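#' Kuncheva stability index for two equal-size selected sets
#'
#' Chance-corrected overlap of two selected-covariate sets of common size
#' s out of N candidates:
#' \eqn{KI = (r - s^2/N) / (s - s^2/N)} with r the shared-covariate count.
#' Ranges over \[-1, 1\]; 1 iff the sets are equal, 0 when the overlap
#' equals its chance expectation \eqn{s^2/N}.
#'
#' @param setA,setB Character vectors of selected covariate names, of
#'   equal size.
#' @param N Number of candidate covariates.
#' @return The index value.
#' @export
kuncheva_index <- function(setA, setB, N) {
  s <- length(setA)
  if (length(setB) != s)
    stop("Kuncheva index requires equal-size sets")
  if (s == 0 || s >= N)
    stop("Kuncheva index undefined for s = 0 or s = N")
  r <- length(intersect(setA, setB))
  (r - s^2 / N) / (s - s^2 / N)
}

#' Stability report across cross-validation fits
#'
#' Per-covariate selection frequency across all (repetition, fold) fits,
#' and — when the strategy selects a constant number of covariates across
#' folds — the mean pairwise Kuncheva index. For strategies whose selected
#' set size varies, only frequencies are reported (the index requires a
#' constrained set size).
#'
#' @param cv A `cv_result`.
#' @param candidates Candidate covariate names (defaults to the strategy's
#'   candidate list).
#' @return A list of class `stability_report`: `frequency` (named vector),
#'   `kuncheva_mean` (`NA` when not applicable), `kuncheva_pairwise`
#'   (vector or `NULL`), `set_sizes`.
#' @export
selection_stability <- function(cv, candidates = NULL) {
  if (is.null(candidates)) candidates <- cv$strategy$candidates
  sets <- lapply(cv$fits, `[[`, "selected")
  freq <- vapply(candidates, function(nm)
    mean(vapply(sets, function(s) nm %in% s, logical(1))), numeric(1))
  sizes <- vapply(sets, length, numeric(1))
  N <- length(candidates)
  ki_pair <- NULL; ki_mean <- NA_real_
  if (length(unique(sizes)) == 1 && sizes[1] > 0 && sizes[1] < N &&
      length(sets) >= 2) {
    pairs <- utils::combn(length(sets), 2)
    ki_pair <- vapply(seq_len(ncol(pairs)), function(j)
      kuncheva_index(sets[[pairs[1, j]]], sets[[pairs[2, j]]], N),
      numeric(1))
    ki_mean <- mean(ki_pair)
  }
  structure(list(frequency = freq, kuncheva_mean = ki_mean,
                 kuncheva_pairwise = ki_pair, set_sizes = sizes),
            class = "stability_report")
}

#' Per-covariate selection frequency
#'
#' Fraction of (repetition, fold) fits in which each candidate covariate
#' carried a nonzero coefficient. Covariates absent from the candidate
#' list get frequency 0.
#'
#' @param cv A `cv_result`.
#' @param candidates Covariate names to report on.
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
selection_frequency <- function(cv, candidates = NULL) {
  if (is.null(candidates)) candidates <- cv$strategy$candidates
  selection_stability(cv, candidates)$frequency
}

#' Residual association of survival with an omitted covariate
#'
#' For every training-fold fit, Martingale residuals
#' \eqn{m_i = \delta_i - \hat\Lambda_0(T_i) e^{Z_i\hat\beta}} are computed
#' for the training-fold patients (recorded during [run_cv()]); per
#' patient they are averaged across all folds and repetitions in which the
#' patient served in a training fold. Association with the omitted
#' covariate is summarized by a Spearman rank-correlation test, plus a
#' lowess smooth of residual vs covariate for plotting.
#'
#' @param cohort A `survival_cohort`.
#' @param cv A `cv_result` whose strategy excluded `omitted` from its
#'   candidates.
#' @param omitted Name of the omitted covariate (must be a cohort column,
#'   must not be among the strategy's candidates).
#' @return A list of class `omitted_martingale_report`: `patient_id`,
#'   `avg_residual`, `covariate`, `spearman_rho`, `p_value`, `smooth`
#'   (data.frame x, fitted).
#' @export
omitted_martingale <- function(cohort, cv, omitted) {
  if (omitted %in% cv$strategy$candidates)
    stop("'", omitted, "' is among the strategy's candidates, not omitted")
  if (!omitted %in% colnames(cohort$covariates))
    stop("omitted covariate '", omitted, "' not found in the cohort")
  res <- cv$residuals
  avg <- tapply(res$residual, res$patient_id, mean)
  ids <- names(avg)
  cov_val <- cohort$covariates[match(ids, cohort$patient_id), omitted]
  ct <- suppressWarnings(
    stats::cor.test(cov_val, as.numeric(avg), method = "spearman"))
  lo <- stats::lowess(cov_val, as.numeric(avg))
  structure(list(patient_id = ids, avg_residual = as.numeric(avg),
                 covariate = cov_val, omitted = omitted,
                 spearman_rho = unname(ct$estimate),
                 p_value = ct$p.value,
                 smooth = data.frame(x = lo$x, fitted = lo$y)),
            class = "omitted_martingale_report")
}

#' Does sensitivity or specificity depend on an omitted covariate?
#'
#' For each repetition and each linear-predictor cutoff c, two logistic
#' models are fitted on patients with known vital status at `t` (patients
#' censored before `t` are excluded): among patients dead by `t`,
#' \eqn{logit P(M_i > c) = \beta_0 + Z_i\beta^{sens}} (does the omitted
#' covariate drive correct classification of the deceased?), and among
#' patients alive after `t`,
#' \eqn{logit P(M_i \le c) = \beta_0 + Z_i\beta^{spec}}. Odds ratios, Wald
#' p-values, the per-cutoff proportion of p < 0.05, and the (sens, spec)
#' pair each cutoff implies are reported. Raw p-values are returned with
#' no multiplicity correction: this is a screening indicator, not a formal
#' test.
#'
#' @param cohort A `survival_cohort`.
#' @param cv A `cv_result` (pooled test-fold linear predictors per
#'   repetition are the markers).
#' @param omitted Omitted covariate name.
#' @param t Evaluation day.
#' @param cutoffs Cutoff grid on the linear predictor; default the deciles
#'   of the pooled linear predictor excluding the extreme deciles
#'   (10%..90%).
#' @return A list of class `omitted_sens_spec_report` with a long
#'   data.frame `results` (repetition, cutoff, side, or, p_value, n,
#'   reason) and a per-cutoff summary `by_cutoff` (proportion of p < 0.05,
#'   implied sens/spec).
#' @export
omitted_sens_spec_models <- function(cohort, cv, omitted, t,
                                     cutoffs = NULL) {
  if (omitted %in% cv$strategy$candidates)
    stop("'", omitted, "' is among the strategy's candidates, not omitted")
  rec <- cv$records
  zc <- cohort$covariates[match(rec$patient_id, cohort$patient_id), omitted]
  if (is.null(cutoffs))
    cutoffs <- unique(stats::quantile(rec$lp, probs = seq(0.1, 0.9, 0.1),
                                      names = FALSE))
  known <- (rec$time <= t & rec$event == 1) | rec$time > t
  fit_cell <- function(y, z) {
    if (length(unique(y)) < 2)
      return(list(or = NA_real_, p = NA_real_, reason = "single-class response"))
    fit <- tryCatch(
      stats::glm(y ~ z, family = stats::binomial()),
      warning = function(w) w, error = function(e) e)
    if (inherits(fit, "condition"))
      return(list(or = NA_real_, p = NA_real_,
                  reason = "separation or non-convergence"))
    s <- summary(fit)$coefficients
    if (nrow(s) < 2 || abs(s["z", "Estimate"]) > 15)
      return(list(or = NA_real_, p = NA_real_, reason = "separation"))
    list(or = exp(s["z", "Estimate"]), p = s["z", "Pr(>|z|)"], reason = NA)
  }
  rows <- list()
  for (r in sort(unique(rec$repetition))) {
    idx <- which(rec$repetition == r & known)
    dead <- rec$time[idx] <= t & rec$event[idx] == 1
    for (cc in cutoffs) {
      hi <- rec$lp[idx] > cc
      cell_s <- fit_cell(as.numeric(hi[dead]), zc[idx][dead])
      cell_p <- fit_cell(as.numeric(!hi[!dead]), zc[idx][!dead])
      rows[[length(rows) + 1]] <- data.frame(
        repetition = r, cutoff = cc,
        side = c("sensitivity", "specificity"),
        or = c(cell_s$or, cell_p$or),
        p_value = c(cell_s$p, cell_p$p),
        n = c(sum(dead), sum(!dead)),
        sens = mean(hi[dead]), spec = mean(!hi[!dead]),
        reason = c(cell_s$reason, cell_p$reason),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  by_cutoff <- do.call(rbind, lapply(split(results,
                                           list(results$cutoff, results$side)),
    function(d) data.frame(cutoff = d$cutoff[1], side = d$side[1],
                           prop_p_below_05 = mean(d$p_value < 0.05,
                                                  na.rm = TRUE),
                           mean_sens = mean(d$sens), mean_spec = mean(d$spec),
                           n_missing = sum(is.na(d$p_value)))))
  rownames(by_cutoff) <- NULL
  structure(list(results = results, by_cutoff = by_cutoff,
                 omitted = omitted, t = t, cutoffs = cutoffs),
            class = "omitted_sens_spec_report")
}
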