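#' Define a model-building strategy
#'
#' A strategy is one row of the model catalogue: a variable-selection
#' method, a functional form for continuous covariates, the survival model
#' (always Cox here) and an optional penalty with its tuning parameter.
#' Penalized strategies may additionally request an unpenalized refit on the
#' selected covariates (the selection-then-refit "Lasso_Cox" family).
#'
#' @param name Strategy label used in reports (e.g. `"Lasso_Cox-4"`).
#' @param selection One of `"none"`, `"univariate"`, `"backward_aic"`,
#'   `"mfp"`, `"l1"`, `"adaptive_l1"`, `"scad"`. `"none"` with an empty
#'   candidate set is the null model.
#' @param candidates Character vector of candidate covariate names offered
#'   to the strategy (columns of the cohort covariate matrix).
#' @param functional `"linear"` or `"fractional_polynomial"`. Dichotomized
#'   variants are expressed by naming `<x>_Fac` columns among `candidates`.
#' @param fp_alpha Significance level controlling fractional-polynomial
#'   flexibility (FP2 vs simpler forms); conventional grid
#'   0.05/0.1/0.2/0.3/0.4.
#' @param mfp_select Significance level of the MFP exclusion test;
#'   conventional grid 0.05/0.10/0.15 (larger = less stringent selection).
#' @param penalty_lambda Penalty strength for the penalized families, on
#'   the standardized-covariate partial-log-likelihood scale; grid
#'   0.01/0.1/1/10/100 (larger = sparser).
#' @param refit_unpenalized If `TRUE`, the penalized fit is used for
#'   selection only and coefficients come from an unpenalized Cox refit.
#' @return An object of class `model_strategy`.
#' @export
model_strategy <- function(name, selection = c("none", "univariate",
                                               "backward_aic", "mfp", "l1",
                                               "adaptive_l1", "scad"),
                           candidates = character(0),
                           functional = c("linear", "fractional_polynomial"),
                           fp_alpha = 0.05, mfp_select = 0.05,
                           penalty_lambda = 1, refit_unpenalized = FALSE) {
  selection <- match.arg(selection)
  functional <- match.arg(functional)
  stopifnot(penalty_lambda >= 0, fp_alpha > 0, fp_alpha < 1,
            mfp_select > 0, mfp_select < 1)
  structure(list(name = name, selection = selection,
                 candidates = candidates, functional = functional,
                 fp_alpha = fp_alpha, mfp_select = mfp_select,
                 penalty_lambda = penalty_lambda,
                 refit_unpenalized = refit_unpenalized),
            class = "model_strategy")
}

# ---- fitted model container --------------------------------------------

# center = mean training-set Z beta; linear predictors are reported
# centered at the training mean (coxph convention) so that pooled
# cross-fold comparisons are not degraded by fold-specific location
# shifts. Predicted survival is invariant to the centering.
new_fitted_cox <- function(coefficients, baseline, loglik, n_events,
                           se = NULL, pvalues = NULL, strategy_name = NULL,
                           fp_forms = NULL, center = 0) {
  structure(list(coefficients = coefficients,
                 selected = names(coefficients)[coefficients != 0],
                 baseline = baseline, loglik = loglik, n_events = n_events,
                 center = center,
                 se = se, pvalues = pvalues, strategy_name = strategy_name,
                 fp_forms = fp_forms),
            class = "fitted_cox")
}

#' @export
print.fitted_cox <- function(x, ...) {
  cat(sprintf("fitted_cox (%s): %d events, %d selected covariate(s)\n",
              if (is.null(x$strategy_name)) "unnamed" else x$strategy_name,
              x$n_events, length(x$selected)))
  if (length(x$selected))
    print(round(x$coefficients[x$selected], 4))
  invisible(x)
}

# Internal formula-based coxph call on a covariate matrix; Breslow ties
# throughout so the baseline-hazard estimator stays consistent with the
# partial likelihood.
coxph_on_matrix <- function(time, event, Z, init = NULL, iter_max = 25L) {
  d <- as.data.frame(Z)
  names(d) <- colnames(Z)
  d$.time <- time
  d$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(Z)), collapse = " + ")))
  ctl <- survival::coxph.control(iter.max = iter_max, eps = 1e-10)
  args <- list(fml, data = d, ties = "breslow", control = ctl)
  if (!is.null(init)) args$init <- init
  fit <- withCallingHandlers(
    do.call(survival::coxph, args),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop("Cox fit produced undefined coefficients (singular design)")
  names(fit$coefficients) <- colnames(Z)
  fit
}

#' Fit an unpenalized Cox proportional hazards model
#'
#' Maximizes the Breslow-ties partial likelihood and attaches the Breslow
#' estimate of the cumulative baseline hazard, so predicted survival
#' \eqn{\hat\pi(t|z) = \exp(-\hat\Lambda_0(t) e^{z\hat\beta})} is fully
#' determined by the returned object.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param Z Numeric covariate matrix with column names; may have zero
#'   columns, in which case the null model (all linear predictors 0,
#'   Nelson-Aalen baseline) is returned.
#' @return A `fitted_cox` object with coefficients, Wald standard errors
#'   and p-values, the Breslow baseline cumulative hazard, the partial
#'   log-likelihood at the estimate and the event count.
#' @export
fit_cox <- function(time, event, Z) {
  Z <- as.matrix(Z)
  if (sum(event) < 1) stop("no events in the data")
  if (ncol(Z) == 0) {
    bl <- breslow_cumhaz(numeric(0), time, event,
                         matrix(numeric(0), length(time), 0))
    return(new_fitted_cox(stats::setNames(numeric(0), character(0)), bl,
                          loglik = null_loglik(time, event),
                          n_events = sum(event)))
  }
  check_candidates(Z, colnames(Z))
  fit <- coxph_on_matrix(time, event, Z)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  pv <- 2 * stats::pnorm(-abs(beta / se))
  bl <- breslow_cumhaz(beta, time, event, Z)
  new_fitted_cox(beta, bl, loglik = fit$loglik[2], n_events = sum(event),
                 se = se, pvalues = pv,
                 center = mean(drop(Z[, names(beta), drop = FALSE] %*% beta)))
}

# Partial log-likelihood of the null model (Breslow ties): at beta = 0 the
# contribution of an event at t_j is -log(#at risk), d_j times.
null_loglik <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  ll <- 0
  for (tj in et) {
    d <- sum(time == tj & event == 1)
    ll <- ll - d * log(sum(time >= tj))
  }
  ll
}

# Breslow cumulative baseline hazard as a knot table; evaluated with
# cumhaz_at(). Lambda0(t) = sum_{tj <= t} d_j / sum_{i at risk} exp(lp_i).
breslow_cumhaz <- function(beta, time, event, Z) {
  lp <- if (length(beta)) drop(as.matrix(Z)[, names(beta), drop = FALSE] %*% beta)
        else rep(0, length(time))
  risk <- exp(lp)
  et <- sort(unique(time[event == 1]))
  inc <- vapply(et, function(tj) {
    sum(event == 1 & time == tj) / sum(risk[time >= tj])
  }, numeric(1))
  data.frame(time = et, cumhaz = cumsum(inc))
}

#' Breslow baseline cumulative hazard of a fitted model
#'
#' Recomputes \eqn{\hat\Lambda_0(t) = \sum_{t_j \le t} d_j / \sum_{i \in
#' R(t_j)} e^{Z_i\hat\beta}} on the supplied training data.
#'
#' @param fit A `fitted_cox`.
#' @param time,event,Z The training data the fit was produced from.
#' @return A data.frame of knots (`time`, `cumhaz`), nondecreasing, with
#'   \eqn{\hat\Lambda_0(0) = 0} implicitly (no knot before the first event).
#' @export
breslow_baseline <- function(fit, time, event, Z) {
  breslow_cumhaz(fit$coefficients, time, event, Z)
}

# Step-function evaluation of a cumulative hazard knot table.
cumhaz_at <- function(baseline, t) {
  if (nrow(baseline) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, baseline$time)
  c(0, baseline$cumhaz)[idx + 1]
}

#' Linear predictor of a fitted model
#'
#' @param fit A `fitted_cox`.
#' @param Z Covariate matrix containing at least the fitted covariates.
#' @return Numeric vector \eqn{Z\hat\beta - \bar{Z}_{train}\hat\beta},
#'   centered at the training-set mean (0 for the null model). The
#'   centering keeps pooled cross-fold score comparisons free of
#'   fold-specific location shifts and cancels in all predicted survival
#'   probabilities.
#' @export
linear_predictor <- function(fit, Z) {
  if (!length(fit$coefficients)) return(rep(0, nrow(Z)))
  miss <- setdiff(names(fit$coefficients), colnames(Z))
  if (length(miss))
    stop("covariate(s) missing from prediction data: ",
         paste(miss, collapse = ", "))
  drop(as.matrix(Z)[, names(fit$coefficients), drop = FALSE] %*%
         fit$coefficients) - fit$center
}

#' Predicted survival probability
#'
#' \eqn{\hat\pi(t|z) = \exp(-\hat\Lambda_0(t)\, e^{z\hat\beta})} using the
#' Breslow baseline stored in the fit. Nonincreasing in `t`, equal to 1 at
#' `t = 0`.
#'
#' @param fit A `fitted_cox`.
#' @param Z Covariate matrix (rows = patients).
#' @param t Vector of evaluation times (days).
#' @return Matrix of survival probabilities, patients x times.
#' @export
predict_survival <- function(fit, Z, t) {
  stopifnot(all(t >= 0))
  lp <- linear_predictor(fit, Z) + fit$center  # baseline is uncentered
  H0 <- cumhaz_at(fit$baseline, t)
  out <- exp(-outer(exp(lp), H0))
  dimnames(out) <- list(NULL, paste0("t", t))
  out
}

# ---- backward elimination by AIC ---------------------------------------

#' Backward elimination using the Akaike Information Criterion
#'
#' Starting from the full candidate model, repeatedly removes the single
#' covariate whose removal most decreases \eqn{AIC = -2\log PL + 2p};
#' stops when no removal decreases AIC. The returned AIC can never exceed
#' the full model's.
#'
#' @param time,event Survival outcome.
#' @param Z Covariate matrix.
#' @param candidates Candidate covariate names (default all columns).
#' @return A list with `selected` (character vector, possibly empty) and
#'   `fit` (the `fitted_cox` of the retained model).
#' @export
backward_aic <- function(time, event, Z, candidates = colnames(Z)) {
  current <- candidates
  fit <- fit_cox(time, event, Z[, current, drop = FALSE])
  aic <- -2 * fit$loglik + 2 * length(current)
  repeat {
    if (!length(current)) break
    trials <- lapply(seq_along(current), function(i) {
      keep <- current[-i]
      f <- fit_cox(time, event, Z[, keep, drop = FALSE])
      list(keep = keep, fit = f, aic = -2 * f$loglik + 2 * length(keep))
    })
    aics <- vapply(trials, `[[`, numeric(1), "aic")
    best <- which.min(aics)
    if (aics[best] < aic) {
      current <- trials[[best]]$keep
      fit <- trials[[best]]$fit
      aic <- aics[best]
    } else break
  }
  list(selected = current, fit = fit, aic = aic)
}

# ---- fractional polynomials --------------------------------------------

FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial transformation of a covariate
#'
#' Box-Tidwell style powers with the usual conventions: power `p != 0`
#' gives \eqn{x^p}, power 0 gives \eqn{\ln x}, and a repeated power
#' \eqn{(p, p)} gives \eqn{(x^p, x^p \ln x)}.
#'
#' @param x Strictly positive values (apply [fp_shift()] first if needed).
#' @param powers One or two powers from \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}.
#' @return A one- or two-column matrix of transformed values.
#' @export
fp_transform <- function(x, powers) {
  if (any(x <= 0)) stop("fractional polynomials require strictly positive values")
  stopifnot(length(powers) %in% 1:2)
  one <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1) {
    out <- matrix(one(powers[1]), ncol = 1)
    colnames(out) <- paste0("fp", powers[1])
  } else if (powers[1] == powers[2]) {
    b <- one(powers[1])
    out <- cbind(b, b * log(x))
    colnames(out) <- paste0("fp", powers[1], c("", ".ln"))
  } else {
    out <- cbind(one(powers[1]), one(powers[2]))
    colnames(out) <- paste0("fp", powers)
  }
  out
}

#' Positivity shift for fractional polynomials
#'
#' Returns the shift added to a covariate so that all values are strictly
#' positive: 0 when already positive, otherwise `-min(x)` plus the smallest
#' nonzero spacing of the sorted values (1 when all values are tied).
#'
#' @param x Numeric vector.
#' @return A single nonnegative shift.
#' @export
fp_shift <- function(x) {
  if (min(x) > 0) return(0)
  ux <- sort(unique(x))
  delta <- if (length(ux) > 1) min(diff(ux)) else 1
  -min(x) + delta
}

# all FP1 (8) and FP2 (36, unordered with repetition) power sets
fp1_sets <- function() as.list(FP_POWERS)
fp2_sets <- function() {
  out <- list()
  for (i in seq_along(FP_POWERS))
    for (j in i:length(FP_POWERS))
      out[[length(out) + 1]] <- c(FP_POWERS[i], FP_POWERS[j])
  out
}

# Build the design matrix for a set of per-covariate forms.
# forms: named list; each element list(type = "omit"|"linear"|"fp",
#   powers = ..., shift = ...).
fp_design <- function(Z, forms) {
  cols <- list()
  for (nm in names(forms)) {
    f <- forms[[nm]]
    if (f$type == "omit") next
    if (f$type == "linear") {
      m <- matrix(Z[, nm], ncol = 1)
      colnames(m) <- nm
    } else {
      m <- fp_transform(Z[, nm] + f$shift, f$powers)
      colnames(m) <- paste0(nm, ".", colnames(m))
    }
    cols[[length(cols) + 1]] <- m
  }
  if (!length(cols)) return(matrix(numeric(0), nrow(Z), 0))
  do.call(cbind, cols)
}

# Best-deviance FP fit for covariate nm given the other covariates' design.
best_fp_fit <- function(time, event, others, x_shifted, sets, prefix) {
  best <- NULL
  for (pw in sets) {
    m <- fp_transform(x_shifted, pw)
    colnames(m) <- paste0(prefix, ".", colnames(m))
    f <- tryCatch(fit_cox(time, event, cbind(others, m)),
                  error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$loglik > best$loglik)
      best <- list(loglik = f$loglik, powers = pw, fit = f)
  }
  best
}

#' Multivariable fractional polynomials: joint form and variable selection
#'
#' Implements the closed-test cycling procedure: for each continuous
#' covariate in turn (others held at their current forms), the best
#' two-term fractional polynomial (FP2) is compared against the null model
#' at level `mfp_select` (exclusion test, 4 df), then against the linear
#' form (3 df) and the best one-term FP1 (2 df) at level `fp_alpha`, via
#' partial-likelihood-ratio chi-square tests with the conventional FP
#' degrees of freedom. Binary or few-valued covariates only undergo the
#' 1-df in/out test. Cycling stops when the selected set and forms
#' stabilize or after 5 cycles.
#'
#' @param time,event Survival outcome.
#' @param Z Covariate matrix.
#' @param candidates Candidate covariate names.
#' @param fp_alpha Level of the FP2-vs-linear and FP2-vs-FP1 tests
#'   (flexibility).
#' @param mfp_select Level of the exclusion test (larger = less stringent
#'   selection).
#' @return A list with `forms` (per-covariate chosen form), `selected`
#'   (covariates retained), `fit` (the `fitted_cox` on the transformed
#'   design) and `design_forms` for rebuilding the design on new data.
#' @export
mfp_select <- function(time, event, Z, candidates = colnames(Z),
                       fp_alpha = 0.05, mfp_select = 0.05) {
  forms <- stats::setNames(vector("list", length(candidates)), candidates)
  n_unique <- vapply(candidates, function(nm) length(unique(Z[, nm])),
                     numeric(1))
  for (nm in candidates)
    forms[[nm]] <- list(type = "linear", shift = fp_shift(Z[, nm]))
  for (cycle in seq_len(5)) {
    prev <- forms
    for (nm in candidates) {
      others_forms <- forms[setdiff(candidates, nm)]
      others <- fp_design(Z, others_forms)
      ll_null <- fit_cox(time, event, others)$loglik
      x_sh <- Z[, nm] + forms[[nm]]$shift
      lin_fit <- tryCatch({
        m <- matrix(Z[, nm], ncol = 1); colnames(m) <- nm
        fit_cox(time, event, cbind(others, m))
      }, error = function(e) NULL)
      if (n_unique[nm] <= 3) {
        # binary / few-valued: in-out test only, 1 df
        keep <- !is.null(lin_fit) &&
          2 * (lin_fit$loglik - ll_null) >
            stats::qchisq(1 - mfp_select, df = 1)
        forms[[nm]] <- if (keep)
          list(type = "linear", shift = forms[[nm]]$shift)
        else list(type = "omit", shift = forms[[nm]]$shift)
        next
      }
      fp2 <- best_fp_fit(time, event, others, x_sh, fp2_sets(), nm)
      if (is.null(fp2)) { # inner fits failed: keep linear this cycle
        forms[[nm]] <- list(type = "linear", shift = forms[[nm]]$shift)
        next
      }
      # closed test, FP2 carries 4 df, FP1 2 df, linear 1 df
      if (2 * (fp2$loglik - ll_null) <= stats::qchisq(1 - mfp_select, df = 4)) {
        forms[[nm]] <- list(type = "omit", shift = forms[[nm]]$shift)
        next
      }
      if (!is.null(lin_fit) &&
          2 * (fp2$loglik - lin_fit$loglik) <=
            stats::qchisq(1 - fp_alpha, df = 3)) {
        forms[[nm]] <- list(type = "linear", shift = forms[[nm]]$shift)
        next
      }
      fp1 <- best_fp_fit(time, event, others, x_sh, fp1_sets(), nm)
      if (!is.null(fp1) &&
          2 * (fp2$loglik - fp1$loglik) <= stats::qchisq(1 - fp_alpha, df = 2)) {
        forms[[nm]] <- list(type = "fp", powers = fp1$powers,
                            shift = forms[[nm]]$shift)
      } else {
        forms[[nm]] <- list(type = "fp", powers = fp2$powers,
                            shift = forms[[nm]]$shift)
      }
    }
    if (identical(forms, prev)) break
  }
  design <- fp_design(Z, forms)
  fit <- fit_cox(time, event, design)
  selected <- names(forms)[vapply(forms, function(f) f$type != "omit",
                                  logical(1))]
  list(forms = forms, selected = selected, fit = fit, design_forms = forms)
}

# ---- penalized Cox families --------------------------------------------

# Partial log-likelihood at a fixed beta (Breslow ties).
partial_loglik_at <- function(beta, time, event, Z) {
  if (!length(beta) || all(beta == 0)) return(null_loglik(time, event))
  lp <- drop(as.matrix(Z)[, names(beta), drop = FALSE] %*% beta)
  et <- sort(unique(time[event == 1]))
  ll <- 0
  for (tj in et) {
    idx <- time == tj & event == 1
    ll <- ll + sum(lp[idx]) - sum(idx) * log(sum(exp(lp[time >= tj])))
  }
  ll
}

# SCAD penalty derivative (Fan & Li), a = 3.7.
scad_deriv <- function(theta, lambda, a = 3.7) {
  ifelse(theta <= lambda, lambda,
         pmax(a * lambda - theta, 0) / (a - 1))
}

glmnet_cox <- function(time, event, Z, alpha, lambda_g, penalty_factor) {
  y <- survival::Surv(time, event)
  # warm-started decreasing path ending exactly at the target lambda
  lam_seq <- lambda_g * c(64, 32, 16, 8, 4, 2, 1)
  fit <- glmnet::glmnet(Z, y, family = "cox", alpha = alpha,
                        standardize = TRUE, thresh = 1e-12,
                        lambda = lam_seq,
                        penalty.factor = penalty_factor)
  as.numeric(stats::coef(fit, s = lambda_g))
}

#' Penalized Cox models: lasso, adaptive lasso, SCAD
#'
#' Maximizes the penalized partial log-likelihood
#' \eqn{\log PL(\beta) - \lambda \sum_j w_j |\beta_j|} with covariates
#' standardized to unit variance internally and coefficients reported on
#' the original scale. For the lasso \eqn{w_j = 1}; for the adaptive lasso
#' \eqn{w_j \propto 1/|\tilde\beta_j|} from an initial lightly
#' ridge-penalized fit, rescaled to mean 1 so that \eqn{\lambda} stays
#' comparable with the plain lasso (the weight scale is otherwise
#' arbitrary) — large coefficients are shrunk less; SCAD is solved by local
#' linear approximation (iterated weighted lasso with SCAD-derivative
#' weights, a = 3.7), leaving large coefficients nearly unpenalized.
#' Exact zeros mark unselected covariates.
#'
#' @param time,event Survival outcome.
#' @param Z Covariate matrix.
#' @param penalty `"l1"`, `"adaptive_l1"` or `"scad"`.
#' @param lambda Penalty strength \eqn{\lambda \ge 0} (grid
#'   0.01/0.1/1/10/100 in the model catalogue; larger = sparser).
#' @return A `fitted_cox`; `selected` holds the names with nonzero
#'   coefficients and the Breslow baseline is computed at the penalized
#'   coefficients.
#' @export
fit_penalized_cox <- function(time, event, Z,
                              penalty = c("l1", "adaptive_l1", "scad"),
                              lambda) {
  penalty <- match.arg(penalty)
  Z <- as.matrix(Z)
  stopifnot(sum(event) >= 1, lambda >= 0, ncol(Z) >= 1)
  check_candidates(Z, colnames(Z))
  n <- length(time)
  sds <- apply(Z, 2, stats::sd)
  # glmnet's Cox objective is (1/n) logPL - lambda_g * sum pf_j |beta_j|,
  # with penalty factors rescaled to mean 1; lambda_g = lambda * mean(w)/n
  # recovers logPL - lambda * sum w_j |beta_j|.
  # normalize = TRUE rescales weights to mean 1 (their scale is arbitrary
  # and absorbed into lambda, as for the adaptive lasso, keeping lambda
  # comparable across penalties); normalize = FALSE keeps the absolute
  # weight scale (needed for SCAD, where w_j = p'(|b_j|)/lambda in [0,1]).
  fit_weighted <- function(w, normalize = TRUE) {
    lam_g <- if (normalize) lambda / n else lambda * mean(w) / n
    if (all(w < 1e-10) || lam_g < 1e-12) {
      # penalty vanished: plain unpenalized fit
      return(fit_cox(time, event, Z)$coefficients)
    }
    stats::setNames(
      glmnet_cox(time, event, Z, alpha = 1, lambda_g = lam_g,
                 penalty_factor = w),
      colnames(Z))
  }
  if (penalty == "l1") {
    beta <- fit_weighted(rep(1, ncol(Z)))
  } else if (penalty == "adaptive_l1") {
    ridge <- stats::setNames(
      glmnet_cox(time, event, Z, alpha = 0, lambda_g = 0.01 / n,
                 penalty_factor = rep(1, ncol(Z))), colnames(Z))
    bstd <- abs(ridge * sds)                 # standardized-scale magnitudes
    w <- 1 / pmax(bstd, 1e-8)
    w <- pmin(w, 1e8)
    beta <- fit_weighted(w)
  } else {
    lam_std <- lambda / n                     # per-observation scale
    beta <- fit_weighted(rep(1, ncol(Z)))     # LLA start: lasso solution
    for (it in 1:3) {
      bstd <- abs(beta * sds)
      w <- scad_deriv(bstd, lam_std) / lam_std
      beta_new <- fit_weighted(w, normalize = FALSE)
      if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
      beta <- beta_new
    }
  }
  bl <- breslow_cumhaz(beta[beta != 0], time, event, Z)
  new_fitted_cox(beta, bl,
                 loglik = partial_loglik_at(beta[beta != 0], time, event, Z),
                 n_events = sum(event),
                 center = mean(drop(Z %*% beta)))
}

#' Unpenalized refit on a selected covariate set
#'
#' The second stage of the selection-then-refit families: an ordinary Cox
#' fit restricted to the selected covariates (no shrinkage). An empty
#' selection yields the null model whose predictions come from the baseline
#' hazard alone.
#'
#' @param time,event Survival outcome.
#' @param Z Covariate matrix.
#' @param selected Character vector of selected covariate names (possibly
#'   empty).
#' @return A `fitted_cox`.
#' @export
refit_selected <- function(time, event, Z, selected) {
  fit_cox(time, event, as.matrix(Z)[, selected, drop = FALSE])
}

# ---- strategy dispatch --------------------------------------------------

# Fit one model strategy on a training slice; returns a fitted_cox plus a
# predictor closure mapping new covariate matrices to (lp, survival).
fit_strategy <- function(strategy, time, event, Z) {
  cand <- strategy$candidates
  if (length(cand)) check_candidates(Z, cand)
  forms <- NULL
  if (strategy$selection == "none") {
    fit <- fit_cox(time, event, Z[, cand, drop = FALSE])
  } else if (strategy$selection == "univariate") {
    stopifnot(length(cand) == 1)
    fit <- fit_cox(time, event, Z[, cand, drop = FALSE])
  } else if (strategy$selection == "backward_aic") {
    if (strategy$functional == "fractional_polynomial") {
      mfp <- mfp_select(time, event, Z, cand,
                        fp_alpha = strategy$fp_alpha, mfp_select = 0.999999)
      forms <- mfp$design_forms   # forms chosen, selection left to AIC
      D <- fp_design(Z, forms)
      ba <- backward_aic(time, event, D)
      fit <- ba$fit
      forms <- prune_forms(forms, ba$selected)
      fit <- fit_cox(time, event, fp_design(Z, forms))
    } else {
      ba <- backward_aic(time, event, Z[, cand, drop = FALSE])
      fit <- ba$fit
    }
  } else if (strategy$selection == "mfp") {
    mfp <- mfp_select(time, event, Z, cand,
                      fp_alpha = strategy$fp_alpha,
                      mfp_select = strategy$mfp_select)
    fit <- mfp$fit
    forms <- mfp$design_forms
  } else { # penalized families
    pen <- switch(strategy$selection, l1 = "l1",
                  adaptive_l1 = "adaptive_l1", scad = "scad")
    fit <- fit_penalized_cox(time, event, Z[, cand, drop = FALSE],
                             penalty = pen,
                             lambda = strategy$penalty_lambda)
    if (strategy$refit_unpenalized)
      fit <- refit_selected(time, event, Z, fit$selected)
  }
  fit$strategy_name <- strategy$name
  fit$fp_forms <- forms
  # selection bookkeeping on the original candidate scale
  sel_orig <- if (is.null(forms)) fit$selected
    else names(forms)[vapply(forms, function(f) f$type != "omit", logical(1))]
  list(fit = fit, forms = forms, selected_original = sel_orig)
}

prune_forms <- function(forms, kept_design_cols) {
  for (nm in names(forms)) {
    if (forms[[nm]]$type == "omit") next
    cols <- colnames(fp_design(matrix(2, 1, 1,
                                      dimnames = list(NULL, nm)),
                               forms[nm]))
    if (!any(cols %in% kept_design_cols))
      forms[[nm]] <- list(type = "omit", shift = forms[[nm]]$shift)
  }
  forms
}

# Predict lp and survival from a strategy fit on new data, applying the
# training-fold FP forms when present.
strategy_predict <- function(sfit, Znew, times) {
  D <- if (is.null(sfit$forms)) Znew else fp_design(Znew, sfit$forms)
  lp <- linear_predictor(sfit$fit, D)
  surv <- predict_survival(sfit$fit, D, times)
  list(lp = lp, surv = surv)
}
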