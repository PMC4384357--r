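#' Build a catalogue of model-building strategies
#'
#' Assembles the standard strategy families over a candidate covariate
#' set: one univariate Cox model per candidate, backward-AIC elimination
#' (optionally with fractional-polynomial forms over a flexibility grid),
#' the MFP procedure over a (select, alpha) grid, and the lasso / adaptive
#' lasso / SCAD penalized families over a penalty grid, each optionally
#' paired with a selection-then-refit variant.
#'
#' @param candidates Candidate covariate names.
#' @param families Subset of `c("uni", "bw_aic", "bw_aic_fp", "mfp",
#'   "lasso", "alasso", "scad", "lasso_cox")`.
#' @param lambdas Penalty grid for the penalized families (larger =
#'   sparser; suffix in the strategy name is the grid index).
#' @param fp_alphas Flexibility grid for the FP-based families.
#' @param mfp_selects Selection-stringency grid for MFP.
#' @return A named list of [model_strategy()] objects.
#' @export
strategy_catalogue <- function(candidates,
                               families = c("uni", "lasso", "lasso_cox"),
                               lambdas = c(0.01, 0.1, 1, 10, 100),
                               fp_alphas = c(0.05, 0.1, 0.2, 0.3, 0.4),
                               mfp_selects = c(0.05, 0.10, 0.15)) {
  out <- list()
  add <- function(s) out[[s$name]] <<- s
  if ("uni" %in% families)
    for (i in seq_along(candidates))
      add(model_strategy(paste0("Uni_Cox-", i), "univariate",
                         candidates[i]))
  if ("bw_aic" %in% families)
    add(model_strategy("bwAIC_Cox", "backward_aic", candidates))
  if ("bw_aic_fp" %in% families)
    for (i in seq_along(fp_alphas))
      add(model_strategy(paste0("bwAIC_FP_Cox-", i), "backward_aic",
                         candidates, functional = "fractional_polynomial",
                         fp_alpha = fp_alphas[i]))
  if ("mfp" %in% families) {
    i <- 0
    for (s in mfp_selects) for (a in fp_alphas) {
      i <- i + 1
      add(model_strategy(paste0("MFP_Cox-", i), "mfp", candidates,
                         functional = "fractional_polynomial",
                         fp_alpha = a, mfp_select = s))
    }
  }
  pen <- c(lasso = "l1", alasso = "adaptive_l1", scad = "scad")
  lab <- c(lasso = "Lasso", alasso = "aLasso", scad = "SCAD")
  for (fam in intersect(names(pen), families))
    for (i in seq_along(lambdas))
      add(model_strategy(paste0(lab[fam], "-", i), pen[fam], candidates,
                         penalty_lambda = lambdas[i]))
  if ("lasso_cox" %in% families)
    for (i in seq_along(lambdas))
      add(model_strategy(paste0("Lasso_Cox-", i), "l1", candidates,
                         penalty_lambda = lambdas[i],
                         refit_unpenalized = TRUE))
  out
}

#' Rank and prune a model shortlist
#'
#' First retains every model whose primary indicator is within `tolerance`
#' of the best; among those, ranks lexicographically by (higher stability,
#' lower optimism, fewer omitted-covariate flags), then keeps at most one
#' model per (selection family, complexity level) — near-duplicate models
#' from the same family at the same penalty level carry no extra
#' information.
#'
#' @param models A data.frame with columns `model`, `primary` (the
#'   shortlist indicator, larger is better), `stability`, `optimism`,
#'   `family`, `complexity`, and optionally `omitted_flags`.
#' @param tolerance Retention band below the best primary value
#'   (default 0.02).
#' @return The retained rows, ranked, with a `rank` column.
#' @export
shortlist <- function(models, tolerance = 0.02) {
  stopifnot(nrow(models) > 0)
  if (is.null(models$omitted_flags)) models$omitted_flags <- 0
  best <- max(models$primary, na.rm = TRUE)
  keep <- models[!is.na(models$primary) &
                   models$primary >= best - tolerance, , drop = FALSE]
  ord <- order(-keep$stability, keep$optimism, keep$omitted_flags,
               -keep$primary)
  keep <- keep[ord, , drop = FALSE]
  dup <- duplicated(paste(keep$family, keep$complexity))
  keep <- keep[!dup, , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}

strategy_family <- function(s) {
  paste0(s$selection,
         if (s$functional == "fractional_polynomial") "_fp" else "",
         if (isTRUE(s$refit_unpenalized)) "_refit" else "")
}

strategy_complexity <- function(s) {
  if (s$selection %in% c("l1", "adaptive_l1", "scad"))
    format(s$penalty_lambda)
  else if (s$selection == "mfp")
    paste0("sel", s$mfp_select)
  else if (s$selection == "univariate") s$candidates[1]
  else "-"
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [run_pipeline()]'s arguments: either a `cohort_file`
#' or a `generator` block (fields of [generator_config()]), a `strategies`
#' block (`candidates` plus `families`/`lambdas` for
#' [strategy_catalogue()]), and scalar settings (`k`, `n_rep`, `seed`,
#' `resampling`, `time_grid`, `eval_time`, `omitted`,
#' `shortlist_tolerance`, `bootstrap_B`).
#'
#' @param path Path to a YAML file.
#' @return A named list usable as `config` in [run_pipeline()].
#' @export
load_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full model-building workflow
#'
#' Generate-or-load the cohort, cross-validate every strategy under the
#' requested resampling strategies, aggregate performance with both the
#' pooling and the averaging method on both score types, compute optimism
#' and selection stability, shortlist the models, refit the top model on
#' the full training set, evaluate it on the test set with bootstrap
#' confidence intervals, and (optionally) screen omitted covariates.
#' All outputs are written as CSV/JSON into `out_dir`; the run is a pure
#' function of the configuration and its seed.
#'
#' @param config A named list (or the result of [load_run_config()]) with:
#'   `cohort` (a `survival_cohort`) or `cohort_file` or `generator`
#'   (a [generator_config()] or its argument list); `strategies` (named
#'   list of [model_strategy()] or a list with `candidates` + catalogue
#'   arguments); `k` (folds, default 5), `n_rep` (default 20), `seed`
#'   (master seed), `resampling` (subset of c("A","B")), `time_grid`
#'   (default `c(7, 14)`), `eval_time` (primary day, default 7), `omitted`
#'   (covariate names to screen), `shortlist_tolerance` (default 0.02),
#'   `bootstrap_B` (default 1000).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `cohort`,
#'   `performance`, `frequency`, `optimism`, `shortlist`, `final`,
#'   `validation`, `omitted_reports`, `log`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  k <- config$k %||% 5L
  n_rep <- config$n_rep %||% 20L
  resampling <- config$resampling %||% c("A", "B")
  time_grid <- config$time_grid %||% c(7, 14)
  eval_time <- config$eval_time %||% 7
  tol <- config$shortlist_tolerance %||% 0.02

  # --- cohort -----------------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
  } else if (!is.null(config$cohort_file)) {
    cohort <- read_cohort(config$cohort_file)
  } else {
    gen <- config$generator
    if (!inherits(gen, "generator_config")) {
      if (is.null(gen$seed)) gen$seed <- seed
      gen <- do.call(generator_config, gen)
    }
    cohort <- generate_cohort(gen)$cohort
  }
  if (!is.null(config$dichotomize)) {
    specs <- lapply(names(config$dichotomize), function(nm)
      covariate_spec(nm, "clinical_continuous",
                     dichotomize_at = config$dichotomize[[nm]]))
    cohort <- add_dichotomized(cohort, specs)
  }
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  # --- strategies -------------------------------------------------------
  strategies <- config$strategies
  if (!is.null(strategies$candidates) && is.character(strategies$candidates)) {
    strategies <- do.call(strategy_catalogue, strategies)
  }
  stopifnot(length(strategies) >= 1)

  # --- cross-validation -------------------------------------------------
  perf_rows <- list(); freq_rows <- list(); opt_rows <- list()
  log_rows <- list(); cv_store <- list()
  tcol <- paste0("t", eval_time)
  for (rs in resampling) {
    plan <- if (rs == "A")
      make_folds_stratified(cohort, k, n_rep, seed + 11L)
    else make_folds_batchwise(cohort, k, n_rep, seed + 13L)
    for (s in strategies) {
      cv <- run_cv(cohort, plan, s, time_grid)
      cv_store[[paste(rs, s$name)]] <- cv
      if (!is.null(cv$skipped))
        log_rows[[length(log_rows) + 1]] <-
          cbind(strategy = s$name, resampling = rs, cv$skipped)
      for (agg in c("pooled", "averaged"))
        for (sc in c("linear_predictor", "predicted_survival")) {
          auc <- suppressWarnings(
            aggregate_cv(cv, "td_auc", sc, agg, time_grid))
          perf_rows[[length(perf_rows) + 1]] <- data.frame(
            model = s$name, resampling = rs, indicator = "td_auc",
            score_type = sc, aggregation = agg,
            time = time_grid, value = as.numeric(auc$values),
            sd_rep = apply(auc$per_repetition, 2, stats::sd))
        }
      ci <- suppressWarnings(
        aggregate_cv(cv, "c_index", "linear_predictor", "pooled"))
      perf_rows[[length(perf_rows) + 1]] <- data.frame(
        model = s$name, resampling = rs, indicator = "c_index",
        score_type = "linear_predictor", aggregation = "pooled",
        time = NA_real_, value = as.numeric(ci$values),
        sd_rep = stats::sd(ci$per_repetition))
      op <- optimism(cv, "td_auc", time_grid)
      opt_rows[[length(opt_rows) + 1]] <- data.frame(
        model = s$name, resampling = rs, time = time_grid,
        apparent = as.numeric(op$apparent),
        validated = as.numeric(op$validated),
        optimism = as.numeric(op$optimism))
      fr <- selection_frequency(cv)
      freq_rows[[length(freq_rows) + 1]] <- data.frame(
        model = s$name, resampling = rs, covariate = names(fr),
        frequency = as.numeric(fr))
    }
  }
  performance <- do.call(rbind, perf_rows)
  optim_tab <- do.call(rbind, opt_rows)
  freq_tab <- do.call(rbind, freq_rows)
  utils::write.csv(performance, file.path(out_dir, "performance.csv"),
                   row.names = FALSE)
  utils::write.csv(optim_tab, file.path(out_dir, "optimism.csv"),
                   row.names = FALSE)
  utils::write.csv(freq_tab, file.path(out_dir, "selection_frequency.csv"),
                   row.names = FALSE)

  # --- shortlist: primary = most conservative scheme available ----------
  prim_rs <- if ("B" %in% resampling) "B" else resampling[1]
  prim <- performance[performance$resampling == prim_rs &
                        performance$indicator == "td_auc" &
                        performance$score_type == "linear_predictor" &
                        performance$aggregation == "pooled" &
                        performance$time == eval_time, ]
  sl_in <- do.call(rbind, lapply(strategies, function(s) {
    cv <- cv_store[[paste(prim_rs, s$name)]]
    st <- selection_stability(cv)
    stab <- if (!is.na(st$kuncheva_mean)) st$kuncheva_mean
            else mean(pmax(st$frequency, 1 - st$frequency))
    op <- optim_tab[optim_tab$model == s$name &
                      optim_tab$resampling == prim_rs &
                      optim_tab$time == eval_time, "optimism"]
    data.frame(model = s$name,
               primary = prim$value[prim$model == s$name][1],
               stability = stab, optimism = op[1],
               family = strategy_family(s),
               complexity = strategy_complexity(s),
               stringsAsFactors = FALSE)
  }))
  rownames(sl_in) <- NULL
  sl <- shortlist(sl_in, tolerance = tol)
  utils::write.csv(sl, file.path(out_dir, "shortlist.csv"),
                   row.names = FALSE)

  # --- omitted-covariate screening on the top model ---------------------
  omitted_reports <- list()
  top_name <- sl$model[1]
  top_strategy <- strategies[[top_name]]
  for (om in config$omitted %||% character(0)) {
    cv <- cv_store[[paste(prim_rs, top_name)]]
    mg <- omitted_martingale(cohort, cv, om)
    ss <- omitted_sens_spec_models(cohort, cv, om, t = eval_time)
    omitted_reports[[om]] <- list(martingale = mg, sens_spec = ss)
    utils::write.csv(ss$by_cutoff,
                     file.path(out_dir, paste0("omitted_", om, ".csv")),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(patient_id = mg$patient_id, covariate = mg$covariate,
                 avg_residual = mg$avg_residual),
      file.path(out_dir, paste0("omitted_", om, "_residuals.csv")),
      row.names = FALSE)
  }

  # --- final fit and test validation ------------------------------------
  ff <- final_fit(cohort, top_strategy)
  utils::write.csv(ff$hr_table, file.path(out_dir, "final_hr.csv"),
                   row.names = FALSE)
  validation <- NULL
  if (any(cohort$role == "test")) {
    ci_tab <- bootstrap_ci(ff, cohort, "td_auc", time_grid,
                           B = config$bootstrap_B %||% 1000,
                           seed = seed + 17L)
    utils::write.csv(ci_tab, file.path(out_dir, "test_validation.csv"),
                     row.names = FALSE)
    validation <- ci_tab
  }

  log_tab <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(strategy = character(0), resampling = character(0),
               repetition = integer(0), fold = integer(0),
               reason = character(0))
  utils::write.csv(log_tab, file.path(out_dir, "log.csv"),
                   row.names = FALSE)
  meta <- list(seed = seed, k = k, n_rep = n_rep, resampling = resampling,
               time_grid = time_grid, eval_time = eval_time,
               n_strategies = length(strategies),
               top_model = top_name)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, performance = performance,
                 frequency = freq_tab, optimism = optim_tab,
                 shortlist = sl, final = ff, validation = validation,
                 omitted_reports = omitted_reports, log = log_tab,
                 cv = cv_store))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
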