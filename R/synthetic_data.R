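#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the septic-shock study design the package targets:
#' 156 training and 95 test patients processed over 14 + 9 PCR batches,
#' 6 candidate gene-expression covariates (normalized Ct scale) and 3
#' clinical covariates, administrative censoring at day 14 and a 28% event
#' proportion, with unbalanced event rates across batches.
#'
#' @param n_train,n_test Patient counts per role.
#' @param n_batches_train,n_batches_test Batch counts per role.
#' @param n_genes,n_clinical Candidate covariate counts.
#' @param beta_true Named vector of true log hazard ratios, one per
#'   covariate (`G1..Gn`, `C1..Cm`). Zeros mark null covariates.
#' @param baseline List `list(shape, scale)` of the Weibull baseline hazard;
#'   shape 1 is the exponential special case. `scale` is recalibrated by
#'   default (see `calibrate_scale`) so the expected event proportion at
#'   `censor_time` matches `target_event_rate`.
#' @param batch_sd Standard deviation of the per-batch additive technical
#'   shift on gene Ct values (0 disables batch effects on expression).
#' @param test_batch_sd Standard deviation of the technical shifts of the
#'   test-dataset batches. Defaults to `batch_sd` (test batches
#'   exchangeable with training batches); set larger to emulate a test
#'   dataset acquired in a separate period, where the between-dataset
#'   technical variability exceeds the within-training variability — the
#'   situation batch-level cross-validation is designed to anticipate.
#' @param batch_event_dispersion Standard deviation of the per-batch
#'   log-hazard frailty that makes event proportions unbalanced across
#'   batches (0 gives balanced batches).
#' @param censor_time Administrative censoring horizon, days.
#' @param target_event_rate Proportion of events expected by `censor_time`.
#' @param dropout_rate Probability of uniform early censoring before
#'   `censor_time`; 0 (default) gives purely administrative censoring.
#' @param calibrate_scale If `TRUE` (default), the Weibull scale is solved
#'   so the expected event proportion equals `target_event_rate`; if
#'   `FALSE`, `baseline$scale` is used as given.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_train = 156, n_test = 95,
                             n_batches_train = 14, n_batches_test = 9,
                             n_genes = 6, n_clinical = 3,
                             beta_true = NULL,
                             baseline = list(shape = 1, scale = 40),
                             batch_sd = 0.5,
                             test_batch_sd = batch_sd,
                             batch_event_dispersion = 0.6,
                             censor_time = 14,
                             target_event_rate = 0.28,
                             dropout_rate = 0,
                             calibrate_scale = TRUE,
                             seed = 1L) {
  gene_names <- paste0("G", seq_len(n_genes))
  clin_names <- if (n_clinical > 0) paste0("C", seq_len(n_clinical)) else character(0)
  if (is.null(beta_true)) {
    beta_true <- stats::setNames(rep(0, n_genes + n_clinical),
                                 c(gene_names, clin_names))
    # magnitudes in the range of the study's final-model hazard ratios
    if (n_genes >= 3) beta_true[c("G2", "G3")] <- c(-0.5, 0.5)
    if (n_clinical >= 2) beta_true[c("C1", "C2")] <- c(0.15, 0.35)
  }
  if (length(beta_true) != n_genes + n_clinical)
    stop("beta_true must have one entry per covariate")
  if (is.null(names(beta_true))) names(beta_true) <- c(gene_names, clin_names)
  cfg <- list(n_train = n_train, n_test = n_test,
              n_batches_train = n_batches_train,
              n_batches_test = n_batches_test,
              n_genes = n_genes, n_clinical = n_clinical,
              beta_true = beta_true, baseline = baseline,
              batch_sd = batch_sd, test_batch_sd = test_batch_sd,
              batch_event_dispersion = batch_event_dispersion,
              censor_time = censor_time,
              target_event_rate = target_event_rate,
              dropout_rate = dropout_rate,
              calibrate_scale = calibrate_scale,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_train > 0, n_test >= 0, n_batches_train > 0,
              n_batches_test >= 0, n_genes >= 0, n_clinical >= 0,
              batch_sd >= 0, test_batch_sd >= 0,
              batch_event_dispersion >= 0,
              censor_time > 0, target_event_rate > 0, target_event_rate < 1,
              dropout_rate >= 0, dropout_rate < 1,
              baseline$shape > 0, baseline$scale > 0)
  })
  if (cfg$n_batches_train > cfg$n_train ||
      (cfg$n_test > 0 && cfg$n_batches_test > cfg$n_test))
    stop("more batches than patients")
  structure(cfg, class = "generator_config")
}

# Split n patients over m batches as equally as possible.
batch_sizes <- function(n, m) {
  base <- n %/% m
  sizes <- rep(base, m)
  extra <- n - base * m
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Solve the Weibull scale so that E[P(T <= tc | lp)] over the realized
# linear predictors equals the target event proportion.
calibrate_weibull_scale <- function(lp, shape, censor_time, target) {
  f <- function(log_scale) {
    mean(1 - exp(-(censor_time / exp(log_scale))^shape * exp(lp))) - target
  }
  exp(stats::uniroot(f, lower = log(1e-4), upper = log(1e6),
                     tol = 1e-10)$root)
}

#' Generate a batch-structured RT-qPCR survival cohort
#'
#' Draws a cohort from a Weibull-baseline proportional-hazards model
#' \eqn{S(t|Z) = \exp(-(t/\mathrm{scale})^{\mathrm{shape}} e^{Z\beta})}
#' with per-batch log-hazard frailties (unbalancing event proportions
#' across batches) and per-batch additive technical shifts on the gene
#' covariates (the plate-level component of RT-qPCR variability). Clinical
#' covariates are batch-free. Event times are drawn by inverse transform
#' and administratively censored at `censor_time`.
#'
#' The hazard depends on the biological gene signal, while the observed
#' gene covariate is signal + per-gene loading x batch shift + measurement
#' noise, so batch effects act as pure technical confounding.
#'
#' @param config A [generator_config()].
#' @return A list with elements `cohort` (a `survival_cohort`) and `truth`
#'   (a list with `beta_true`, `batch_shifts`, `gene_loadings`,
#'   `batch_frailty`, `lp_true`, `uncensored_times`, and the calibrated
#'   `baseline` actually used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_train + config$n_test
  gene_names <- paste0("G", seq_len(config$n_genes))
  clin_names <- if (config$n_clinical > 0)
    paste0("C", seq_len(config$n_clinical)) else character(0)

  # batches: train batches first, then test batches
  tr_sizes <- batch_sizes(config$n_train, config$n_batches_train)
  te_sizes <- if (config$n_test > 0)
    batch_sizes(config$n_test, config$n_batches_test) else integer(0)
  batch_lab <- c(paste0("TR", seq_len(config$n_batches_train)),
                 if (length(te_sizes)) paste0("TE", seq_len(config$n_batches_test)))
  batch <- rep(batch_lab, c(tr_sizes, te_sizes))
  role <- rep(c("train", "test"), c(config$n_train, config$n_test))
  n_batches <- length(batch_lab)

  # biological gene signal (normalized Ct scale) and clinical covariates
  gene_mu <- if (config$n_genes > 0)
    seq(2, 7, length.out = config$n_genes) else numeric(0)
  signal <- matrix(stats::rnorm(n * config$n_genes), n, config$n_genes)
  signal <- sweep(signal, 2, gene_mu, "+")
  clin_mu <- c(7, 2.5, 12)[seq_len(config$n_clinical)]
  clin_sd <- c(3, 1, 4)[seq_len(config$n_clinical)]
  if (config$n_clinical > 3) {
    clin_mu <- c(clin_mu, rep(0, config$n_clinical - 3))
    clin_sd <- c(clin_sd, rep(1, config$n_clinical - 3))
  }
  clinical <- matrix(stats::rnorm(n * config$n_clinical), n, config$n_clinical)
  clinical <- sweep(sweep(clinical, 2, clin_sd, "*"), 2, clin_mu, "+")

  # technical batch shifts on genes: shared per batch, per-gene loading;
  # test batches may carry larger shifts (between-dataset variability)
  shift_sd <- ifelse(startsWith(batch_lab, "TR"),
                     config$batch_sd, config$test_batch_sd)
  batch_shift <- stats::setNames(stats::rnorm(n_batches, 0, shift_sd),
                                 batch_lab)
  loadings <- if (config$n_genes > 0)
    stats::setNames(stats::runif(config$n_genes, 0.5, 1.5), gene_names)
  else numeric(0)
  observed_genes <- signal
  if (config$n_genes > 0) {
    shift_per_patient <- batch_shift[batch]
    observed_genes <- signal +
      outer(shift_per_patient, loadings) +
      matrix(stats::rnorm(n * config$n_genes, 0, 0.25), n, config$n_genes)
  }

  # per-batch frailty unbalances event proportions across batches
  frailty <- stats::setNames(
    stats::rnorm(n_batches, 0, config$batch_event_dispersion), batch_lab)

  Ztrue <- cbind(signal, clinical)
  colnames(Ztrue) <- c(gene_names, clin_names)
  beta <- config$beta_true[colnames(Ztrue)]
  lp_biol <- drop(Ztrue %*% beta)
  lp_biol <- lp_biol - mean(lp_biol)   # center so scale calibration is stable
  lp <- lp_biol + frailty[batch]

  shape <- config$baseline$shape
  scale <- config$baseline$scale
  if (config$calibrate_scale)
    scale <- calibrate_weibull_scale(lp, shape, config$censor_time,
                                     config$target_event_rate)
  u <- stats::runif(n)
  t_event <- scale * (-log(u) / exp(lp))^(1 / shape)

  cens <- rep(config$censor_time, n)
  if (config$dropout_rate > 0) {
    drop_idx <- stats::runif(n) < config$dropout_rate
    cens[drop_idx] <- pmin(cens[drop_idx],
                           stats::runif(sum(drop_idx), 0, config$censor_time))
  }
  time <- pmin(t_event, cens)
  event <- as.numeric(t_event <= cens)

  covariates <- cbind(observed_genes, clinical)
  colnames(covariates) <- c(gene_names, clin_names)
  kinds <- stats::setNames(c(rep("gene", config$n_genes),
                             rep("clinical_continuous", config$n_clinical)),
                           colnames(covariates))
  cohort <- survival_cohort(sprintf("P%03d", seq_len(n)), time, event,
                            batch, role, covariates, kinds)
  truth <- list(beta_true = beta, batch_shifts = batch_shift,
                gene_loadings = loadings, batch_frailty = frailty,
                lp_true = lp, lp_biological = lp_biol,
                uncensored_times = t_event,
                baseline = list(shape = shape, scale = scale))
  list(cohort = cohort, truth = truth)
}

#' Normalize raw Ct values against a single reference gene
#'
#' Computes per-patient \eqn{\Delta Ct = Ct_{gene} - Ct_{reference}} for
#' every gene column and removes the reference column. Adding a constant to
#' all of a patient's Ct values (a sample-level efficiency shift) leaves
#' the normalized values unchanged.
#'
#' @param raw_ct Patient x gene numeric matrix of raw Ct values, with
#'   column names.
#' @param reference Name of the reference (housekeeping) gene column.
#' @return The normalized matrix without the reference column.
#' @export
normalize_delta_ct <- function(raw_ct, reference) {
  raw_ct <- as.matrix(raw_ct)
  if (!reference %in% colnames(raw_ct))
    stop("reference gene '", reference, "' not found")
  out <- raw_ct[, setdiff(colnames(raw_ct), reference), drop = FALSE] -
    raw_ct[, reference]
  out
}

#' Per-batch event-proportion summary
#'
#' One row per batch with patient count, event count and event proportion,
#' plus an `ALL` row whose proportion is the unweighted mean across batches.
#' The interquartile range of the per-batch proportions is attached as
#' attributes `iqr_low`/`iqr_high`.
#'
#' @param cohort A `survival_cohort`.
#' @param role Optional role filter (`"train"`, `"test"`), default all.
#' @return A data.frame with columns `batch`, `n`, `n_events`, `proportion`.
#' @export
batch_event_summary <- function(cohort, role = NULL) {
  keep <- if (is.null(role)) rep(TRUE, length(cohort$role))
          else cohort$role == role
  b <- cohort$batch[keep]; e <- cohort$event[keep]
  tab <- data.frame(batch = sort(unique(b)), stringsAsFactors = FALSE)
  tab$n <- as.integer(table(b)[tab$batch])
  tab$n_events <- vapply(tab$batch, function(x) sum(e[b == x]), numeric(1))
  tab$proportion <- tab$n_events / tab$n
  q <- stats::quantile(tab$proportion, c(0.25, 0.75), names = FALSE)
  out <- rbind(tab, data.frame(batch = "ALL", n = sum(tab$n),
                               n_events = sum(tab$n_events),
                               proportion = mean(tab$proportion)))
  attr(out, "iqr_low") <- q[1]
  attr(out, "iqr_high") <- q[2]
  out
}
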