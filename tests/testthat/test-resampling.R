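test_that("stratified folds balance events to within one", {
  # 44 events among 156 patients, k = 5 -> event counts {9,9,9,9,8}
  set.seed(99)
  ev <- c(rep(1, 44), rep(0, 112))[sample.int(156)]
  co <- survival_cohort(sprintf("p%03d", 1:156), time = stats::rexp(156, 0.1),
                        event = ev, batch = rep(paste0("B", 1:14), length.out = 156),
                        role = rep("train", 156))
  plan <- make_folds_stratified(co, 5, 4, 7)
  for (r in 1:4) {
    a <- plan$assignment[plan$assignment$repetition == r, ]
    ev_by_fold <- tapply(co$event[match(a$patient_id, co$patient_id)],
                         a$fold, sum)
    expect_setequal(as.numeric(ev_by_fold), c(9, 9, 9, 9, 8))
    n_by_fold <- table(a$fold)
    expect_lte(max(n_by_fold) - min(n_by_fold), 2)
  }
})

test_that("exact divisibility gives perfectly balanced stratified folds", {
  co <- survival_cohort(paste0("p", 1:10), time = 1:10,
                        event = rep(c(1, 0), 5),
                        batch = rep("B1", 10), role = rep("train", 10))
  plan <- make_folds_stratified(co, 5, 2, 1)
  for (r in 1:2) {
    a <- plan$assignment[plan$assignment$repetition == r, ]
    ev <- co$event[match(a$patient_id, co$patient_id)]
    expect_true(all(tapply(ev, a$fold, sum) == 1))
    expect_true(all(table(a$fold) == 2))
  }
})

test_that("fold plans are pure functions of (cohort, k, n_rep, seed)", {
  g <- small_cohort(seed = 1, n = 80, batches = 8)
  p1 <- make_folds_stratified(g$cohort, 5, 3, 42)
  p2 <- make_folds_stratified(g$cohort, 5, 3, 42)
  p3 <- make_folds_stratified(g$cohort, 5, 3, 43)
  expect_identical(p1$assignment, p2$assignment)
  expect_false(identical(p1$assignment, p3$assignment))
  b1 <- make_folds_batchwise(g$cohort, 4, 3, 42)
  b2 <- make_folds_batchwise(g$cohort, 4, 3, 42)
  expect_identical(b1$assignment, b2$assignment)
})

test_that("batchwise folds keep batches whole and balance patient counts", {
  # 14 equal-size batches, k = 5 -> batch counts per fold {3,3,3,3,2}
  co <- survival_cohort(sprintf("p%03d", 1:140), time = stats::rexp(140, 0.1),
                        event = rep(c(1, 0, 0, 0), 35),
                        batch = rep(paste0("B", 1:14), each = 10),
                        role = rep("train", 140))
  plan <- make_folds_batchwise(co, 5, 20, 3)
  for (r in 1:20) {
    a <- plan$assignment[plan$assignment$repetition == r, ]
    fold_of_batch <- tapply(a$fold, co$batch[match(a$patient_id,
                                                   co$patient_id)],
                            function(f) length(unique(f)))
    expect_true(all(fold_of_batch == 1))   # batch never split
    bpf <- table(tapply(a$fold,
                        co$batch[match(a$patient_id, co$patient_id)],
                        unique))
    expect_setequal(as.numeric(bpf), c(3, 3, 3, 3, 2))
  }
})

test_that("five batches and five folds give one batch per fold", {
  co <- survival_cohort(paste0("p", 1:25), time = stats::rexp(25, 0.1),
                        event = rep(c(1, 0, 0, 0, 1), 5),
                        batch = rep(paste0("B", 1:5), each = 5),
                        role = rep("train", 25))
  plan <- make_folds_batchwise(co, 5, 2, 1)
  a <- plan$assignment[plan$assignment$repetition == 1, ]
  expect_equal(length(unique(tapply(a$fold, co$batch, unique))), 5)
})

test_that("every train patient is scored exactly n_rep times in CV", {
  g <- small_cohort(seed = 2, n = 80, batches = 8)
  co <- g$cohort
  st <- model_strategy("uni", "univariate", "C1")
  for (mk in list(make_folds_stratified, make_folds_batchwise)) {
    plan <- mk(co, 4, 3, 5)
    cv <- run_cv(co, plan, st, c(7, 14))
    counts <- table(cv$records$patient_id)
    expect_true(all(counts == 3))
  }
})

test_that("the null strategy yields zero predictors and C-index 0.5", {
  g <- small_cohort(seed = 3, n = 60, batches = 4)
  plan <- make_folds_stratified(g$cohort, 4, 2, 1)
  cv <- run_cv(g$cohort, plan, model_strategy("null", "none", character(0)),
               c(7, 14))
  expect_true(all(cv$records$lp == 0))
  ci <- aggregate_cv(cv, "c_index", "linear_predictor", "pooled")
  expect_equal(unname(ci$values), 0.5)
})

test_that("test-fold predictors equal covariate x training-fold coefficient", {
  # k = 2, n_rep = 1, 6-patient toy cohort, univariate Cox; refit by hand
  co <- survival_cohort(paste0("p", 1:6),
                        time = c(2, 4, 6, 3, 5, 7),
                        event = c(1, 1, 0, 1, 1, 0),
                        batch = rep("B1", 6), role = rep("train", 6),
                        covariates = matrix(c(0.2, -1, 0.5, 1.2, -0.3, 0.8),
                                            dimnames = list(NULL, "x")),
                        covariate_kinds = c(x = "clinical_continuous"))
  plan <- make_folds_stratified(co, 2, 1, 9)
  cv <- run_cv(co, plan, model_strategy("uni", "univariate", "x"), 7)
  a <- plan$assignment
  for (f in 1:2) {
    tr_ids <- a$patient_id[a$fold != f]
    te_ids <- a$patient_id[a$fold == f]
    tr_idx <- match(tr_ids, co$patient_id)
    hand <- survival::coxph(
      survival::Surv(co$time[tr_idx], co$event[tr_idx]) ~
        co$covariates[tr_idx, "x"], ties = "breslow")
    b <- unname(stats::coef(hand))
    zc <- co$covariates[match(te_ids, co$patient_id), "x"]
    zc_train_mean <- mean(co$covariates[tr_idx, "x"])
    got <- cv$records$lp[match(te_ids, cv$records$patient_id)]
    expect_equal(got, unname(b * (zc - zc_train_mean)), tolerance = 1e-6)
  }
})

test_that("leakage probe: an outcome-derived noise covariate stays at chance", {
  # a covariate built by permuting the 7-day outcome indicator carries no
  # signal; an implementation that let test-fold outcomes influence the
  # fit or the evaluation would score it above chance
  aucs <- vapply(1:20, function(r) {
    g <- small_cohort(seed = 400 + r, n = 80, batches = 8,
                      beta_true = rep(0, 9), batch_sd = 0,
                      batch_event_dispersion = 0)
    co <- g$cohort
    set.seed(4000 + r)
    fake <- sample(as.numeric(co$time <= 7 & co$event == 1)) +
      stats::rnorm(length(co$time), 0, 0.5)
    co$covariates <- cbind(co$covariates, fake = fake)
    co$covariate_kinds <- c(co$covariate_kinds,
                            fake = "clinical_continuous")
    plan <- make_folds_stratified(co, 4, 1, r)
    cv <- run_cv(co, plan, model_strategy("probe", "none", "fake"), 7)
    aggregate_cv(cv, "td_auc", "linear_predictor", "pooled")$values[1]
  }, numeric(1))
  expect_lt(mean(aucs), 0.55)
  expect_gt(mean(aucs), 0.45)
})

test_that("training folds with zero events are skipped and logged", {
  # batch B1 holds every event; whenever B1 lands in the test fold the
  # training fold has zero events and must be skipped, not imputed
  co <- survival_cohort(paste0("p", 1:20),
                        time = c(rep(2, 5), rep(10, 15)),
                        event = c(rep(1, 5), rep(0, 15)),
                        batch = rep(c("B1", "B2", "B3", "B4"), each = 5),
                        role = rep("train", 20),
                        covariates = matrix(stats::rnorm(20),
                                            dimnames = list(NULL, "x")),
                        covariate_kinds = c(x = "clinical_continuous"))
  plan <- make_folds_batchwise(co, 2, 4, 1)
  cv <- run_cv(co, plan, model_strategy("uni", "univariate", "x"), 7)
  expect_false(is.null(cv$skipped))
  expect_match(cv$skipped$reason, "no events", all = TRUE)
  # skipped folds contribute no scored records
  skipped_keys <- paste(cv$skipped$repetition, cv$skipped$fold)
  rec_keys <- unique(paste(cv$records$repetition, cv$records$fold))
  expect_length(intersect(skipped_keys, rec_keys), 0)
})
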