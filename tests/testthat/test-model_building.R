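test_that("Cox estimate matches brute-force partial-likelihood maximization", {
  d <- toy_twogroup_6()
  fit <- fit_cox(d$time, d$event, d$Z)
  # coarse grid then golden-section refinement on the hand-written
  # partial likelihood
  grid <- seq(-4, 4, by = 0.01)
  ll <- vapply(grid, oracle_partial_loglik, numeric(1),
               time = d$time, event = d$event, z = d$Z[, 1])
  b0 <- grid[which.max(ll)]
  opt <- stats::optimize(function(b)
    -oracle_partial_loglik(b, d$time, d$event, d$Z[, 1]),
    c(b0 - 0.02, b0 + 0.02))
  expect_equal(unname(fit$coefficients), opt$minimum, tolerance = 1e-4)
  expect_equal(fit$loglik,
               oracle_partial_loglik(fit$coefficients, d$time, d$event,
                                     d$Z[, 1]), tolerance = 1e-8)
})

test_that("constant columns are rejected and signs are equivariant", {
  d <- toy_twogroup_6()
  Zc <- cbind(d$Z, const = 0)
  expect_error(fit_cox(d$time, d$event, Zc), "constant")
  f1 <- fit_cox(d$time, d$event, d$Z)
  Zneg <- -d$Z
  f2 <- fit_cox(d$time, d$event, Zneg)
  expect_equal(unname(f2$coefficients), -unname(f1$coefficients),
               tolerance = 1e-8)
})

test_that("partial likelihood is invariant to covariate location shifts", {
  g <- small_cohort(seed = 2, n = 60, batches = 4)
  tr <- cohort_subset(g$cohort, "train")
  f1 <- fit_cox(tr$time, tr$event, tr$covariates)
  f2 <- fit_cox(tr$time, tr$event, tr$covariates + 5)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("Breslow baseline reduces to Nelson-Aalen at beta = 0 and matches
           hand-computed risk-set sums", {
  # single event at t = 3 among 4 at risk, beta = 0 -> Lambda0(3) = 0.25
  time <- c(3, 5, 6, 8); event <- c(1, 0, 0, 0)
  Z <- matrix(0:3 * 0, ncol = 1, dimnames = list(NULL, "z"))
  null_fit <- list(coefficients = stats::setNames(numeric(0), character(0)))
  bl <- breslow_baseline(structure(null_fit, class = "fitted_cox"),
                         time, event, Z)
  expect_equal(bl$cumhaz, 0.25)
  # beta = 0 on a larger set equals Nelson-Aalen from survival
  g <- small_cohort(seed = 4, n = 50, batches = 5)
  tr <- cohort_subset(g$cohort, "train")
  bl0 <- breslow_baseline(structure(null_fit, class = "fitted_cox"),
                          tr$time, tr$event, tr$covariates)
  na <- survival::survfit(survival::Surv(tr$time, tr$event) ~ 1,
                          ctype = 1)
  expect_equal(bl0$cumhaz, na$cumhaz[na$n.event > 0], tolerance = 1e-10)
  # censored 5-patient set, nonzero beta: hand-computed risk-set sums
  t5 <- c(1, 2, 3, 4, 5); e5 <- c(1, 0, 1, 1, 0)
  z5 <- c(0.5, -1, 2, 0, 1)
  beta <- 0.3
  r <- exp(beta * z5)
  hand <- cumsum(c(1 / sum(r), 1 / sum(r[3:5]), 1 / sum(r[4:5])))
  fit5 <- list(coefficients = c(z = beta))
  bl5 <- breslow_baseline(structure(fit5, class = "fitted_cox"), t5, e5,
                          matrix(z5, ncol = 1, dimnames = list(NULL, "z")))
  expect_equal(bl5$cumhaz, hand, tolerance = 1e-12)
})

test_that("breslow baseline agrees with survival::basehaz on a fitted model", {
  g <- small_cohort(seed = 6, n = 80, batches = 4)
  tr <- cohort_subset(g$cohort, "train")
  Z <- tr$covariates[, c("G1", "C1")]
  fit <- fit_cox(tr$time, tr$event, Z)
  cox <- survival::coxph(survival::Surv(tr$time, tr$event) ~ Z,
                         ties = "breslow")
  bh <- survival::basehaz(cox, centered = FALSE)
  bh <- bh[bh$time %in% fit$baseline$time, ]
  expect_equal(fit$baseline$cumhaz, bh$hazard, tolerance = 1e-6)
})

test_that("predicted survival behaves like a survival function", {
  g <- small_cohort(seed = 8, n = 60, batches = 4)
  tr <- cohort_subset(g$cohort, "train")
  fit <- fit_cox(tr$time, tr$event, tr$covariates[, 1:3])
  s <- predict_survival(fit, tr$covariates, c(0, 3, 7, 14))
  expect_true(all(s[, 1] == 1))
  expect_true(all(diff(t(s)) <= 1e-12))      # nonincreasing in t
  # larger linear predictor -> smaller survival at t > first event
  lp <- linear_predictor(fit, tr$covariates)
  o <- order(lp)
  expect_true(all(diff(s[o, 4]) <= 1e-12))
  # null model predicts the same value for everyone
  f0 <- fit_cox(tr$time, tr$event,
                matrix(numeric(0), length(tr$time), 0))
  s0 <- predict_survival(f0, tr$covariates, 7)
  expect_equal(length(unique(s0[, 1])), 1L)
})

test_that("backward AIC drops noise, never worsens AIC, handles 1 candidate", {
  # AIC removes a 1-df noise covariate iff its LR statistic falls below 2,
  # i.e. with probability P(chisq_1 < 2) ~ 0.843; the strong covariate
  # must survive essentially always
  drops <- vapply(1:50, function(r) {
    set.seed(1000 + r)
    n <- 300
    x_sig <- stats::rnorm(n); x_noise <- stats::rnorm(n)
    t_ev <- stats::rexp(n, exp(1.0 * x_sig) / 20)
    time <- pmin(t_ev, 14); event <- as.numeric(t_ev <= 14)
    Z <- cbind(sig = x_sig, noise = x_noise)
    ba <- backward_aic(time, event, Z)
    expect_true("sig" %in% ba$selected)
    !("noise" %in% ba$selected)
  }, logical(1))
  expect_gte(mean(drops), 0.70)
  expect_lte(mean(drops), 0.95)

  g <- small_cohort(seed = 9, n = 80, batches = 4,
                    beta_true = rep(0, 9))
  tr <- cohort_subset(g$cohort, "train")
  full <- fit_cox(tr$time, tr$event, tr$covariates)
  aic_full <- -2 * full$loglik + 2 * ncol(tr$covariates)
  ba <- backward_aic(tr$time, tr$event, tr$covariates)
  expect_lte(ba$aic, aic_full)

  # single candidate: same decision as comparing univariate vs null AIC
  z1 <- tr$covariates[, "G1", drop = FALSE]
  uni <- fit_cox(tr$time, tr$event, z1)
  null_ll <- fit_cox(tr$time, tr$event,
                     matrix(numeric(0), nrow(z1), 0))$loglik
  keep_expected <- (-2 * uni$loglik + 2) < (-2 * null_ll)
  ba1 <- backward_aic(tr$time, tr$event, z1)
  expect_identical("G1" %in% ba1$selected, keep_expected)
})

test_that("fractional polynomial transforms follow the power conventions", {
  expect_equal(unname(fp_transform(c(2, 3), 1)[, 1]), c(2, 3))
  expect_equal(unname(fp_transform(exp(1), 0)[, 1]), 1)
  out <- fp_transform(2, c(2, 2))
  expect_equal(unname(out[1, ]), c(4, 4 * log(2)))
  out2 <- fp_transform(c(2, 4), c(-1, 0.5))
  expect_equal(unname(out2[, 1]), c(0.5, 0.25))
  expect_equal(unname(out2[, 2]), c(sqrt(2), 2))
  expect_error(fp_transform(c(-1, 2), 1), "positive")
  expect_equal(fp_shift(c(1, 2)), 0)
  x <- c(-2, 0, 2)
  expect_true(all(x + fp_shift(x) > 0))
})

test_that("MFP keeps a linear effect linear and finds a log shape", {
  linear_kept <- vapply(1:20, function(r) {
    set.seed(2000 + r)
    n <- 250
    x <- stats::rnorm(n, 5, 1)
    t_ev <- stats::rexp(n, exp(0.8 * (x - 5)) / 15)
    time <- pmin(t_ev, 14); event <- as.numeric(t_ev <= 14)
    Z <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
    res <- mfp_select(time, event, Z, fp_alpha = 0.05, mfp_select = 0.05)
    identical(res$forms$x$type, "linear")
  }, logical(1))
  expect_gte(mean(linear_kept), 0.8)

  log_found <- vapply(1:12, function(r) {
    set.seed(3000 + r)
    n <- 400
    x <- stats::runif(n, 0.2, 8)
    t_ev <- stats::rexp(n, exp(1.5 * log(x)) / 40)
    time <- pmin(t_ev, 14); event <- as.numeric(t_ev <= 14)
    Z <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
    res <- mfp_select(time, event, Z, fp_alpha = 0.2, mfp_select = 0.05)
    f <- res$forms$x
    f$type == "fp" && any(abs(f$powers) < 0.75)  # log or sqrt-like shape
  }, logical(1))
  expect_gte(mean(log_found), 0.5)
})

test_that("MFP excludes pure noise at roughly the select level", {
  excluded <- vapply(1:40, function(r) {
    set.seed(4000 + r)
    n <- 150
    x <- stats::rnorm(n)
    t_ev <- stats::rexp(n, 1 / 15)
    time <- pmin(t_ev, 14); event <- as.numeric(t_ev <= 14)
    Z <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
    res <- mfp_select(time, event, Z, fp_alpha = 0.05, mfp_select = 0.15)
    identical(res$forms$x$type, "omit")
  }, logical(1))
  expect_gt(mean(excluded), 0.85 - 0.18)
  expect_lte(mean(excluded), 1)
})

test_that("lasso limits: unpenalized at tiny lambda, all-zero with KKT at
           large lambda", {
  g <- small_cohort(seed = 12, n = 120, batches = 6)
  tr <- cohort_subset(g$cohort, "train")
  Z <- tr$covariates
  mle <- fit_cox(tr$time, tr$event, Z)
  near0 <- fit_penalized_cox(tr$time, tr$event, Z, "l1", 1e-6)
  expect_lt(max(abs(near0$coefficients - mle$coefficients)), 1e-3)

  big <- fit_penalized_cox(tr$time, tr$event, Z, "l1", 100)
  expect_true(all(big$coefficients == 0))
  # KKT at the null: |score_j| on standardized scale must be <= lambda
  Zs <- scale(Z)
  eps <- 1e-5
  score <- vapply(seq_len(ncol(Zs)), function(j) {
    b <- stats::setNames(eps, colnames(Zs)[j])
    (batchsurv:::partial_loglik_at(b, tr$time, tr$event, Zs) -
       batchsurv:::partial_loglik_at(stats::setNames(0, colnames(Zs)[j]),
                                     tr$time, tr$event, Zs)) / eps
  }, numeric(1))
  expect_true(all(abs(score) <= 100))
})

test_that("sparsity is monotone along the lambda grid", {
  for (s in 1:6) {
    g <- small_cohort(seed = 500 + s, n = 100, batches = 5)
    tr <- cohort_subset(g$cohort, "train")
    nsel <- vapply(c(0.01, 0.1, 1, 10, 100), function(l)
      length(fit_penalized_cox(tr$time, tr$event, tr$covariates,
                               "l1", l)$selected), numeric(1))
    expect_true(all(diff(nsel) <= 0))
  }
})

test_that("adaptive lasso shrinks a strong coefficient less than lasso", {
  wins <- vapply(1:50, function(r) {
    set.seed(6000 + r)
    n <- 150
    Z <- cbind(strong = stats::rnorm(n), weak = stats::rnorm(n),
               n1 = stats::rnorm(n), n2 = stats::rnorm(n))
    t_ev <- stats::rexp(n, exp(1.2 * Z[, 1] + 0.2 * Z[, 2]) / 15)
    time <- pmin(t_ev, 14); event <- as.numeric(t_ev <= 14)
    la <- fit_penalized_cox(time, event, Z, "l1", 3)
    ad <- fit_penalized_cox(time, event, Z, "adaptive_l1", 3)
    abs(ad$coefficients["strong"]) >= abs(la$coefficients["strong"])
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("SCAD leaves large coefficients closer to the MLE than lasso", {
  set.seed(77)
  n <- 200
  Z <- cbind(strong = stats::rnorm(n), n1 = stats::rnorm(n),
             n2 = stats::rnorm(n))
  t_ev <- stats::rexp(n, exp(1.2 * Z[, 1]) / 15)
  time <- pmin(t_ev, 14); event <- as.numeric(t_ev <= 14)
  mle <- fit_cox(time, event, Z)
  la <- fit_penalized_cox(time, event, Z, "l1", 5)
  sc <- fit_penalized_cox(time, event, Z, "scad", 5)
  expect_lt(abs(sc$coefficients["strong"] - mle$coefficients["strong"]),
            abs(la$coefficients["strong"] - mle$coefficients["strong"]))
})

test_that("selection-then-refit removes the shrinkage", {
  g <- small_cohort(seed = 13, n = 120, batches = 6)
  tr <- cohort_subset(g$cohort, "train")
  la <- fit_penalized_cox(tr$time, tr$event, tr$covariates, "l1", 5)
  expect_gt(length(la$selected), 0)
  expect_lt(length(la$selected), ncol(tr$covariates))
  re <- refit_selected(tr$time, tr$event, tr$covariates, la$selected)
  expect_true(all(abs(re$coefficients[la$selected]) >=
                    abs(la$coefficients[la$selected]) - 1e-8))
  expect_false(isTRUE(all.equal(re$coefficients[la$selected],
                                la$coefficients[la$selected])))
  # empty selection -> null model
  f0 <- refit_selected(tr$time, tr$event, tr$covariates, character(0))
  expect_length(f0$coefficients, 0)
  expect_equal(linear_predictor(f0, tr$covariates), rep(0, sum(tr$role == "train")))
  # full selection -> identical to fit_cox
  fall <- refit_selected(tr$time, tr$event, tr$covariates,
                         colnames(tr$covariates))
  expect_equal(fall$coefficients,
               fit_cox(tr$time, tr$event, tr$covariates)$coefficients)
})
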