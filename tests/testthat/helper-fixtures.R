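# Small in-code fixtures shared across test files.

# 4-patient toy cohort (2 events), no covariates.
toy_cohort_4 <- function() {
  survival_cohort(paste0("p", 1:4), time = c(2, 5, 7, 14),
                  event = c(1, 1, 0, 0), batch = c("B1", "B1", "B2", "B2"),
                  role = rep("train", 4))
}

# 6-patient two-group toy set: distinct times, all events, binary Z.
toy_twogroup_6 <- function() {
  list(time = c(1, 2, 3, 4, 5, 6),
       event = rep(1, 6),
       Z = matrix(c(1, 0, 1, 0, 1, 0), ncol = 1,
                  dimnames = list(NULL, "z")))
}

# Breslow-ties partial log-likelihood written independently of the
# package (event-time loop over risk sets), used as a brute-force oracle.
oracle_partial_loglik <- function(beta, time, event, z) {
  lp <- z * beta
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + lp[i] - log(sum(exp(lp[risk])))
  }
  ll
}

# Exhaustive-pair Harrell concordance, written independently (double loop).
oracle_c_index <- function(marker, time, event) {
  num <- 0; den <- 0
  n <- length(marker)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    # usable: i dies strictly before j's observed time
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (marker[i] > marker[j]) num <- num + 1
      else if (marker[i] == marker[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no usable pairs")
  num / den
}

# small generated cohort for CV tests: quick but realistic structure
small_cohort <- function(seed = 1, n = 100, batches = 8, n_test = 0,
                         batches_test = 1, ...) {
  generate_cohort(generator_config(
    n_train = n, n_test = n_test, n_batches_train = batches,
    n_batches_test = batches_test, seed = seed, ...))
}
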