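#' Describe a candidate covariate
#'
#' A covariate specification names a candidate predictor, declares its kind,
#' and optionally requests a dichotomized companion column for continuous
#' clinical covariates (the expert-knowledge "-Fac" variants).
#'
#' @param name Covariate name, matching a column of the cohort file.
#' @param kind One of `"gene"`, `"clinical_continuous"`, `"clinical_binary"`.
#' @param dichotomize_at Optional numeric cutoff; only allowed for
#'   `kind = "clinical_continuous"`. When present, a companion column
#'   `<name>_Fac` is created with value 1 when the raw value exceeds the
#'   cutoff, 0 otherwise.
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, kind = c("gene", "clinical_continuous",
                                          "clinical_binary"),
                           dichotomize_at = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(dichotomize_at)) {
    if (kind != "clinical_continuous")
      stop("dichotomize_at is only meaningful for clinical_continuous covariates")
    stopifnot(is.numeric(dichotomize_at), length(dichotomize_at) == 1L,
              is.finite(dichotomize_at))
  }
  structure(list(name = name, kind = kind, dichotomize_at = dichotomize_at),
            class = "covariate_spec")
}

#' Construct and validate a survival cohort
#'
#' The central data container: one row per patient with follow-up time
#' (days), event indicator (1 = death observed), PCR batch label, dataset
#' role (train/test) and a numeric covariate matrix. Batches are the unit of
#' shared technical variability; a batch must belong entirely to one role.
#'
#' @param patient_id Character vector of unique patient labels.
#' @param time Nonnegative follow-up times in days.
#' @param event 0/1 event indicators (1 = death observed).
#' @param batch Batch labels (coerced to character).
#' @param role `"train"` or `"test"` per patient.
#' @param covariates Numeric matrix or data.frame, one column per candidate
#'   covariate, rows aligned with patients. May have zero columns.
#' @param covariate_kinds Named character vector tagging each covariate
#'   column as `"gene"`, `"clinical_continuous"` or `"clinical_binary"`.
#'   Defaults to `"clinical_continuous"` for all columns.
#' @return An object of class `survival_cohort`: a list with fields
#'   `patient_id`, `time`, `event`, `batch`, `role`, `covariates` (matrix),
#'   `covariate_kinds`.
#' @export
survival_cohort <- function(patient_id, time, event, batch, role,
                            covariates = NULL, covariate_kinds = NULL) {
  patient_id <- as.character(patient_id)
  n <- length(patient_id)
  time <- as.numeric(time)
  event <- as.numeric(event)
  batch <- as.character(batch)
  role <- as.character(role)
  if (anyDuplicated(patient_id))
    stop("patient_id values must be unique")
  if (length(time) != n || length(event) != n || length(batch) != n ||
      length(role) != n)
    stop("all patient-level fields must have the same length")
  if (anyNA(time) || anyNA(event) || anyNA(batch))
    stop("missing values are not allowed in time, event or batch")
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("event must be coded 0/1")
  if (!all(role %in% c("train", "test")))
    stop("role must be 'train' or 'test'")
  split_batches <- tapply(role, batch, function(r) length(unique(r)) > 1L)
  if (any(split_batches))
    stop("batch(es) span both train and test roles: ",
         paste(names(split_batches)[split_batches], collapse = ", "))
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    rownames(covariates) <- NULL
    if (nrow(covariates) != n)
      stop("covariate matrix row count does not match patient count")
  }
  if (is.null(covariate_kinds)) {
    covariate_kinds <- rep("clinical_continuous", ncol(covariates))
    names(covariate_kinds) <- colnames(covariates)
  }
  if (length(covariate_kinds) != ncol(covariates))
    stop("covariate_kinds must tag every covariate column")
  structure(list(patient_id = patient_id, time = time, event = event,
                 batch = batch, role = role, covariates = covariates,
                 covariate_kinds = covariate_kinds),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d patients (%d train / %d test), %d batches\n",
              length(x$patient_id), sum(x$role == "train"),
              sum(x$role == "test"), length(unique(x$batch))))
  cat(sprintf("  events: %d (%.1f%%); covariates: %d (%s)\n",
              sum(x$event), 100 * mean(x$event), ncol(x$covariates),
              paste(colnames(x$covariates), collapse = ", ")))
  invisible(x)
}

#' Subset a cohort by patient index or role
#'
#' @param cohort A `survival_cohort`.
#' @param idx Logical or integer row index, or a role string
#'   (`"train"`/`"test"`).
#' @return The subset, still a `survival_cohort`.
#' @export
cohort_subset <- function(cohort, idx) {
  if (is.character(idx) && length(idx) == 1L && idx %in% c("train", "test"))
    idx <- cohort$role == idx
  survival_cohort(cohort$patient_id[idx], cohort$time[idx],
                  cohort$event[idx], cohort$batch[idx], cohort$role[idx],
                  cohort$covariates[idx, , drop = FALSE],
                  cohort$covariate_kinds)
}

# Append <name>_Fac indicator columns for every spec with a cutoff.
# Idempotent: existing _Fac columns are recomputed, not duplicated.
apply_dichotomization <- function(covariates, specs) {
  for (sp in specs) {
    if (is.null(sp$dichotomize_at)) next
    if (!sp$name %in% colnames(covariates))
      stop("covariate '", sp$name, "' not found for dichotomization")
    fac <- as.numeric(covariates[, sp$name] > sp$dichotomize_at)
    nm <- paste0(sp$name, "_Fac")
    if (nm %in% colnames(covariates)) {
      covariates[, nm] <- fac
    } else {
      covariates <- cbind(covariates, fac)
      colnames(covariates)[ncol(covariates)] <- nm
    }
  }
  covariates
}

#' Read a cohort from delimited text
#'
#' Expects a comma-separated file with header columns `patient_id`, `time`,
#' `event`, `batch`, `role` followed by one numeric column per covariate.
#' For every [covariate_spec()] carrying a `dichotomize_at` cutoff, a
#' companion indicator column `<name>_Fac` (1 if raw value > cutoff) is
#' appended alongside the continuous original, so a model strategy can name
#' either variant.
#'
#' @param path Path to a CSV cohort file.
#' @param spec Optional list of [covariate_spec()] objects. Covariates
#'   present in the file but not in `spec` are kept with kind
#'   `"clinical_continuous"`.
#' @return A validated `survival_cohort`.
#' @export
read_cohort <- function(path, spec = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "time", "event", "batch", "role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  cov_names <- setdiff(names(df), required)
  covariates <- as.matrix(df[, cov_names, drop = FALSE])
  kinds <- rep("clinical_continuous", length(cov_names))
  names(kinds) <- cov_names
  if (!is.null(spec)) {
    for (sp in spec) {
      if (sp$name %in% cov_names) kinds[sp$name] <- sp$kind
    }
    covariates <- apply_dichotomization(covariates, spec)
    new_cols <- setdiff(colnames(covariates), cov_names)
    kinds <- c(kinds, stats::setNames(rep("clinical_binary", length(new_cols)),
                                      new_cols))
  }
  survival_cohort(df$patient_id, df$time, df$event, df$batch, df$role,
                  covariates, kinds)
}

#' Write a cohort to delimited text
#'
#' Deterministic column order: `patient_id,time,event,batch,role` followed by
#' covariate columns in their stored order. Numeric fields are printed with
#' full precision so that a write/read round trip is the identity.
#'
#' @param cohort A `survival_cohort`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(patient_id = cohort$patient_id,
                   time = cohort$time,
                   event = cohort$event,
                   batch = cohort$batch,
                   role = cohort$role,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(cohort$covariates) > 0)
    df <- cbind(df, as.data.frame(cohort$covariates, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Append dichotomized companion covariates to a cohort
#'
#' Applies every `dichotomize_at` cutoff in `spec` to an existing cohort,
#' appending (or recomputing) `<name>_Fac` indicator columns. Idempotent and
#' row-count preserving.
#'
#' @param cohort A `survival_cohort`.
#' @param spec List of [covariate_spec()] objects.
#' @return The cohort with companion columns appended.
#' @export
add_dichotomized <- function(cohort, spec) {
  old <- colnames(cohort$covariates)
  cov <- apply_dichotomization(cohort$covariates, spec)
  new_cols <- setdiff(colnames(cov), old)
  kinds <- c(cohort$covariate_kinds,
             stats::setNames(rep("clinical_binary", length(new_cols)),
                             new_cols))
  survival_cohort(cohort$patient_id, cohort$time, cohort$event, cohort$batch,
                  cohort$role, cov, kinds)
}

# Columns offered to model building: drop constant columns is an error,
# not a silent fix — the caller decides which candidates to offer.
check_candidates <- function(covariates, candidates) {
  missing <- setdiff(candidates, colnames(covariates))
  if (length(missing))
    stop("candidate covariate(s) not in cohort: ",
         paste(missing, collapse = ", "))
  const <- vapply(candidates, function(nm) {
    v <- covariates[, nm]
    max(v) - min(v) < .Machine$double.eps^0.5
  }, logical(1))
  if (any(const))
    stop("constant candidate covariate(s): ",
         paste(candidates[const], collapse = ", "))
  invisible(TRUE)
}
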