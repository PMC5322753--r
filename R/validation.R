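# Ten-fold cross-validation of the cascade and cohort-level evaluation:
# positive-only (PF) true positive rate and external-cohort validation.

# Stratified fold assignment: within each status, shuffled members are
# dealt round-robin into folds, with the starting fold rolling across
# strata so overall fold sizes differ by at most one.
stratified_folds <- function(status, n_folds, seed) {
  n <- length(status)
  fold <- integer(n)
  offset <- 0L
  local_seed(seed, {
    for (s in unique(status)) {
      idx <- which(status == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  fold
}

#' Ten-fold cross-validation of the cascade
#'
#' Patients are divided into `n_folds` mutually exclusive, nearly
#' equal-size sets, stratified by lung status. For each repetition the
#' complete cascade (normalizer, first-stage network, reference cohort,
#' division scheme and second-stage network) is rebuilt from scratch on
#' the other folds and the held-out fold is scored as an external cohort
#' (its patients never enter the reference, so no labels leak). The
#' out-of-fold scores are pooled into a single ROC summary.
#'
#' @inheritParams train_cascade
#' @param n_folds number of folds (default 10).
#' @param max_retries fold draws leaving any training set single-class are
#'   redrawn with an incremented seed at most this many times.
#' @return object of class `cv_report`: list with `folds` (named integer
#'   vector), `scores` (pooled out-of-fold `cascade_scores`), `summary`
#'   (pooled [roc_summary()] row) and `seed_used`.
#' @export
ten_fold_cv <- function(cohort, inputs, n_folds = 10, m_values = c(5, 10, 15, 20),
                        k_centers = 12, ridge = 1e-6, seed = 1,
                        max_retries = 20) {
  if (any(cohort$data$lung_status == "PF")) {
    stop("cohort contains PF records; apply model_building_subset() first")
  }
  cohort <- filter_complete(cohort, inputs)
  n <- n_patients(cohort)
  if (n < 2 * n_folds) stop("cohort too small for ", n_folds, "-fold CV")
  status <- as.character(cohort$data$lung_status)

  fold <- NULL
  seed_used <- seed
  for (attempt in 0:max_retries) {
    seed_used <- seed + attempt
    f <- stratified_folds(status, n_folds, derive_seed(seed_used, 11))
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(status[f != k])) == 2
    }, TRUE))
    if (ok) { fold <- f; break }
  }
  if (is.null(fold)) stop("could not draw folds keeping both classes in every training set")

  scores <- rep(NA_real_, n)
  for (k in seq_len(n_folds)) {
    tr <- cohort; tr$data <- cohort$data[fold != k, , drop = FALSE]
    va <- cohort; va$data <- cohort$data[fold == k, , drop = FALSE]
    fit <- train_cascade(tr, inputs, m_values = m_values,
                         k_centers = k_centers, ridge = ridge,
                         seed = derive_seed(seed_used, 100 + k))
    scores[fold == k] <- predict_cascade(fit$model, va)$score
  }
  y <- status == "ILD"
  structure(list(folds = stats::setNames(fold, cohort$data$patient_id),
                 scores = data.frame(patient_id = cohort$data$patient_id,
                                     lung_status = status, fold = fold,
                                     score = scores, stringsAsFactors = FALSE),
                 summary = roc_summary(scores, y, direction = "positive"),
                 n_folds = n_folds, seed_used = seed_used),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold, pooled AUC %.3f, Youden J %.3f\n",
              x$n_folds, x$summary$auc, x$summary$youden_j))
  invisible(x)
}

confusion_counts <- function(is_pos, call) {
  c(TP = sum(is_pos & call), FN = sum(is_pos & !call),
    FP = sum(!is_pos & call), TN = sum(!is_pos & !call))
}

#' Evaluate a cascade on an all-positive (PF) cohort
#'
#' Every patient carries established pulmonary fibrosis; the question is
#' what fraction the frozen model flags at its decision cutoff. With a
#' single class no AUC exists, so only the confusion counts and the TPR
#' are reported.
#'
#' @param model a `cascade_model`.
#' @param pf_cohort `ild_cohort` containing only PF records.
#' @return object of class `evaluation_report`: confusion counts at the
#'   model cutoff, `tpr` (percent), `auc = NA`, and the scores.
#' @export
evaluate_positive_only <- function(model, pf_cohort) {
  if (!all(pf_cohort$data$lung_status == "PF")) {
    stop("evaluate_positive_only expects a cohort of PF records only")
  }
  sc <- predict_cascade(model, pf_cohort)
  ok <- !is.na(sc$score)
  counts <- confusion_counts(rep(TRUE, sum(ok)), sc$call[ok])
  structure(list(counts = counts, tpr = tpr(counts["TP"], counts["FN"]),
                 auc = NA_real_, cutoff = model$cutoff, scores = sc,
                 clip_fraction = attr(sc, "clip_fraction"),
                 clip_warning = FALSE),
            class = "evaluation_report")
}

#' Evaluate a cascade on an external labeled cohort
#'
#' Scores a cohort of HEALTHY and ILD patients through the frozen cascade,
#' tabulates the 2x2 contingency table at the frozen decision cutoff, and
#' reports TPR and AUC. When more than half of the normalized input values
#' fall outside the training range (and are clipped), the report carries a
#' scale warning.
#'
#' @param model a `cascade_model`.
#' @param cohort external `ild_cohort` with HEALTHY and ILD records.
#' @return an `evaluation_report` with confusion counts, `tpr`, `auc` and
#'   the scores.
#' @export
evaluate_external <- function(model, cohort) {
  if (any(cohort$data$lung_status == "PF")) {
    stop("external validation cohort must contain only HEALTHY and ILD records")
  }
  sc <- predict_cascade(model, cohort)
  ok <- !is.na(sc$score)
  is_pos <- sc$lung_status[ok] == "ILD"
  counts <- confusion_counts(is_pos, sc$call[ok])
  auc <- if (any(is_pos) && any(!is_pos)) {
    roc_curve(sc$score[ok], is_pos, "positive")$auc
  } else NA_real_
  clip <- attr(sc, "clip_fraction")
  clip_warn <- isTRUE(clip > 0.5)
  if (clip_warn) {
    warning("more than 50% of normalized input values were clipped; ",
            "the external cohort's CEI scale may not match the training cohort")
  }
  structure(list(counts = counts, tpr = tpr(counts["TP"], counts["FN"]),
                 auc = auc, cutoff = model$cutoff, scores = sc,
                 clip_fraction = clip, clip_warning = clip_warn),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:\n  counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  cat(sprintf("  TPR %.1f%%; AUC %s; cutoff %.4f\n", x$tpr,
              ifelse(is.na(x$auc), "NA (single class)", sprintf("%.3f", x$auc)),
              x$cutoff))
  invisible(x)
}
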