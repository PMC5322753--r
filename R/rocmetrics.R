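# Empirical ROC analysis: AUC (Mann-Whitney), DeLong variance and paired
# test, Youden-optimal cutoff, DOR, TPR, sensitivity at fixed specificity.

as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (is.null(positive)) stop("character labels need `positive =` level")
    return(labels == positive)
  }
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  stop("labels must be logical, 0/1 numeric, or character/factor")
}

# Mann-Whitney AUC with midranks; ties count 1/2. Higher score = positive.
auc_mw <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 over positives, V01 over negatives.
# psi(x, y) = 1 if x > y, 1/2 if x == y, 0 if x < y (higher = positive).
delong_components <- function(scores, is_pos) {
  x <- scores[is_pos]; y <- scores[!is_pos]
  m <- length(x); n <- length(y)
  rx <- rank(c(x, y))
  # midrank decomposition: V10_i = (rank of x_i among all - rank among pos)/n
  rall_x <- rx[seq_len(m)]
  rpos_x <- rank(x)
  v10 <- (rall_x - rpos_x) / n
  rall_y <- rx[m + seq_len(n)]
  rneg_y <- rank(y)
  v01 <- 1 - (rall_y - rneg_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

# Variance of a single AUC (DeLong).
delong_var <- function(comp) {
  m <- length(comp$v10); n <- length(comp$v01)
  s10 <- if (m > 1) stats::var(comp$v10) else 0
  s01 <- if (n > 1) stats::var(comp$v01) else 0
  s10 / m + s01 / n
}

#' Empirical ROC curve
#'
#' Operating points are computed at every distinct score threshold plus the
#' degenerate endpoint, so the curve always contains (sens = 1, spec = 0)
#' and (sens = 0, spec = 1). Under the `"positive"` direction a patient is
#' called positive when `score >= threshold`; under `"inverse"`, when
#' `score <= threshold`. `"auto"` picks the direction with AUC >= 0.5 and
#' records it (the convention under which screening tables report all AUCs
#' at or above one half).
#'
#' @param scores numeric vector.
#' @param labels logical, 0/1, or character/factor with `positive =`.
#' @param direction `"auto"`, `"positive"` or `"inverse"`.
#' @param positive positive-class level for character/factor labels.
#' @return object of class `ild_roc`: data.frame of operating points
#'   (`threshold`, `sensitivity`, `specificity`) plus the direction, AUC and
#'   the raw scores/labels needed by the DeLong machinery.
#' @export
roc_curve <- function(scores, labels, direction = c("auto", "positive", "inverse"),
                      positive = NULL) {
  direction <- match.arg(direction)
  is_pos <- as_binary_labels(labels, positive)
  ok <- !is.na(scores) & !is.na(is_pos)
  scores <- scores[ok]; is_pos <- is_pos[ok]
  if (sum(is_pos) == 0 || sum(!is_pos) == 0) {
    stop("roc_curve needs at least one positive and one negative label")
  }
  if (direction == "auto") {
    direction <- if (auc_mw(scores, is_pos) >= 0.5) "positive" else "inverse"
  }
  eff <- if (direction == "positive") scores else -scores
  thr <- sort(unique(eff))
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  # positive call: eff >= t
  sens <- vapply(thr, function(t) sum(eff[is_pos] >= t), 0) / n1
  spec <- vapply(thr, function(t) sum(eff[!is_pos] < t), 0) / n0
  pts <- data.frame(threshold = c(thr, Inf),
                    sensitivity = c(sens, 0),
                    specificity = c(spec, 1))
  if (direction == "inverse") pts$threshold <- -pts$threshold
  structure(list(points = pts, direction = direction,
                 auc = auc_mw(eff, is_pos),
                 scores = scores, is_pos = is_pos),
            class = "ild_roc")
}

#' @export
print.ild_roc <- function(x, ...) {
  cat(sprintf("ild_roc: AUC %.4f (direction %s), %d positives / %d negatives\n",
              x$auc, x$direction, sum(x$is_pos), sum(!x$is_pos)))
  invisible(x)
}

#' Test an AUC against 0.5 (no diagnostic information)
#'
#' Two-sided z test using the DeLong standard error. A score is considered
#' disease-associated when the AUC exceeds 0.5 and the test rejects at
#' `alpha`. Constant scores carry no information: p = 1 by construction.
#'
#' @inheritParams roc_curve
#' @param alpha significance level for the association verdict.
#' @return list with `auc`, `se`, `z`, `p_value`, `associated`.
#' @export
auc_test_vs_half <- function(scores, labels, direction = c("auto", "positive", "inverse"),
                             positive = NULL, alpha = 0.05) {
  direction <- match.arg(direction)
  is_pos <- as_binary_labels(labels, positive)
  ok <- !is.na(scores) & !is.na(is_pos)
  scores <- scores[ok]; is_pos <- is_pos[ok]
  if (sum(is_pos) == 0 || sum(!is_pos) == 0) {
    stop("auc_test_vs_half needs both classes")
  }
  if (direction == "auto") {
    direction <- if (auc_mw(scores, is_pos) >= 0.5) "positive" else "inverse"
  }
  eff <- if (direction == "positive") scores else -scores
  comp <- delong_components(eff, is_pos)
  v <- delong_var(comp)
  if (v <= 0) {
    return(list(auc = comp$auc, se = 0, z = 0, p_value = 1,
                associated = FALSE, direction = direction))
  }
  z <- (comp$auc - 0.5) / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  list(auc = comp$auc, se = sqrt(v), z = z, p_value = p,
       associated = (comp$auc > 0.5) && (p < alpha), direction = direction)
}

#' Youden index
#'
#' J = sensitivity + specificity - 1, the screening and model-selection
#' criterion used throughout the pipeline.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return J in \[-1, 1\].
#' @examples
#' youden(0.772, 0.615)
#' @export
youden <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1, na.rm = TRUE) ||
      any(specificity < 0 | specificity > 1, na.rm = TRUE)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  sensitivity + specificity - 1
}

#' Diagnostic odds ratio
#'
#' DOR = (SE * SP) / ((1 - SE) * (1 - SP)): the odds of a positive call in
#' the diseased versus the non-diseased. A sensitivity or specificity of
#' exactly 1 makes the DOR infinite; this is signalled as an error of class
#' `ildcascade_infinite_dor` rather than returned silently.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return non-negative odds ratio.
#' @examples
#' dor(0.772, 0.615)  # 5.41 to two decimals
#' @export
dor <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  if (any(sensitivity == 1 | specificity == 1)) {
    stop(structure(class = c("ildcascade_infinite_dor", "error", "condition"),
                   list(message = "DOR is infinite (sensitivity or specificity equals 1)",
                        call = sys.call(-1))))
  }
  (sensitivity * specificity) / ((1 - sensitivity) * (1 - specificity))
}

# dor() that maps the infinite case to Inf, for report tables.
dor_or_inf <- function(sensitivity, specificity) {
  tryCatch(dor(sensitivity, specificity),
           ildcascade_infinite_dor = function(e) Inf)
}

#' True positive rate (percent)
#'
#' TPR = TP / (TP + FN) * 100.
#'
#' @param tp,fn non-negative counts of true positives and false negatives.
#' @return percentage in \[0, 100\].
#' @export
tpr <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp + fn == 0) stop("tpr undefined: no positive cases (tp + fn = 0)")
  unname(100 * tp / (tp + fn))
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Maximizes J = SE + SP - 1 over all operating points; among ties the
#' point with the highest specificity is chosen, making the output
#' deterministic.
#'
#' @param curve an `ild_roc`.
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "ild_roc"))
  pts <- curve$points
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(pts$specificity[best])]
  list(threshold = pts$threshold[best],
       sensitivity = pts$sensitivity[best],
       specificity = pts$specificity[best],
       youden = j[best])
}

#' Sensitivity at a fixed specificity
#'
#' Step-function convention (no interpolation): among achievable operating
#' points with specificity at or above the target, the one with the
#' smallest such specificity is reported. Conservative and exactly
#' reproducible.
#'
#' @param curve an `ild_roc`.
#' @param spec_target required specificity (default 0.8).
#' @return sensitivity in \[0, 1\].
#' @export
sens_at_spec <- function(curve, spec_target = 0.8) {
  stopifnot(inherits(curve, "ild_roc"))
  pts <- curve$points
  elig <- pts$specificity >= spec_target
  if (!any(elig)) return(0)
  max(pts$sensitivity[elig])
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two scores measured on the same patients, using
#' the covariance of their DeLong structural components. Both scores are
#' taken in the higher-is-positive direction.
#'
#' @param scores_a,scores_b numeric score vectors over the same patients.
#' @param labels binary labels (see [roc_curve()]).
#' @param positive positive-class level for character/factor labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, positive = NULL) {
  is_pos <- as_binary_labels(labels, positive)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(is_pos)) {
    stop("delong_compare requires scores and labels over the same patients")
  }
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(is_pos)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]; is_pos <- is_pos[ok]
  if (sum(is_pos) == 0 || sum(!is_pos) == 0) stop("need both classes")
  ca <- delong_components(scores_a, is_pos)
  cb <- delong_components(scores_b, is_pos)
  m <- sum(is_pos); n <- sum(!is_pos)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (v <= 0) {
    return(list(auc_a = ca$auc, auc_b = cb$auc, z = 0, p_value = 1, var_diff = 0))
  }
  z <- (ca$auc - cb$auc) / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), var_diff = v)
}

#' Full per-score diagnostic summary
#'
#' Computes everything a screening-table row carries: AUC with DeLong
#' standard error and p-value against 0.5, the Youden-optimal cutoff with
#' its sensitivity/specificity/J, the diagnostic odds ratio, and the
#' sensitivity at fixed specificity 0.8. An infinite DOR (boundary
#' operating point) is reported as `Inf`.
#'
#' @inheritParams roc_curve
#' @param alpha significance level for the association verdict.
#' @param spec_target fixed specificity for `sens_at_spec80`.
#' @return one-row data.frame (class `roc_summary_row`).
#' @export
roc_summary <- function(scores, labels, direction = c("auto", "positive", "inverse"),
                        positive = NULL, alpha = 0.05, spec_target = 0.8) {
  direction <- match.arg(direction)
  curve <- roc_curve(scores, labels, direction, positive)
  test <- auc_test_vs_half(scores, labels, direction = curve$direction,
                           positive = positive, alpha = alpha)
  oc <- optimal_cutoff(curve)
  data.frame(auc = curve$auc, auc_se = test$se, p_vs_half = test$p_value,
             optimal_cutoff = oc$threshold,
             sensitivity = oc$sensitivity, specificity = oc$specificity,
             youden_j = oc$youden,
             sens_at_spec80 = sens_at_spec(curve, spec_target),
             dor = dor_or_inf(oc$sensitivity, oc$specificity),
             associated = test$associated,
             direction = curve$direction,
             stringsAsFactors = FALSE)
}
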