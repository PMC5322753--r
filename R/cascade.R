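# Distance-division derivative features and the two-stage network cascade:
# ANN I integrates the selected CEIs; for each patient the remaining
# reference patients are divided into m nearly equal blocks by ascending
# distance, a chosen division d yields four derivative features, and a
# second RBF network (ANN II) integrates those.

# Block sizes for dividing n items into m nearly equal contiguous blocks:
# n = q*m + r gives the first r blocks q+1 members (the extras go to the
# nearest divisions).
division_sizes <- function(n, m) {
  if (m < 1) stop("m must be >= 1")
  if (n < m) stop("cannot divide ", n, " patients into ", m, " divisions")
  q <- n %/% m
  r <- n %% m
  sizes <- rep.int(q, m)
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  as.integer(sizes)
}

#' Divide a patient's neighbors into distance-ranked divisions
#'
#' Sorts the other patients by ascending distance to the index patient
#' (stable ties by patient ID) and splits them into `m` mutually exclusive
#' contiguous divisions of nearly equal size; when sizes cannot be equal,
#' the extra members go to the nearest (lowest-index) divisions. Division
#' 1 always holds the most similar patients.
#'
#' @param distances named numeric vector of distances from the index
#'   patient to every other patient (self excluded by the caller).
#' @param m number of divisions.
#' @return list of length `m`; element `d` is the character vector of
#'   patient IDs (or indices when unnamed) in division `d`.
#' @export
assign_divisions <- function(distances, m) {
  n <- length(distances)
  sizes <- division_sizes(n, m)
  ids <- names(distances)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(distances, ids)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(m), function(d) ids[ord[starts[d]:ends[d]]])
}

#' Derivative features of one patient
#'
#' The four neighborhood-derived inputs of the second-stage network:
#' `f1` the patient's own first-stage score; `f2` the mean first-stage
#' score of the reference patients in division `d`; `f3` the mean distance
#' to those patients; `f4` the observed ILD proportion among them.
#'
#' @param own_output first-stage network score of the index patient.
#' @param distances named distances from the index patient to the
#'   reference patients (excluding the patient itself when it belongs to
#'   the reference cohort).
#' @param ref_outputs named first-stage scores of the reference patients.
#' @param ref_ild named logical: is each reference patient ILD?
#' @param m,d division count and chosen division index (1 = most similar).
#' @return named numeric vector `c(f1, f2, f3, f4)`.
#' @export
derivative_features <- function(own_output, distances, ref_outputs, ref_ild,
                                m, d) {
  if (d < 1 || d > m) stop("division index d must lie in 1..m")
  div <- assign_divisions(distances, m)[[d]]
  if (length(div) == 0) stop("empty division")
  c(f1 = unname(own_output),
    f2 = mean(ref_outputs[div]),
    f3 = mean(distances[div]),
    f4 = mean(ref_ild[div]))
}

# Derivative feature matrix for all reference patients, leave-self-out.
# ord_list[[i]] is the index order of the other patients by (distance, id).
reference_features <- function(dmat, f1, ild, m, d) {
  n <- nrow(dmat)
  sizes <- division_sizes(n - 1, m)
  ends <- cumsum(sizes)
  start <- if (d == 1) 1L else ends[d - 1] + 1L
  block <- start:ends[d]
  out <- matrix(NA_real_, n, 4,
                dimnames = list(rownames(dmat), c("f1", "f2", "f3", "f4")))
  ids <- rownames(dmat)
  for (i in seq_len(n)) {
    di <- dmat[i, -i]
    oi <- order(di, ids[-i])[block]
    out[i, ] <- c(f1[i], mean(f1[-i][oi]), mean(di[oi]), mean(ild[-i][oi]))
  }
  out
}

#' Train the two-stage cascade
#'
#' Fits the full deployable predictor on a model-building cohort (HEALTHY
#' and ILD only): (1) 0-1 normalization of the input CEIs, frozen for all
#' later cohorts; (2) the first-stage RBF network ("ANN I") under the
#' 2:1:1 holdout protocol; (3) pairwise Euclidean distances between all
#' reference patients in input space; (4) for every division scheme
#' (m, d), m in `m_values`, d in 1..m, a candidate second-stage network on
#' the four derivative features; (5) selection of the candidate with the
#' highest Youden J as "ANN II", and its ROC-optimal cutoff as the
#' decision threshold.
#'
#' @param cohort model-building `ild_cohort` (no PF records) with complete
#'   values for `inputs`.
#' @param inputs CEI names feeding the first-stage network (e.g. the set
#'   chosen by [forward_select_inputs()]).
#' @param m_values division counts to explore (default 5, 10, 15, 20:
#'   50 candidates).
#' @param k_centers,ridge RBF hyperparameters shared by both stages.
#' @param seed pipeline seed; per-stage seeds are derived by fixed offsets.
#' @param evaluation `"pooled"` scores every reference patient with each
#'   trained candidate and summarizes that ROC (default); `"holdout"`
#'   summarizes the candidate's 2:1:1 testing subset only.
#' @return list with `model` (class `cascade_model`) and `report` (class
#'   `candidate_report`: one row per (m, d) candidate in screening-table
#'   shape, attribute `selected`).
#' @export
train_cascade <- function(cohort, inputs, m_values = c(5, 10, 15, 20),
                          k_centers = 12, ridge = 1e-6, seed = 1,
                          evaluation = c("pooled", "holdout")) {
  evaluation <- match.arg(evaluation)
  if (any(cohort$data$lung_status == "PF")) {
    stop("cohort contains PF records; apply model_building_subset() first")
  }
  if (length(inputs) == 0) stop("no input CEIs")
  cohort <- filter_complete(cohort, inputs)
  y <- cohort$data$lung_status == "ILD"
  if (sum(y) == 0 || sum(!y) == 0) stop("need both HEALTHY and ILD records")

  norm <- fit_normalization(cohort, inputs)
  ncoh <- apply_normalization(norm, cohort)
  x <- cei_matrix(ncoh, inputs)
  ids <- rownames(x)

  ann1 <- holdout_fit(x, y, k_centers = k_centers, ridge = ridge,
                      seed = derive_seed(seed, 1))
  f1 <- stats::setNames(predict(ann1$model, x), ids)
  y <- stats::setNames(y, ids)
  dmat <- as.matrix(stats::dist(x))
  dimnames(dmat) <- list(ids, ids)

  seed2 <- derive_seed(seed, 2)
  rows <- list()
  fits <- list()
  for (m in m_values) {
    for (d in seq_len(m)) {
      cid <- sprintf("%dD%d", m, d)
      res <- tryCatch({
        feat <- reference_features(dmat, f1, y, m, d)
        hf <- holdout_fit(feat, y, k_centers = k_centers, ridge = ridge,
                          seed = seed2)
        if (evaluation == "pooled") {
          sc <- predict(hf$model, feat)
          summ <- roc_summary(sc, y, direction = "positive")
        } else {
          te <- hf$report$test_idx
          sc_te <- predict(hf$model, feat[te, , drop = FALSE])
          summ <- roc_summary(sc_te, y[te], direction = "positive")
          sc <- predict(hf$model, feat)
        }
        list(fit = hf, feat = feat, scores = sc, summ = summ)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[cid]] <- data.frame(model = cid, m = m, d = d, auc = NA_real_,
                                  youden_j = NA_real_, sensitivity = NA_real_,
                                  specificity = NA_real_,
                                  sens_at_spec80 = NA_real_, dor = NA_real_,
                                  failed = TRUE, stringsAsFactors = FALSE)
      } else {
        s <- res$summ
        rows[[cid]] <- data.frame(model = cid, m = m, d = d, auc = s$auc,
                                  youden_j = s$youden_j,
                                  sensitivity = s$sensitivity,
                                  specificity = s$specificity,
                                  sens_at_spec80 = s$sens_at_spec80,
                                  dor = s$dor, failed = FALSE,
                                  stringsAsFactors = FALSE)
        fits[[cid]] <- res
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (all(report$failed)) stop("every division-scheme candidate failed to train")
  ok <- which(!report$failed)
  best <- ok[which.max(report$youden_j[ok])]
  sel <- report$model[best]
  chosen <- fits[[sel]]
  cut <- optimal_cutoff(roc_curve(chosen$scores, y, "positive"))

  model <- structure(list(
    norm = norm, inputs = inputs,
    ann1 = ann1$model, ann1_report = ann1$report,
    reference = list(ids = ids, x = x, ild = y, f1 = f1,
                     lung_status = as.character(cohort$data$lung_status)),
    m = report$m[best], d = report$d[best],
    ann2 = chosen$fit$model, ann2_report = chosen$fit$report,
    cutoff = cut$threshold,
    k_centers = k_centers, ridge = ridge, seed = seed,
    evaluation = evaluation), class = "cascade_model")

  class(report) <- c("candidate_report", "data.frame")
  attr(report, "selected") <- sel
  list(model = model, report = report)
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("cascade_model:\n")
  cat("  inputs:", paste(x$inputs, collapse = ", "), "\n")
  cat(sprintf("  ANN I : %d-%d-1; ANN II: 4-%d-1 on division scheme %dD%d\n",
              length(x$inputs), x$k_centers, x$k_centers, x$m, x$d))
  cat(sprintf("  reference cohort: %d patients; decision cutoff %.4f\n",
              length(x$reference$ids), x$cutoff))
  invisible(x)
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("candidate_report:", nrow(x), "division-scheme candidates; selected:",
      attr(x, "selected"), "\n")
  df <- as.data.frame(x)
  print.data.frame(utils::head(df[order(-df$youden_j), ], 8), digits = 3)
  invisible(x)
}

#' Write a candidate report in the standard model-table layout
#'
#' Columns: Model, AUC, Youden index, SE, SP, SE_SP=0.8, DOR; rows are
#' labeled `{m}D{d}`.
#'
#' @param report a `candidate_report`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path, sep = ",") {
  out <- data.frame(Model = report$model, AUC = report$auc,
                    `Youden index` = report$youden_j, SE = report$sensitivity,
                    SP = report$specificity, `SE_SP=0.8` = report$sens_at_spec80,
                    DOR = report$dor, check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score patients with a trained cascade
#'
#' Each patient is normalized through the frozen training normalizer
#' (out-of-range values clipped to \[0, 1\]), scored by the first-stage
#' network, located among the reference patients by Euclidean distance,
#' given derivative features from the model's division scheme, and scored
#' by the second-stage network. A patient whose ID matches a reference
#' patient is scored leave-self-out, reproducing its training-time score;
#' external patients use the full reference cohort. Patients missing an
#' input CEI get `NA` scores (with a warning); the rest proceed.
#'
#' @param model a `cascade_model`.
#' @param cohort `ild_cohort` carrying the model's input CEIs.
#' @return data.frame (class `cascade_scores`) with `patient_id`,
#'   `lung_status`, `score` in \[0, 1\] and `call` (`score >= cutoff`);
#'   attribute `clip_fraction` records the share of normalized values
#'   clipped.
#' @export
predict_cascade <- function(model, cohort) {
  stopifnot(inherits(model, "cascade_model"))
  absent <- setdiff(model$inputs, cei_names(cohort))
  if (length(absent) > 0) {
    stop("cohort lacks model input CEI(s): ", paste(absent, collapse = ", "))
  }
  ncoh <- apply_normalization(model$norm, cohort)
  xq <- cei_matrix(ncoh, model$inputs)
  complete <- stats::complete.cases(xq)
  if (any(!complete)) {
    warning(sum(!complete), " patient(s) missing input CEIs scored as NA")
  }
  n <- nrow(xq)
  scores <- rep(NA_real_, n)
  if (any(complete)) {
    xc <- xq[complete, , drop = FALSE]
    f1q <- predict(model$ann1, xc)
    ref <- model$reference
    names(ref$f1) <- ref$ids
    names(ref$ild) <- ref$ids
    dq <- sqrt(cross_dist2(xc, ref$x))
    rownames(dq) <- rownames(xc); colnames(dq) <- ref$ids
    feats <- matrix(NA_real_, nrow(xc), 4)
    for (i in seq_len(nrow(xc))) {
      di <- dq[i, ]
      self <- match(rownames(xc)[i], ref$ids)
      if (!is.na(self)) {
        feats[i, ] <- derivative_features(f1q[i], di[-self], ref$f1[-self],
                                          ref$ild[-self], model$m, model$d)
      } else {
        feats[i, ] <- derivative_features(f1q[i], di, ref$f1, ref$ild,
                                          model$m, model$d)
      }
    }
    scores[complete] <- predict(model$ann2, feats)
  }
  out <- data.frame(patient_id = cohort$data$patient_id,
                    lung_status = as.character(cohort$data$lung_status),
                    score = scores, call = scores >= model$cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "clip_fraction") <- attr(ncoh, "clip_fraction")
  class(out) <- c("cascade_scores", "data.frame")
  out
}
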