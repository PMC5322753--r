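# Screening of ILD-associated CEIs and greedy forward selection of the
# first-stage network inputs.

#' Screen CEIs for association with ILD status
#'
#' Each registered CEI is put through ROC analysis (ILD = positive class,
#' direction chosen so AUC >= 0.5) on the model-building cohort. A CEI is
#' flagged as ILD-associated when its AUC is significantly larger than 0.5
#' (two-sided DeLong test, `p < alpha`). CEIs are ranked by the Youden
#' index of their optimal cutoff. No multiple-testing correction is
#' applied, by design: the screen reproduces the single-indicator protocol
#' exactly as practised, and the downstream greedy selection re-evaluates
#' candidates jointly.
#'
#' @param cohort model-building `ild_cohort` (HEALTHY and ILD only; run
#'   [model_building_subset()] first if PF records are present).
#' @param alpha significance level of the AUC-vs-0.5 screen.
#' @return object of class `ild_screening`: a data.frame with one row per
#'   CEI (AUC, SE of AUC, p-value, optimal cutoff, sensitivity,
#'   specificity, Youden J, sensitivity at specificity 0.8, DOR,
#'   association verdict, direction), ranked by Youden J.
#' @export
screen_ceis <- function(cohort, alpha = 0.05) {
  if (any(cohort$data$lung_status == "PF")) {
    stop("cohort contains PF records; apply model_building_subset() before screening")
  }
  y <- cohort$data$lung_status == "ILD"
  if (sum(y) == 0 || sum(!y) == 0) {
    stop("screening needs both HEALTHY and ILD records")
  }
  rows <- lapply(cei_names(cohort), function(cc) {
    v <- cohort$data[[cc]]
    ok <- !is.na(v)
    s <- roc_summary(v[ok], y[ok], direction = "auto", alpha = alpha)
    cbind(data.frame(cei = cc,
                     class = cohort$registry$class[cohort$registry$cei == cc],
                     n_used = sum(ok), stringsAsFactors = FALSE),
          s)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$youden_j, out$cei), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ild_screening", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.ild_screening <- function(x, ...) {
  cat("ild_screening:", nrow(x), "CEIs,", sum(x$associated),
      "ILD-associated (alpha =", attr(x, "alpha"), ")\n")
  print.data.frame(utils::head(as.data.frame(x)[, c("cei", "auc", "youden_j",
                                                    "p_vs_half", "associated")], 10),
                   digits = 3)
  invisible(x)
}

#' Write a screening report in the standard screening-table layout
#'
#' Columns: CEI, AUC, Youden index, SE, SP, SE_SP=0.8, DOR.
#'
#' @param screening an `ild_screening`.
#' @param path output path.
#' @param sep field separator.
#' @param associated_only keep only the flagged CEIs (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_screening <- function(screening, path, sep = ",", associated_only = TRUE) {
  x <- as.data.frame(screening)
  if (associated_only) x <- x[x$associated, , drop = FALSE]
  out <- data.frame(CEI = x$cei, AUC = x$auc, `Youden index` = x$youden_j,
                    SE = x$sensitivity, SP = x$specificity,
                    `SE_SP=0.8` = x$sens_at_spec80, DOR = x$dor,
                    check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Greedy forward selection of first-stage network inputs
#'
#' Starting from the empty set, each step trains an RBF network (from the
#' same base seed, so steps differ only by input set) on the current
#' inputs plus each remaining candidate, scores the full model-building
#' cohort, and adds the candidate whose model output attains the highest
#' Youden J. The loop continues until all candidates are included; the
#' chosen input set is the prefix at which J peaks. Ties in J break toward
#' the candidate with the higher single-CEI AUC.
#'
#' @param cohort normalized model-building `ild_cohort` (apply
#'   [apply_normalization()] first; network inputs must live in \[0, 1\]).
#' @param candidates CEI names to select from (typically the associated
#'   set from [screen_ceis()]).
#' @param k_centers,ridge RBF hyperparameters (see [train_rbf()]).
#' @param seed base seed reused at every step.
#' @param evaluation `"resubstitution"` scores the full cohort with the
#'   trained model (default); `"holdout"` trains under the 2:1:1 protocol
#'   and evaluates J on the testing subset only.
#' @return object of class `selection_trace`: data.frame with `step`,
#'   `cei`, `youden_j`; attribute `chosen` holds the selected input set.
#' @export
forward_select_inputs <- function(cohort, candidates, k_centers = 12,
                                  ridge = 1e-6, seed = 1,
                                  evaluation = c("resubstitution", "holdout")) {
  evaluation <- match.arg(evaluation)
  if (length(candidates) == 0) stop("no candidate CEIs supplied")
  if (is.null(attr(cohort, "normalized_ceis")) ||
      !all(candidates %in% attr(cohort, "normalized_ceis"))) {
    stop("cohort must be normalized over every candidate CEI (apply_normalization)")
  }
  y <- cohort$data$lung_status == "ILD"
  x_all <- cei_matrix(cohort, candidates)
  if (anyNA(x_all)) stop("candidates contain missing values; filter_complete() first")

  # single-CEI AUCs for deterministic tie-breaking
  single_auc <- vapply(candidates, function(cc) {
    roc_curve(x_all[, cc], y, "auto")$auc
  }, 0)

  eval_j <- function(inputs) {
    xm <- x_all[, inputs, drop = FALSE]
    if (evaluation == "resubstitution") {
      fit <- train_rbf(xm, y, k_centers = k_centers, ridge = ridge, seed = seed)
      sc <- predict(fit, xm)
      optimal_cutoff(roc_curve(sc, y, "positive"))$youden
    } else {
      hf <- holdout_fit(xm, y, k_centers = k_centers, ridge = ridge, seed = seed)
      te <- hf$report$test_idx
      sc <- predict(hf$model, xm[te, , drop = FALSE])
      optimal_cutoff(roc_curve(sc, y[te], "positive"))$youden
    }
  }

  chosen <- character(0)
  remaining <- candidates
  trace <- data.frame(step = integer(0), cei = character(0),
                      youden_j = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  while (length(remaining) > 0) {
    step <- step + 1L
    js <- vapply(remaining, function(cc) {
      tryCatch(eval_j(c(chosen, cc)), error = function(e) NA_real_)
    }, 0)
    if (all(is.na(js))) {
      warning("model training failed for every remaining candidate at step ",
              step, "; returning trace so far")
      break
    }
    best_j <- max(js, na.rm = TRUE)
    tied <- remaining[!is.na(js) & js == best_j]
    pick <- tied[which.max(single_auc[tied])]
    chosen <- c(chosen, pick)
    trace <- rbind(trace, data.frame(step = step, cei = pick,
                                     youden_j = best_j,
                                     stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, pick)
  }
  best_prefix <- which.max(trace$youden_j)
  structure(trace, class = c("selection_trace", "data.frame"),
            chosen = trace$cei[seq_len(best_prefix)], seed = seed,
            evaluation = evaluation)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("selection_trace (", attr(x, "evaluation"), "):\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 3)
  cat("chosen inputs:", paste(attr(x, "chosen"), collapse = ", "), "\n")
  invisible(x)
}
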