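# Cohort container, I/O, inclusion filtering and 0-1 normalization.

LUNG_STATUS_LEVELS <- c("HEALTHY", "ILD", "PF")
CEI_CLASSES <- c("basic", "blood", "urine")

#' Construct a patient cohort
#'
#' An `ild_cohort` bundles one row per patient (ID, lung status, numeric
#' clinical examination indicator (CEI) values) with a registry describing
#' each CEI's name and class (basic / blood / urine).
#'
#' @param data data.frame with columns `patient_id`, `lung_status`
#'   (case-insensitive "healthy", "ILD" or "PF"), and one numeric column per
#'   CEI. Missing CEI values are allowed (they are removed by
#'   [filter_complete()], never imputed).
#' @param registry data.frame with columns `cei` and `class`; `cei` must
#'   match the CEI columns of `data`. If omitted, all CEI columns are
#'   registered with class `"blood"`.
#' @return An object of class `ild_cohort`: a list with elements `data`
#'   (patient table, `lung_status` as factor) and `registry`.
#' @examples
#' df <- data.frame(patient_id = c("a", "b"), lung_status = c("healthy", "ILD"),
#'                  WBC = c(5.1, 7.9), AGE = c(44, 61))
#' coh <- ild_cohort(df)
#' n_patients(coh)
#' @export
ild_cohort <- function(data, registry = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame")
  need <- c("patient_id", "lung_status")
  if (!all(need %in% names(data))) {
    stop("cohort data must have columns 'patient_id' and 'lung_status'")
  }
  data$patient_id <- as.character(data$patient_id)
  if (anyDuplicated(data$patient_id)) {
    dup <- unique(data$patient_id[duplicated(data$patient_id)])
    stop("duplicate patient_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  status_raw <- toupper(as.character(data$lung_status))
  bad <- setdiff(unique(status_raw), LUNG_STATUS_LEVELS)
  if (length(bad) > 0) {
    stop("unknown lung_status label(s): ", paste(bad, collapse = ", "),
         " (expected healthy, ILD or PF, case-insensitive)")
  }
  data$lung_status <- factor(status_raw, levels = LUNG_STATUS_LEVELS)
  cei_cols <- setdiff(names(data), need)
  if (is.null(registry)) {
    registry <- data.frame(cei = cei_cols, class = "blood",
                           stringsAsFactors = FALSE)
  }
  registry$cei <- as.character(registry$cei)
  registry$class <- as.character(registry$class)
  if (!setequal(registry$cei, cei_cols)) {
    stop("registry CEIs do not match the cohort's CEI columns")
  }
  if (!all(registry$class %in% CEI_CLASSES)) {
    stop("registry classes must be one of: ", paste(CEI_CLASSES, collapse = ", "))
  }
  for (cc in cei_cols) {
    if (!is.numeric(data[[cc]])) {
      data[[cc]] <- suppressWarnings(as.numeric(as.character(data[[cc]])))
    }
  }
  data <- data[, c(need, registry$cei), drop = FALSE]
  structure(list(data = data, registry = registry), class = "ild_cohort")
}

#' @export
print.ild_cohort <- function(x, ...) {
  tab <- table(x$data$lung_status)
  cat("ild_cohort:", nrow(x$data), "patients (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  cls <- table(factor(x$registry$class, levels = CEI_CLASSES))
  cat("  CEIs:", nrow(x$registry), "(",
      paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "),
      ")\n")
  invisible(x)
}

#' @rdname ild_cohort
#' @param cohort an `ild_cohort`.
#' @export
n_patients <- function(cohort) nrow(cohort$data)

#' @rdname ild_cohort
#' @export
cei_names <- function(cohort) cohort$registry$cei

#' Extract CEI values as a numeric matrix
#'
#' @param cohort an `ild_cohort`.
#' @param ceis character vector of CEI names (default: all registered CEIs).
#' @return numeric matrix, rows named by `patient_id`.
#' @export
cei_matrix <- function(cohort, ceis = cei_names(cohort)) {
  missing_ceis <- setdiff(ceis, cei_names(cohort))
  if (length(missing_ceis) > 0) {
    stop("CEI(s) not in cohort registry: ", paste(missing_ceis, collapse = ", "))
  }
  m <- as.matrix(cohort$data[, ceis, drop = FALSE])
  rownames(m) <- cohort$data$patient_id
  m
}

#' Read a cohort from a delimited text file
#'
#' Expects a header row with `patient_id` and `lung_status` columns followed
#' by numeric CEI columns. Unparseable numeric cells become missing values.
#'
#' @param path file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @param registry optional CEI registry (see [ild_cohort()]).
#' @param missing_token string treated as missing (default: the empty cell;
#'   `"NA"` is always treated as missing).
#' @param id_col,status_col names of the ID and label columns in the file.
#' @return an `ild_cohort`.
#' @export
read_cohort <- function(path, sep = ",", registry = NULL, missing_token = "",
                        id_col = "patient_id", status_col = "lung_status") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = unique(c("NA", missing_token)))
  if (!all(c(id_col, status_col) %in% names(df))) {
    stop("file ", path, " is missing header column(s): ",
         paste(setdiff(c(id_col, status_col), names(df)), collapse = ", "))
  }
  names(df)[names(df) == id_col] <- "patient_id"
  names(df)[names(df) == status_col] <- "lung_status"
  ild_cohort(df, registry = registry)
}

#' Write a cohort to a delimited text file
#'
#' @param cohort an `ild_cohort`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(cohort$data, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Keep only patients with complete values for the listed CEIs
#'
#' Mirrors the study inclusion rule: patients with inadequate examinations
#' are excluded, never imputed.
#'
#' @param cohort an `ild_cohort`.
#' @param ceis CEI names that must be non-missing (default: all).
#' @return filtered `ild_cohort`; warns (does not fail) when empty.
#' @export
filter_complete <- function(cohort, ceis = cei_names(cohort)) {
  if (length(ceis) == 0) return(cohort)
  m <- cei_matrix(cohort, ceis)
  keep <- stats::complete.cases(m)
  if (!any(keep)) warning("filter_complete: no complete records remain")
  cohort$data <- cohort$data[keep, , drop = FALSE]
  rownames(cohort$data) <- NULL
  cohort
}

#' Restrict a cohort to the model-building classes (HEALTHY and ILD)
#'
#' Patients with established pulmonary fibrosis (PF) are excluded from
#' screening, network construction and model training; they are reserved
#' for positive-only evaluation.
#'
#' @param cohort an `ild_cohort`.
#' @return `ild_cohort` containing only HEALTHY and ILD records.
#' @export
model_building_subset <- function(cohort) {
  keep <- cohort$data$lung_status %in% c("HEALTHY", "ILD")
  cohort$data <- cohort$data[keep, , drop = FALSE]
  rownames(cohort$data) <- NULL
  cohort
}

#' Fit 0-1 (min-max) normalization parameters on a reference cohort
#'
#' @param cohort reference `ild_cohort` (typically the model-building set).
#' @param ceis CEI names to normalize.
#' @return object of class `ild_norm`: per-CEI (min, max) frozen for reuse
#'   on later cohorts.
#' @export
fit_normalization <- function(cohort, ceis = cei_names(cohort)) {
  m <- cei_matrix(cohort, ceis)
  lo <- apply(m, 2, min, na.rm = TRUE)
  hi <- apply(m, 2, max, na.rm = TRUE)
  const <- ceis[!(hi > lo)]
  if (length(const) > 0) {
    stop("cannot normalize constant CEI(s): ", paste(const, collapse = ", "))
  }
  structure(list(cei = ceis, min = lo, max = hi), class = "ild_norm")
}

#' @export
print.ild_norm <- function(x, ...) {
  cat("ild_norm: 0-1 scaling for", length(x$cei), "CEI(s)\n")
  invisible(x)
}

#' Apply frozen 0-1 normalization to a cohort
#'
#' Values map through (value - min) / (max - min) with the reference
#' min/max; values from new cohorts that fall outside the reference range
#' are clipped to \[0, 1\] so downstream network inputs stay in the trained
#' domain.
#'
#' @param params an `ild_norm` from [fit_normalization()].
#' @param cohort an `ild_cohort` carrying the normalized CEIs.
#' @return `ild_cohort` with the listed CEIs rescaled; carries attribute
#'   `normalized_ceis` and `clip_fraction` (share of values clipped).
#' @export
apply_normalization <- function(params, cohort) {
  if (!inherits(params, "ild_norm")) stop("`params` must be an ild_norm")
  absent <- setdiff(params$cei, cei_names(cohort))
  if (length(absent) > 0) {
    stop("cohort lacks normalized CEI(s): ", paste(absent, collapse = ", "))
  }
  clipped <- 0L; total <- 0L
  for (k in seq_along(params$cei)) {
    cc <- params$cei[k]
    v <- (cohort$data[[cc]] - params$min[k]) / (params$max[k] - params$min[k])
    ok <- !is.na(v)
    clipped <- clipped + sum(v[ok] < 0 | v[ok] > 1)
    total <- total + sum(ok)
    cohort$data[[cc]] <- pmin(1, pmax(0, v))
  }
  attr(cohort, "normalized_ceis") <- params$cei
  attr(cohort, "clip_fraction") <- if (total > 0) clipped / total else 0
  cohort
}
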