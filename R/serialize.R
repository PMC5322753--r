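# Plain-text, versioned serialization of trained models so cascade
# bundles are portable across sessions and machines.

SERIAL_VERSION <- "1"

#' Write / read an RBF network as a self-describing JSON file
#'
#' The payload is plain-text numeric (full precision) with a format
#' version, so bundles remain diffable and portable.
#'
#' @param model an `rbf_model`.
#' @param path file path.
#' @return `write_rbf`: `path` invisibly; `read_rbf`: the `rbf_model`.
#' @export
write_rbf <- function(model, path) {
  stopifnot(inherits(model, "rbf_model"))
  payload <- list(format = "ildcascade/rbf", version = SERIAL_VERSION,
                  dim = model$dim, k_centers = model$k_centers,
                  ridge = model$ridge, width_mult = model$width_mult,
                  seed = model$seed, centers = model$centers,
                  sigma = model$sigma, weights = model$weights,
                  output_bounds = model$output_bounds)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rbf
#' @export
read_rbf <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ildcascade/rbf")) {
    stop(path, " is not an RBF model file")
  }
  structure(list(centers = matrix(p$centers, ncol = p$dim),
                 sigma = as.numeric(p$sigma), weights = as.numeric(p$weights),
                 output_bounds = as.numeric(p$output_bounds),
                 dim = as.integer(p$dim), k_centers = as.integer(p$k_centers),
                 ridge = p$ridge, width_mult = p$width_mult, seed = p$seed),
            class = "rbf_model")
}

#' Write / read a cascade model bundle
#'
#' A bundle is a directory holding a versioned `manifest.json` (config,
#' division scheme, decision cutoff), `norm.json`, `ann1.json`,
#' `ann2.json` and `reference.csv` (the frozen reference cohort:
#' coordinates, labels and first-stage scores). All files are plain text.
#'
#' @param model a `cascade_model`.
#' @param path bundle directory (created if needed).
#' @return `write_cascade`: `path` invisibly; `read_cascade`: the
#'   `cascade_model`.
#' @export
write_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "ildcascade/cascade", version = SERIAL_VERSION,
                   inputs = model$inputs, m = model$m, d = model$d,
                   cutoff = model$cutoff, k_centers = model$k_centers,
                   ridge = model$ridge, seed = model$seed,
                   evaluation = model$evaluation)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(list(format = "ildcascade/norm", version = SERIAL_VERSION,
                            cei = model$norm$cei, min = model$norm$min,
                            max = model$norm$max),
                       file.path(path, "norm.json"), digits = NA,
                       auto_unbox = TRUE)
  write_rbf(model$ann1, file.path(path, "ann1.json"))
  write_rbf(model$ann2, file.path(path, "ann2.json"))
  ref <- data.frame(patient_id = model$reference$ids,
                    lung_status = model$reference$lung_status,
                    ild = model$reference$ild, f1 = model$reference$f1,
                    model$reference$x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(format(ref, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(path, "reference.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cascade
#' @export
read_cascade <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "ildcascade/cascade")) {
    stop(path, " is not a cascade model bundle")
  }
  nj <- jsonlite::read_json(file.path(path, "norm.json"), simplifyVector = TRUE)
  norm <- structure(list(cei = nj$cei, min = stats::setNames(nj$min, nj$cei),
                         max = stats::setNames(nj$max, nj$cei)),
                    class = "ild_norm")
  ref_df <- utils::read.table(file.path(path, "reference.csv"), header = TRUE,
                              sep = ",", stringsAsFactors = FALSE,
                              check.names = FALSE)
  x <- as.matrix(ref_df[, man$inputs, drop = FALSE])
  rownames(x) <- ref_df$patient_id
  structure(list(norm = norm, inputs = man$inputs,
                 ann1 = read_rbf(file.path(path, "ann1.json")),
                 ann1_report = NULL,
                 reference = list(ids = ref_df$patient_id, x = x,
                                  ild = stats::setNames(as.logical(ref_df$ild),
                                                        ref_df$patient_id),
                                  f1 = stats::setNames(as.numeric(ref_df$f1),
                                                       ref_df$patient_id),
                                  lung_status = ref_df$lung_status),
                 m = as.integer(man$m), d = as.integer(man$d),
                 ann2 = read_rbf(file.path(path, "ann2.json")),
                 ann2_report = NULL, cutoff = as.numeric(man$cutoff),
                 k_centers = as.integer(man$k_centers), ridge = man$ridge,
                 seed = man$seed, evaluation = man$evaluation),
            class = "cascade_model")
}
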