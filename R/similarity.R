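# Euclidean distances in normalized CEI space and the patient-patient
# similarity network (PPSN).

#' Pairwise Euclidean distances between patients
#'
#' Each patient becomes a point in the n-dimensional space whose
#' coordinates are the listed (normalized) CEIs; the standard Euclidean
#' metric gives every patient-patient distance.
#'
#' @param cohort normalized `ild_cohort`.
#' @param ceis coordinate CEIs (typically the selected first-stage network
#'   inputs).
#' @return symmetric matrix of class `ppsn_dist` with patient IDs as
#'   dimnames; carries the coordinate CEIs and per-patient lung status as
#'   attributes.
#' @export
pairwise_distances <- function(cohort, ceis) {
  m <- cei_matrix(cohort, ceis)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing value: patient ", rownames(m)[bad[1]], ", CEI ",
         colnames(m)[bad[2]], " (filter_complete() first)")
  }
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(d, class = c("ppsn_dist", "matrix"),
            ceis = ceis,
            lung_status = stats::setNames(as.character(cohort$data$lung_status),
                                          cohort$data$patient_id))
}

# Upper-triangle pairs of a distance matrix ordered by (distance, id pair).
ranked_pairs <- function(dm) {
  ids <- rownames(dm)
  n <- length(ids)
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  pairs <- data.frame(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                      distance = dm[ut], stringsAsFactors = FALSE)
  swap <- pairs$id_a > pairs$id_b
  tmp <- pairs$id_a[swap]; pairs$id_a[swap] <- pairs$id_b[swap]; pairs$id_b[swap] <- tmp
  pairs[order(pairs$distance, pairs$id_a, pairs$id_b), , drop = FALSE]
}

#' Build a patient-patient similarity network
#'
#' Retains exactly the `n_edges` smallest pairwise distances as undirected
#' edges; every patient is a node regardless of degree. Distance ties at
#' the edge-count boundary break by lexicographic patient-ID pair, so the
#' graph is deterministic.
#'
#' @param dm a `ppsn_dist` from [pairwise_distances()].
#' @param n_edges number of edges to retain, between 0 and n(n-1)/2.
#' @return an [igraph][igraph::igraph-package] graph with node attribute
#'   `lung_status` and edge attribute `distance`.
#' @export
build_ppsn <- function(dm, n_edges) {
  stopifnot(inherits(dm, "ppsn_dist"))
  ids <- rownames(dm)
  n <- length(ids)
  max_edges <- n * (n - 1) / 2
  if (n_edges < 0 || n_edges > max_edges) {
    stop("n_edges must be between 0 and ", max_edges)
  }
  status <- attr(dm, "lung_status")[ids]
  vertices <- data.frame(name = ids, lung_status = unname(status),
                         stringsAsFactors = FALSE)
  pairs <- ranked_pairs(dm)[seq_len(n_edges), , drop = FALSE]
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = vertices)
  igraph::graph_attr(g, "n_edges") <- as.integer(n_edges)
  igraph::graph_attr(g, "ceis") <- paste(attr(dm, "ceis"), collapse = ",")
  g
}

#' Average number of neighbors in a PPSN
#'
#' Mean node degree, 2|E|/|V|, with isolated nodes included.
#'
#' @param g an igraph graph (e.g. from [build_ppsn()]).
#' @return mean degree.
#' @export
average_neighbors <- function(g) {
  nv <- igraph::vcount(g)
  if (nv == 0) stop("graph has no nodes")
  2 * igraph::ecount(g) / nv
}

#' Export a PPSN to disk
#'
#' `"graphml"` writes standard GraphML (node attribute `lung_status`, edge
#' attribute `distance`; importable by Cytoscape and other graph tools).
#' `"edgelist"` writes a tab-separated edge table `id_a  id_b  distance`
#' with header, plus a companion node-attribute table at
#' `<path>.nodes.tsv` (`patient_id  lung_status`) so isolated nodes and
#' their status survive the round trip.
#'
#' @param g graph from [build_ppsn()].
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(g, what = "edges")
    names(ed)[1:2] <- c("id_a", "id_b")
    utils::write.table(ed[, c("id_a", "id_b", "distance")], path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    nd <- igraph::as_data_frame(g, what = "vertices")
    names(nd)[names(nd) == "name"] <- "patient_id"
    utils::write.table(nd[, c("patient_id", "lung_status")],
                       paste0(path, ".nodes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Re-import an exported PPSN
#'
#' Inverse of [export_graph()]; used to verify round trips.
#'
#' @param path file written by [export_graph()].
#' @param format `"edgelist"` or `"graphml"`.
#' @return an igraph graph.
#' @export
import_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  ed <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  nd <- utils::read.table(paste0(path, ".nodes.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  names(nd)[names(nd) == "patient_id"] <- "name"
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
}
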