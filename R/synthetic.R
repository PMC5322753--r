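# Synthetic cohort generator: three-class lung status, 32 CEIs with a
# minority of weakly informative indicators, optional latent patient
# clusters with cluster-level ILD enrichment, and MCAR missingness.

#' Effect size for a target single-CEI AUC
#'
#' Under the equal-variance binormal model a mean shift of delta standard
#' deviations gives AUC = Phi(delta / sqrt(2)); these helpers invert and
#' apply that identity, which is what keeps the generator's AUC
#' calibration exact for Gaussian CEIs.
#'
#' @param auc target AUC in (0, 1).
#' @param delta standardized mean shift.
#' @return `auc_to_delta`: the shift; `binormal_auc`: the AUC implied by a
#'   shift.
#' @export
auc_to_delta <- function(auc) sqrt(2) * stats::qnorm(auc)

#' @rdname auc_to_delta
#' @export
binormal_auc <- function(delta) stats::pnorm(abs(delta) / sqrt(2))

#' Latent cluster specification for the generator
#'
#' Patients receive latent cluster centers in CEI space and
#' cluster-specific ILD prevalences, creating the correlation between
#' neighborhood and label that the second-stage network exploits. Cluster
#' prevalences are spread around the cohort ILD fraction by `enrichment`
#' (0 = no label signal in the clusters; larger values push clusters
#' toward purity). The defaults put the latent subpopulation scale (about
#' 533/30, i.e. 18 patients) below both the coarsest division block and
#' the resolution of a 12-center first-stage network, which is the regime
#' in which neighborhood label composition carries information the
#' first-stage network cannot express.
#'
#' @param n_clusters number of latent clusters.
#' @param center_sd spread of the cluster centers, in units of each
#'   shifted CEI's SD.
#' @param enrichment width of the cluster-prevalence spread, in
#'   probability units.
#' @param prevalences optional explicit per-cluster ILD prevalences
#'   (overrides `enrichment`).
#' @return a `cluster_spec` list.
#' @export
cluster_spec <- function(n_clusters = 30, center_sd = 2.5, enrichment = 1.2,
                         prevalences = NULL) {
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (enrichment < 0 || enrichment >= 2) stop("enrichment must lie in [0, 2)")
  if (!is.null(prevalences) && length(prevalences) != n_clusters) {
    stop("prevalences must have length n_clusters")
  }
  structure(list(n_clusters = as.integer(n_clusters), center_sd = center_sd,
                 enrichment = enrichment, prevalences = prevalences),
            class = "cluster_spec")
}

#' Cohort generator specification
#'
#' @param n_healthy,n_ild,n_pf patient counts per lung status.
#' @param cei_spec data.frame with one row per CEI: `name`, `class`
#'   (basic/blood/urine), `delta` (standardized ILD-vs-HEALTHY mean shift;
#'   0 = null indicator; sign sets the direction of the shift), `mean`,
#'   `sd` (healthy-class distribution), and optional `dist` ("normal",
#'   default, or "lognormal", where `mean`/`sd` are meanlog/sdlog and the
#'   shift acts on the log scale).
#' @param pf_extra_shift multiplier >= 1 on the informative shifts for PF
#'   patients, making PF the "more extreme ILD" end of the severity
#'   ordering.
#' @param clusters optional [cluster_spec()].
#' @param missing_rate completely-at-random missingness probability per
#'   CEI value, in \[0, 1).
#' @param seed integer seed.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_healthy, n_ild, n_pf = 0, cei_spec,
                           pf_extra_shift = 1.3, clusters = NULL,
                           missing_rate = 0, seed = 1) {
  if (n_healthy < 0 || n_ild < 0 || n_pf < 0) stop("counts must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (pf_extra_shift < 1) stop("pf_extra_shift must be >= 1")
  stopifnot(is.data.frame(cei_spec),
            all(c("name", "class", "delta", "mean", "sd") %in% names(cei_spec)))
  if (!"dist" %in% names(cei_spec)) cei_spec$dist <- "normal"
  if (any(cei_spec$sd <= 0)) stop("cei_spec$sd must be positive")
  if (!all(cei_spec$dist %in% c("normal", "lognormal"))) {
    stop("cei_spec$dist must be 'normal' or 'lognormal'")
  }
  if (anyDuplicated(cei_spec$name)) stop("duplicate CEI names in cei_spec")
  if (!is.null(clusters) && !inherits(clusters, "cluster_spec")) {
    stop("clusters must be a cluster_spec()")
  }
  structure(list(n_healthy = as.integer(n_healthy), n_ild = as.integer(n_ild),
                 n_pf = as.integer(n_pf), cei_spec = cei_spec,
                 pf_extra_shift = pf_extra_shift, clusters = clusters,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("generator_spec: %d HEALTHY + %d ILD + %d PF; %d CEIs (%d shifted)%s\n",
              x$n_healthy, x$n_ild, x$n_pf, nrow(x$cei_spec),
              sum(x$cei_spec$delta != 0),
              if (is.null(x$clusters)) "" else sprintf("; %d latent clusters",
                                                       x$clusters$n_clusters)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Informative CEIs are drawn with their mean shifted by `delta * sd` for
#' ILD patients (and `delta * sd * pf_extra_shift` for PF); null CEIs are
#' identically distributed across groups. With a cluster specification,
#' patients are assigned to latent clusters (probability proportional to
#' the cluster's ILD prevalence for ILD/PF patients and its complement
#' for healthy patients) and the shifted CEIs gain cluster-center
#' offsets. Missingness, when requested, is completely at random.
#'
#' @param spec a [generator_spec()].
#' @return an [ild_cohort()] of `n_healthy + n_ild + n_pf` patients.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_healthy + spec$n_ild + spec$n_pf
  if (n == 0) stop("empty cohort requested")
  status <- c(rep("HEALTHY", spec$n_healthy), rep("ILD", spec$n_ild),
              rep("PF", spec$n_pf))
  shift_mult <- c(HEALTHY = 0, ILD = 1, PF = spec$pf_extra_shift)[status]
  cs <- spec$cei_spec

  local_seed(spec$seed, {
    cluster_of <- NULL
    centers <- NULL
    if (!is.null(spec$clusters)) {
      k <- spec$clusters$n_clusters
      prev <- spec$clusters$prevalences
      if (is.null(prev)) {
        p_bar <- if (spec$n_healthy + spec$n_ild > 0) {
          spec$n_ild / (spec$n_healthy + spec$n_ild)
        } else 0.5
        u <- if (k == 1) 0 else seq(-0.5, 0.5, length.out = k)
        prev <- pmin(0.98, pmax(0.02, p_bar + spec$clusters$enrichment * u))
      }
      cluster_of <- integer(n)
      is_case <- status != "HEALTHY"
      cluster_of[is_case] <- sample.int(k, sum(is_case), replace = TRUE,
                                        prob = prev)
      cluster_of[!is_case] <- sample.int(k, sum(!is_case), replace = TRUE,
                                         prob = 1 - prev)
      centers <- matrix(0, k, nrow(cs))
      shifted <- which(cs$delta != 0)
      for (j in shifted) {
        centers[, j] <- stats::rnorm(k, 0, spec$clusters$center_sd * cs$sd[j])
      }
    }

    vals <- matrix(NA_real_, n, nrow(cs))
    colnames(vals) <- cs$name
    for (j in seq_len(nrow(cs))) {
      mu <- cs$mean[j] + cs$delta[j] * cs$sd[j] * shift_mult
      if (!is.null(cluster_of)) mu <- mu + centers[cluster_of, j]
      v <- stats::rnorm(n, mu, cs$sd[j])
      if (cs$dist[j] == "lognormal") v <- exp(v)
      vals[, j] <- v
    }
    if (spec$missing_rate > 0) {
      vals[stats::runif(length(vals)) < spec$missing_rate] <- NA_real_
    }

    df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                     lung_status = status, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(vals))
    cohort <- ild_cohort(df, registry = data.frame(cei = cs$name,
                                                   class = cs$class,
                                                   stringsAsFactors = FALSE))
    if (!is.null(cluster_of)) attr(cohort, "latent_cluster") <- cluster_of
    cohort
  })
}

#' Generator specification emulating the study cohort
#'
#' 32 CEIs in three classes (2 basic, 22 blood, 8 urine) over
#' 169 HEALTHY + 364 ILD + 87 PF patients. Four indicators carry the
#' study-scale signal: age (single-CEI AUC approximately 0.71), and the
#' eosinophil, platelet and white blood cell counts (AUCs approximately
#' 0.56-0.59; the platelet shift is negative, i.e. lower counts in ILD).
#' Four further indicators (neutrophil count and three urine markers) are
#' near-null (AUC approximately 0.53), and the remaining 24 are null.
#'
#' @param n_healthy,n_ild,n_pf group sizes (study composition by default).
#' @param clustered add the latent-cluster structure (off by default; the
#'   study network showed one large cluster, so the unclustered spec is
#'   the baseline emulation).
#' @param clusters [cluster_spec()] used when `clustered = TRUE`.
#' @param missing_rate,seed,pf_extra_shift passed to [generator_spec()].
#' @return a `generator_spec`.
#' @export
default_study_spec <- function(n_healthy = 169, n_ild = 364, n_pf = 87,
                               clustered = FALSE, clusters = cluster_spec(),
                               missing_rate = 0, pf_extra_shift = 1.3,
                               seed = 1) {
  d_age <- auc_to_delta(0.710)
  d_eo <- auc_to_delta(0.562)
  d_plt <- -auc_to_delta(0.569)
  d_wbc <- auc_to_delta(0.587)
  d_near <- auc_to_delta(0.53)
  row <- function(name, class, delta, mean, sd) {
    data.frame(name = name, class = class, delta = delta, mean = mean,
               sd = sd, dist = "normal", stringsAsFactors = FALSE)
  }
  cs <- rbind(
    row("AGE", "basic", d_age, 55, 12),
    row("BMI", "basic", 0, 23, 3.5),
    row("WBC", "blood", d_wbc, 6.5, 2.0),
    row("RBC", "blood", 0, 4.3, 0.5),
    row("HGB", "blood", 0, 128, 15),
    row("HCT", "blood", 0, 39, 4),
    row("MCV", "blood", 0, 90, 5),
    row("MCH", "blood", 0, 30, 2),
    row("MCHC", "blood", 0, 335, 12),
    row("RDW", "blood", 0, 13.5, 1.2),
    row("PLT", "blood", d_plt, 230, 60),
    row("NEUT", "blood", d_near, 4.0, 1.5),
    row("LYMPH", "blood", 0, 1.8, 0.6),
    row("MONO", "blood", 0, 0.45, 0.15),
    row("EO", "blood", d_eo, 0.15, 0.12),
    row("BASO", "blood", 0, 0.03, 0.02),
    row("NEUT_PCT", "blood", 0, 60, 8),
    row("LYMPH_PCT", "blood", 0, 30, 7),
    row("MONO_PCT", "blood", 0, 6.5, 1.8),
    row("EO_PCT", "blood", 0, 2.3, 1.5),
    row("BASO_PCT", "blood", 0, 0.5, 0.3),
    row("MPV", "blood", 0, 10.5, 1.0),
    row("PDW", "blood", 0, 13, 2),
    row("PCT", "blood", 0, 0.24, 0.06),
    row("U_SG", "urine", d_near, 1.018, 0.006),
    row("U_PH", "urine", 0, 6.0, 0.7),
    row("U_WBC", "urine", d_near, 12, 10),
    row("U_WBCH", "urine", d_near, 3, 2.5),
    row("U_RBC", "urine", 0, 4, 3),
    row("U_PRO", "urine", 0, 0.08, 0.06),
    row("U_GLU", "urine", 0, 0.3, 0.3),
    row("U_KET", "urine", 0, 0.05, 0.05))
  generator_spec(n_healthy, n_ild, n_pf, cs,
                 pf_extra_shift = pf_extra_shift,
                 clusters = if (clustered) clusters else NULL,
                 missing_rate = missing_rate, seed = seed)
}

#' The four study-scale informative CEI names in [default_study_spec()]
#' @return character vector `c("AGE", "EO", "PLT", "WBC")`.
#' @export
study_informative_ceis <- function() c("AGE", "EO", "PLT", "WBC")
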