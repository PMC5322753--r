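# Shared fixtures: all built in code at test time.

# Six-patient, four-CEI toy cohort with one missing WBC value.
toy_cohort <- function() {
  ild_cohort(
    data.frame(
      patient_id = paste0("p", 1:6),
      lung_status = c("healthy", "ILD", "pf", "ILD", "healthy", "ILD"),
      AGE = c(40, 65, 70, 55, 48, 61),
      WBC = c(5.0, 8.2, NA, 7.1, 6.0, 9.3),
      PLT = c(250, 180, 160, 210, 240, 170),
      EO = c(0.12, 0.30, 0.40, 0.22, 0.15, 0.28),
      stringsAsFactors = FALSE),
    registry = data.frame(cei = c("AGE", "WBC", "PLT", "EO"),
                          class = c("basic", "blood", "blood", "blood"),
                          stringsAsFactors = FALSE))
}

# Two well-separated Gaussian clusters in d dimensions, scaled to [0, 1].
separable_clusters <- function(n = 200, d = 4, delta = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- matrix(rnorm(n * d), n, d) + delta * y
  x <- apply(x, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  list(x = x, y = y)
}

# Compact generator spec: a few CEIs with chosen deltas, the rest null.
small_spec <- function(n_healthy, n_ild, n_pf = 0, deltas = c(A = 1, B = 0),
                       seed = 1, clusters = NULL, missing_rate = 0,
                       pf_extra_shift = 1.3) {
  cs <- data.frame(name = names(deltas), class = "blood",
                   delta = unname(deltas), mean = 10, sd = 2,
                   dist = "normal", stringsAsFactors = FALSE)
  generator_spec(n_healthy, n_ild, n_pf, cs, seed = seed,
                 clusters = clusters, missing_rate = missing_rate,
                 pf_extra_shift = pf_extra_shift)
}

# Brute-force AUC by exhaustive pair enumeration (ties count 1/2).
brute_auc <- function(scores, is_pos) {
  xs <- scores[is_pos]; ys <- scores[!is_pos]
  tot <- 0
  for (xi in xs) for (yj in ys) {
    tot <- tot + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  tot / (length(xs) * length(ys))
}

# Brute-force best Youden J over every possible threshold (>= rule).
brute_best_youden <- function(scores, is_pos) {
  best <- -Inf
  for (t in c(sort(unique(scores)), Inf)) {
    se <- mean(scores[is_pos] >= t)
    sp <- mean(scores[!is_pos] < t)
    best <- max(best, se + sp - 1)
  }
  best
}
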