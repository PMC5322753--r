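# Small clustered cohort used across cascade tests.
cascade_cohort <- function(seed = 1, n_h = 80, n_i = 160) {
  spec <- small_spec(n_h, n_i,
                     deltas = c(A = 0.8, B = 0.3, C = -0.25, D = 0.3),
                     seed = seed,
                     clusters = cluster_spec(n_clusters = 12))
  model_building_subset(generate_cohort(spec))
}

test_that("division sizes are nearly equal with extras to the nearest blocks", {
  expect_equal(ildcascade:::division_sizes(10, 5), rep(2L, 5))
  expect_equal(ildcascade:::division_sizes(532, 5),
               c(107L, 107L, 106L, 106L, 106L))
  for (m in c(5, 10, 15, 20)) {
    s <- ildcascade:::division_sizes(532, m)
    expect_equal(sum(s), 532)
    expect_lte(max(s) - min(s), 1)
    expect_true(all(diff(s) <= 0))  # extras go to the nearest divisions
  }
  expect_error(ildcascade:::division_sizes(3, 5), "cannot divide")
})

test_that("assign_divisions sorts by distance and partitions the neighbors", {
  set.seed(2)
  d <- setNames(runif(23), paste0("q", 1:23))
  div <- assign_divisions(d, 5)
  expect_equal(lengths(div), c(5L, 5L, 5L, 4L, 4L))
  expect_setequal(unlist(div), names(d))
  # sort contract: max of block k <= min of block k+1
  for (k in 1:4) expect_lte(max(d[div[[k]]]), min(d[div[[k + 1]]]))
})

test_that("derivative features follow their definitions", {
  ref_out <- setNames(c(0.2, 0.4, 0.6, 0.8, 1.0, 0.1, 0.3, 0.5, 0.7, 0.9),
                      paste0("r", 1:10))
  ref_ild <- setNames(rep(c(TRUE, FALSE), 5), names(ref_out))
  d <- setNames(seq(0.1, 1, by = 0.1), names(ref_out))
  # division 1 of m=2 holds r1..r5 whose outputs are 0.2,0.4,0.6,0.8,1.0
  f <- derivative_features(0.77, d, ref_out, ref_ild, m = 2, d = 1)
  expect_equal(unname(f["f1"]), 0.77)
  expect_equal(unname(f["f2"]), 0.6)
  expect_equal(unname(f["f3"]), mean(d[1:5]))
  expect_equal(unname(f["f4"]), 3 / 5)
  # an all-ILD division gives f4 = 1
  all_ild <- setNames(rep(TRUE, 10), names(ref_out))
  expect_equal(unname(derivative_features(0.5, d, ref_out, all_ild, 2, 2)["f4"]),
               1)
  # f3 is non-decreasing in d for fixed m
  f3s <- sapply(1:5, function(dd) {
    derivative_features(0.5, d, ref_out, ref_ild, 5, dd)["f3"]
  })
  expect_true(all(diff(f3s) >= 0))
  expect_error(derivative_features(0.5, d, ref_out, ref_ild, 2, 3), "1..m")
})

test_that("f4 equals brute-force label counting on the division members", {
  coh <- cascade_cohort(seed = 3, n_h = 30, n_i = 50)
  fit <- train_cascade(coh, c("A", "B", "C", "D"), m_values = 5, seed = 4)
  m <- fit$model
  dmat <- as.matrix(dist(m$reference$x))
  dimnames(dmat) <- list(m$reference$ids, m$reference$ids)
  feats <- ildcascade:::reference_features(dmat, m$reference$f1,
                                           m$reference$ild, 5, 2)
  for (i in c(1, 17, 80)) {
    di <- dmat[i, -i]
    div <- assign_divisions(di, 5)[[2]]
    ild_named <- setNames(m$reference$ild, m$reference$ids)
    expect_equal(unname(feats[i, "f4"]),
                 sum(ild_named[div]) / length(div))
  }
})

test_that("train_cascade evaluates the full candidate grid and selects max J", {
  coh <- cascade_cohort(seed = 5)
  fit <- train_cascade(coh, c("A", "B", "C", "D"), seed = 6)
  expect_equal(nrow(fit$report), 50)  # 5 + 10 + 15 + 20
  expect_equal(fit$report$model,
               unlist(lapply(c(5, 10, 15, 20),
                             function(m) sprintf("%dD%d", m, 1:m))))
  sel <- attr(fit$report, "selected")
  expect_equal(fit$report$youden_j[fit$report$model == sel],
               max(fit$report$youden_j, na.rm = TRUE))
  expect_equal(sprintf("%dD%d", fit$model$m, fit$model$d), sel)
  expect_true(fit$model$cutoff >= 0 && fit$model$cutoff <= 1)
})

test_that("candidate reports are bit-identical under a fixed seed", {
  coh <- cascade_cohort(seed = 7, n_h = 40, n_i = 80)
  f1 <- train_cascade(coh, c("A", "B", "C", "D"), m_values = c(5, 10), seed = 8)
  f2 <- train_cascade(coh, c("A", "B", "C", "D"), m_values = c(5, 10), seed = 8)
  expect_identical(f1$report$youden_j, f2$report$youden_j)
  expect_identical(f1$model$cutoff, f2$model$cutoff)
  expect_identical(f1$model$ann2$weights, f2$model$ann2$weights)
})

test_that("predict_cascade reproduces reference scores and bounds outputs", {
  coh <- cascade_cohort(seed = 9, n_h = 40, n_i = 80)
  fit <- train_cascade(coh, c("A", "B", "C", "D"), m_values = 5, seed = 10)
  sc <- predict_cascade(fit$model, coh)
  expect_true(all(sc$score >= 0 & sc$score <= 1))

  # training-time scores of the selected candidate, recomputed leave-self-out
  m <- fit$model
  dmat <- as.matrix(dist(m$reference$x))
  dimnames(dmat) <- list(m$reference$ids, m$reference$ids)
  feats <- ildcascade:::reference_features(dmat, m$reference$f1,
                                           m$reference$ild, m$m, m$d)
  train_scores <- predict(m$ann2, feats)
  expect_equal(sc$score, unname(train_scores), tolerance = 1e-8)
  expect_equal(sc$call, sc$score >= m$cutoff)
})

test_that("external patients are scored against the full reference cohort", {
  coh <- cascade_cohort(seed = 11, n_h = 40, n_i = 80)
  fit <- train_cascade(coh, c("A", "B", "C", "D"), m_values = 5, seed = 12)
  ext <- coh
  ext$data <- ext$data[3, , drop = FALSE]
  ext$data$patient_id <- "EXTERNAL1"   # same coordinates, new identity
  s_ext <- predict_cascade(fit$model, ext)$score
  # manual: all reference patients are candidates (no self-exclusion)
  m <- fit$model
  xq <- cei_matrix(apply_normalization(m$norm, ext), m$inputs)
  f1q <- predict(m$ann1, xq)
  d <- sqrt(ildcascade:::cross_dist2(xq, m$reference$x))[1, ]
  names(d) <- m$reference$ids
  fe <- derivative_features(f1q, d,
                            setNames(m$reference$f1, m$reference$ids),
                            setNames(m$reference$ild, m$reference$ids),
                            m$m, m$d)
  expect_equal(s_ext, unname(predict(m$ann2, matrix(fe, 1))))

  # a missing input CEI fails per patient, others proceed
  holey <- coh
  holey$data$A[2] <- NA
  expect_warning(sch <- predict_cascade(fit$model, holey), "missing input")
  expect_true(is.na(sch$score[2]))
  expect_false(anyNA(sch$score[-2]))
})

test_that("with m = 1 the cascade collapses toward the first-stage model", {
  diffs <- sapply(1:10, function(s) {
    coh <- cascade_cohort(seed = 400 + s, n_h = 60, n_i = 120)
    fit <- train_cascade(coh, c("A", "B", "C", "D"), m_values = 1, seed = s)
    m <- fit$model
    x <- cei_matrix(apply_normalization(m$norm, coh), m$inputs)
    y <- coh$data$lung_status == "ILD"
    j1 <- optimal_cutoff(roc_curve(predict(m$ann1, x), y, "positive"))$youden
    abs(fit$report$youden_j[1] - j1)
  })
  expect_lte(median(diffs), 0.1)
})

test_that("division-1 information lifts the cascade above distant divisions", {
  res <- sapply(1:20, function(s) {
    spec <- small_spec(80, 160,
                       deltas = c(A = 0.8, B = 0.3, C = -0.25, D = 0.3),
                       seed = 500 + s,
                       clusters = cluster_spec(n_clusters = 12))
    coh <- model_building_subset(generate_cohort(spec))
    fit <- train_cascade(coh, c("A", "B", "C", "D"), m_values = c(10, 20),
                         seed = s)
    rep <- fit$report
    c(d1 = max(rep$youden_j[rep$d == 1]),
      dm = max(rep$youden_j[rep$d == rep$m]))
  })
  expect_gt(median(res["d1", ]), median(res["dm", ]))
})
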