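test_that("generated cohorts honor the requested composition", {
  spec <- default_study_spec(seed = 3)
  coh <- generate_cohort(spec)
  tab <- table(coh$data$lung_status)
  expect_equal(as.integer(tab[c("HEALTHY", "ILD", "PF")]), c(169L, 364L, 87L))
  expect_equal(n_patients(coh), 620)
  # registry split 2 basic / 22 blood / 8 urine
  expect_equal(as.integer(table(coh$registry$class)[c("basic", "blood", "urine")]),
               c(2L, 22L, 8L))
  expect_true(all(study_informative_ceis() %in% cei_names(coh)))
})

test_that("identical specs give identical cohorts; the RNG stream is scoped", {
  spec <- small_spec(20, 30, deltas = c(A = 1, B = 0), seed = 11)
  set.seed(1); before <- runif(1)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$data, c2$data)
  set.seed(1)
  generate_cohort(spec)
  expect_identical(runif(1), before)  # generator does not disturb the session RNG
})

test_that("planted shifts recover the binormal AUC calibration", {
  # delta = 0.783 corresponds to AUC 0.71 under AUC = Phi(delta / sqrt(2))
  expect_equal(binormal_auc(auc_to_delta(0.71)), 0.71)
  aucs <- sapply(1:40, function(s) {
    coh <- generate_cohort(small_spec(169, 364,
                                      deltas = c(X = 0.783, N = 0),
                                      seed = 2000 + s))
    y <- coh$data$lung_status == "ILD"
    roc_curve(coh$data$X, y, "auto")$auc
  })
  expect_lt(abs(mean(aucs) - 0.71), 0.03)
})

test_that("negative shifts are emulated and recovered in the inverse direction", {
  coh <- generate_cohort(small_spec(169, 364, deltas = c(DOWN = -0.8),
                                    seed = 5))
  y <- coh$data$lung_status == "ILD"
  cv <- roc_curve(coh$data$DOWN, y, "auto")
  expect_equal(cv$direction, "inverse")
  expect_gt(cv$auc, 0.6)
  # group means move the stated way
  expect_lt(mean(coh$data$DOWN[y]), mean(coh$data$DOWN[!y]))
})

test_that("group-conditional means recover the spec within 3 standard errors", {
  spec <- small_spec(169, 364, deltas = c(A = 0.8, B = 0), seed = 7)
  coh <- generate_cohort(spec)
  y <- coh$data$lung_status == "ILD"
  se_h <- 2 / sqrt(169); se_i <- 2 / sqrt(364)  # sd = 2 in small_spec
  expect_lt(abs(mean(coh$data$A[!y]) - 10), 3 * se_h)
  expect_lt(abs(mean(coh$data$A[y]) - (10 + 0.8 * 2)), 3 * se_i)
  expect_lt(abs(mean(coh$data$B[y]) - 10), 3 * se_i)
})

test_that("null cohorts produce chance-level AUCs downstream", {
  aucs <- sapply(1:20, function(s) {
    coh <- generate_cohort(small_spec(100, 150, deltas = c(A = 0, B = 0),
                                      seed = 3000 + s))
    y <- coh$data$lung_status == "ILD"
    roc_curve(coh$data$A, y, "positive")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("PF patients sit beyond ILD on informative indicators", {
  spec <- small_spec(100, 200, n_pf = 87, deltas = c(A = 1, B = 0),
                     seed = 9, pf_extra_shift = 1.3)
  coh <- generate_cohort(spec)
  st <- coh$data$lung_status
  expect_gt(mean(coh$data$A[st == "PF"]), mean(coh$data$A[st == "ILD"]))
})

test_that("missingness is applied at the requested rate and is MCAR-ish", {
  spec <- small_spec(200, 300, deltas = c(A = 0.5, B = 0),
                     missing_rate = 0.1, seed = 13)
  coh <- generate_cohort(spec)
  miss <- mean(is.na(cei_matrix(coh)))
  expect_lt(abs(miss - 0.1), 0.02)
  # invalid specs are rejected
  expect_error(small_spec(-1, 10), "counts must be")
  expect_error(generator_spec(10, 10, 0,
                              data.frame(name = "A", class = "blood",
                                         delta = 0, mean = 1, sd = 0),
                              missing_rate = 0), "sd must be positive")
})

test_that("enrichment increases the division-1 advantage over the first stage", {
  adv <- function(e, s) {
    spec <- default_study_spec(seed = s, clustered = TRUE,
                               clusters = cluster_spec(enrichment = e))
    coh <- model_building_subset(generate_cohort(spec))
    fit <- train_cascade(coh, study_informative_ceis(),
                         m_values = c(10, 20), seed = 1000 + s)
    rep <- fit$report
    x <- cei_matrix(apply_normalization(fit$model$norm, coh),
                    fit$model$inputs)
    j1 <- optimal_cutoff(roc_curve(predict(fit$model$ann1, x),
                                   coh$data$lung_status == "ILD",
                                   "positive"))$youden
    max(rep$youden_j[rep$d == 1]) - j1
  }
  meds <- sapply(c(0, 0.6, 1.2), function(e) {
    median(sapply(1:10, function(s) adv(e, s)))
  })
  expect_true(all(diff(meds) >= 0))
})

test_that("cluster enrichment creates neighborhood-label correlation", {
  # with enrichment, a patient's nearest neighbors share its label more
  # often than the cohort mixing rate predicts
  frac_same <- function(enr, s) {
    spec <- small_spec(100, 140, deltas = c(A = 0.5, B = 0.5, C = 0.5, D = 0.5),
                       seed = s,
                       clusters = cluster_spec(n_clusters = 12,
                                               enrichment = enr))
    coh <- model_building_subset(generate_cohort(spec))
    attr(coh, "normalized_ceis") <- cei_names(coh)
    dm <- pairwise_distances(coh, c("A", "B", "C", "D"))
    y <- coh$data$lung_status == "ILD"
    mean(sapply(seq_len(nrow(dm)), function(i) {
      nn <- order(dm[i, -i])[1:10]
      mean(y[-i][nn] == y[i])
    }))
  }
  expect_gt(mean(sapply(1:3, function(s) frac_same(1.2, s))),
            mean(sapply(1:3, function(s) frac_same(0, s))))
})
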