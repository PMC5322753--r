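test_that("AUC equals brute-force concordant-pair counting (ties as 1/2)", {
  # worked example: positives {0.9, 0.8}, negatives {0.7, 0.85}
  sc <- c(0.9, 0.8, 0.7, 0.85)
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_curve(sc, y, "positive")$auc, 0.75)

  set.seed(42)
  for (rep in 1:25) {
    n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
    # coarse grid forces ties
    sc <- sample(seq(0, 1, by = 0.1), n1 + n0, replace = TRUE)
    y <- c(rep(TRUE, n1), rep(FALSE, n0))
    expect_equal(roc_curve(sc, y, "positive")$auc, brute_auc(sc, y))
  }
})

test_that("reversing the direction flag maps AUC to 1 - AUC", {
  set.seed(7)
  sc <- rnorm(60)
  y <- rep(c(TRUE, FALSE), 30)
  a_pos <- roc_curve(sc, y, "positive")$auc
  a_inv <- roc_curve(sc, y, "inverse")$auc
  expect_equal(a_inv, 1 - a_pos)
  # auto picks the >= 0.5 side
  expect_gte(roc_curve(sc, y, "auto")$auc, 0.5)
})

test_that("roc_curve covers endpoints and degenerate inputs", {
  # perfectly separable: some point attains sens = spec = 1
  cv <- roc_curve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T), "positive")
  expect_true(any(cv$points$sensitivity == 1 & cv$points$specificity == 1))
  expect_true(any(cv$points$sensitivity == 1 & cv$points$specificity == 0))
  expect_true(any(cv$points$sensitivity == 0 & cv$points$specificity == 1))
  # all scores equal: only the two trivial endpoints
  flat <- roc_curve(rep(1, 6), c(T, T, T, F, F, F), "positive")
  expect_equal(nrow(flat$points), 2)
  expect_equal(flat$auc, 0.5)
  # single-class labels fail
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "positive and one negative")
})

test_that("youden and dor reproduce their closed forms and guard bounds", {
  expect_equal(youden(1, 1), 1)
  expect_equal(youden(0.5, 0.5), 0)
  expect_error(youden(1.2, 0.5), "\\[0, 1\\]")

  expect_equal(dor(0.5, 0.5), 1)
  expect_error(dor(1, 0.5), class = "ildcascade_infinite_dor")
  # algebraic identity DOR = (SE/(1-SE)) / ((1-SP)/SP)
  set.seed(3)
  se <- runif(20, 0.05, 0.95); sp <- runif(20, 0.05, 0.95)
  expect_equal(dor(se, sp), (se / (1 - se)) / ((1 - sp) / sp))
})

test_that("tpr is the true-positive percentage", {
  expect_equal(tpr(10, 0), 100)
  expect_equal(tpr(0, 10), 0)
  expect_equal(round(tpr(72, 15), 1), 82.8)
  expect_error(tpr(0, 0), "no positive cases")
})

test_that("optimal_cutoff matches exhaustive threshold search", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    sc <- sample(seq(0, 1, by = 0.125), n, replace = TRUE)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    cv <- roc_curve(sc, y, "positive")
    expect_equal(optimal_cutoff(cv)$youden, brute_best_youden(sc, y))
  }
  # separable: J = 1
  cv <- roc_curve(c(1, 2, 8, 9), c(F, F, T, T), "positive")
  expect_equal(optimal_cutoff(cv)$youden, 1)
  # degenerate: all equal scores give J = 0 at an endpoint
  flat <- roc_curve(rep(2, 6), c(T, T, T, F, F, F), "positive")
  oc <- optimal_cutoff(flat)
  expect_equal(oc$youden, 0)
  expect_equal(oc$specificity, 1)  # tie broken toward higher specificity
})

test_that("sens_at_spec uses the step-function convention", {
  # perfect classifier
  cv <- roc_curve(c(1, 2, 8, 9), c(F, F, T, T), "positive")
  expect_equal(sens_at_spec(cv, 0.8), 1)
  # uninformative curve: sens 0 once spec >= 0.8
  flat <- roc_curve(rep(1, 8), c(T, T, T, T, F, F, F, F), "positive")
  expect_equal(sens_at_spec(flat, 0.8), 0)
  # enumeration oracle on a hand-built 10-point score set
  sc <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.45, 0.35, 0.6, 0.7, 0.15)
  y <- c(F, F, F, T, T, F, T, T, T, F)
  cv <- roc_curve(sc, y, "positive")
  best <- -Inf
  for (t in c(sort(unique(sc)), Inf)) {
    sp <- mean(sc[!y] < t)
    if (sp >= 0.8) best <- max(best, mean(sc[y] >= t))
  }
  expect_equal(sens_at_spec(cv, 0.8), best)
})

test_that("single-AUC inference agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (rep in 1:5) {
    n <- 80
    y <- rep(c(TRUE, FALSE), n / 2)
    sc <- rnorm(n) + 0.8 * y
    ours <- auc_test_vs_half(sc, y, direction = "positive")
    ref <- pROC::roc(response = y, predictor = sc, direction = "<",
                     quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
    expect_equal(ours$se^2, as.numeric(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
  }
  # constant scores carry no information
  flat <- auc_test_vs_half(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$p_value, 1)
  expect_false(flat$associated)
  # strongly separated classes are associated
  y <- rep(c(TRUE, FALSE), 100)
  expect_true(auc_test_vs_half(rnorm(200) + 3 * y, y, "positive")$associated)
})

test_that("paired DeLong test agrees with pROC and handles identities", {
  set.seed(31)
  y <- rep(c(TRUE, FALSE), 40)
  base <- rnorm(80) + 1 * y
  sa <- base + rnorm(80, sd = 0.6)
  sb <- base + rnorm(80, sd = 0.6)
  ours <- delong_compare(sa, sb, y)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(y, sa, direction = "<", quiet = TRUE)
  rb <- pROC::roc(y, sb, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, as.numeric(ref$p.value), tolerance = 1e-10)
  # identical scores: z = 0, p = 1
  same <- delong_compare(sa, sa, y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

test_that("DeLong variance of an AUC difference matches a bootstrap estimate", {
  set.seed(5)
  n <- 40
  y <- rep(c(TRUE, FALSE), n / 2)
  base <- rnorm(n) + 1.2 * y
  sa <- base + rnorm(n, sd = 0.5)
  sb <- base + rnorm(n, sd = 0.5)
  v_delong <- delong_compare(sa, sb, y)$var_diff
  boots <- replicate(10000, {
    i <- c(sample(which(y), sum(y), TRUE), sample(which(!y), sum(!y), TRUE))
    ri <- rank(sa[i]); pos <- y[i]
    a1 <- (sum(ri[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
    ri <- rank(sb[i])
    a2 <- (sum(ri[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
    a1 - a2
  })
  expect_equal(v_delong, var(boots), tolerance = 0.15)
})
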