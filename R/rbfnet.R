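# Radial basis function network: k-means centers, nearest-center widths,
# ridge-regularized linear output layer, 0-1 output rescaling, and the
# 2:1:1 holdout protocol with width selection on the verification set.

# Squared Euclidean cross-distances between rows of a and b.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  pmax(d2, 0)
}

rbf_design <- function(x, centers, sigma) {
  phi <- exp(-cross_dist2(x, centers) / (2 * rep(sigma^2, each = nrow(x))))
  cbind(1, phi)
}

#' Train an RBF network
#'
#' Architecture: Gaussian hidden layer of `k_centers` units (12 by default,
#' the "4-12-1" contract with four inputs) and a linear output unit.
#' Centers are placed by seeded k-means on the inputs; each unit's width is
#' its distance to the nearest other center times `width_mult`; the output
#' layer is solved by ridge-regularized least squares. Raw training outputs
#' define the (min, max) bounds used to rescale predictions to \[0, 1\].
#'
#' @param x numeric matrix of inputs (rows = patients), expected on the
#'   0-1 normalized scale.
#' @param y numeric/logical binary targets (1 = positive class).
#' @param k_centers number of hidden units.
#' @param ridge ridge penalty on the hidden-to-output weights (the bias is
#'   not penalized).
#' @param width_mult global multiplier on the nearest-center widths.
#' @param seed integer seed: k-means placement is fully reproducible.
#' @return object of class `rbf_model`.
#' @export
train_rbf <- function(x, y, k_centers = 12, ridge = 1e-6, width_mult = 1,
                      seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (k_centers < 1) stop("k_centers must be >= 1")
  if (k_centers > n) stop("k_centers (", k_centers, ") exceeds sample size (", n, ")")
  if (ridge < 0) stop("ridge must be non-negative")

  centers <- local_seed(seed, {
    if (k_centers == n) {
      x
    } else {
      km <- tryCatch(
        stats::kmeans(x, centers = k_centers, nstart = 5, iter.max = 100),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(km)) {
        km <- tryCatch(
          stats::kmeans(x, centers = k_centers, nstart = 10, iter.max = 200),
          error = function(e) NULL, warning = function(w) NULL)
      }
      if (is.null(km)) stop("k-means center placement failed (degenerate inputs)")
      km$centers
    }
  })
  centers <- unname(as.matrix(centers))

  if (k_centers == 1) {
    sigma <- sqrt(mean(cross_dist2(x, centers)))
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  } else {
    dc <- as.matrix(stats::dist(centers))
    diag(dc) <- Inf
    sigma <- apply(dc, 1, min)
    bad <- !is.finite(sigma) | sigma <= 0
    if (all(bad)) sigma[] <- 1 else sigma[bad] <- min(sigma[!bad])
  }
  sigma <- sigma * width_mult

  a <- rbf_design(x, centers, sigma)
  pen <- diag(ncol(a)) * ridge
  pen[1, 1] <- 0
  w <- solve(crossprod(a) + pen, crossprod(a, y))
  raw <- drop(a %*% w)

  structure(list(centers = centers, sigma = sigma, weights = drop(w),
                 output_bounds = range(raw), dim = ncol(x),
                 k_centers = k_centers, ridge = ridge,
                 width_mult = width_mult, seed = seed),
            class = "rbf_model")
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("rbf_model: %d-%d-1 (Gaussian RBF, width_mult %.3g, ridge %.3g)\n",
              x$dim, x$k_centers, x$width_mult, x$ridge))
  invisible(x)
}

#' Predict with a trained RBF network
#'
#' Raw network output is min-max rescaled by the bounds recorded on the
#' training outputs and clipped to \[0, 1\].
#'
#' @param object an `rbf_model`.
#' @param newdata numeric matrix with the training dimensionality.
#' @param rescale set `FALSE` for the raw linear output.
#' @param ... unused.
#' @return numeric scores in \[0, 1\] (or raw outputs).
#' @export
predict.rbf_model <- function(object, newdata, rescale = TRUE, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dim) {
    stop("input has ", ncol(newdata), " columns; model expects ", object$dim)
  }
  raw <- drop(rbf_design(newdata, object$centers, object$sigma) %*% object$weights)
  if (!rescale) return(raw)
  b <- object$output_bounds
  if (b[2] <= b[1]) return(rep(0.5, length(raw)))
  pmin(1, pmax(0, (raw - b[1]) / (b[2] - b[1])))
}

# Largest-remainder apportionment of n into parts proportional to ratio.
# Ties in the fractional part go to the earlier part (training first).
split_sizes <- function(n, ratio = c(2, 1, 1)) {
  target <- n * ratio / sum(ratio)
  base <- floor(target)
  extra <- n - sum(base)
  if (extra > 0) {
    ord <- order(-(target - base), seq_along(ratio))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Train an RBF network under the 2:1:1 holdout protocol
#'
#' Patients are randomly partitioned into training, verification and
#' testing subsets in a 2:1:1 ratio (largest-remainder rounding). The
#' network is fit on the training set for each width multiplier in
#' `width_grid`; the multiplier with the best verification-set Youden J is
#' kept (ties to the smaller multiplier). The report carries the Pearson
#' correlations between model output and binary status on the training
#' (`r_tr`) and testing (`r_te`) sets; similar values indicate good
#' generalization.
#'
#' @inheritParams train_rbf
#' @param width_grid candidate width multipliers.
#' @param max_retries partitions yielding a single-class subset are redrawn
#'   with an incremented seed at most this many times.
#' @param generalization_tol `|r_tr - r_te|` below this flags good
#'   generalization.
#' @return list with elements `model` (the `rbf_model`) and `report`
#'   (subset index sets, `r_tr`, `r_te`, chosen `width_mult`,
#'   `good_generalization`, `seed_used`).
#' @export
holdout_fit <- function(x, y, k_centers = 12, ridge = 1e-6,
                        width_grid = c(0.5, 1, 2, 4), seed = 1,
                        max_retries = 20, generalization_tol = 0.1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 8) stop("holdout_fit needs at least 8 patients for a 2:1:1 split")
  sizes <- split_sizes(n)

  split <- NULL
  seed_used <- seed
  for (attempt in 0:max_retries) {
    seed_used <- seed + attempt
    perm <- local_seed(seed_used, sample.int(n))
    idx <- list(train = perm[seq_len(sizes[1])],
                ver = perm[sizes[1] + seq_len(sizes[2])],
                test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
    two_class <- vapply(idx, function(i) length(unique(y[i])) == 2, TRUE)
    if (all(two_class)) { split <- idx; break }
  }
  if (is.null(split)) {
    stop("holdout_fit: could not draw a split with both classes in every subset")
  }

  best <- NULL
  for (wm in sort(width_grid)) {
    fit <- train_rbf(x[split$train, , drop = FALSE], y[split$train],
                     k_centers = k_centers, ridge = ridge,
                     width_mult = wm, seed = seed_used)
    sv <- predict(fit, x[split$ver, , drop = FALSE])
    j <- optimal_cutoff(roc_curve(sv, y[split$ver] == 1, "positive"))$youden
    if (is.null(best) || j > best$j) best <- list(model = fit, j = j, wm = wm)
  }

  pr_tr <- predict(best$model, x[split$train, , drop = FALSE])
  pr_te <- predict(best$model, x[split$test, , drop = FALSE])
  r_tr <- suppressWarnings(stats::cor(pr_tr, y[split$train]))
  r_te <- suppressWarnings(stats::cor(pr_te, y[split$test]))
  report <- list(train_idx = split$train, ver_idx = split$ver,
                 test_idx = split$test, r_tr = r_tr, r_te = r_te,
                 width_mult = best$wm, verification_youden = best$j,
                 good_generalization = is.finite(r_tr) && is.finite(r_te) &&
                   abs(r_tr - r_te) < generalization_tol,
                 seed_used = seed_used)
  list(model = best$model, report = report)
}
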