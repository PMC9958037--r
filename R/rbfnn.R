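#' Hidden-unit centers by Lloyd's k-means
#'
#' Places the RBF hidden-unit centers among the training points by k-means
#' clustering: Lloyd's iterations started from a seeded random sample of
#' `k` distinct training points, run until the assignments are stable or
#' 100 iterations. A cluster that empties is re-seeded to the point
#' currently farthest from its assigned center.
#'
#' @param X Numeric matrix (or data frame) of training inputs, one row per
#'   point.
#' @param k Number of centers; must not exceed the number of distinct rows.
#' @param seed Optional integer seed for the initialization.
#' @return A `k x p` matrix of centers.
#' @export
kmeans_centers <- function(X, k, seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("inputs must be finite", call. = FALSE)
  k <- as.integer(k)
  distinct <- unique(X)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > nrow(distinct)) {
    stop("k exceeds the number of distinct input points", call. = FALSE)
  }
  pick <- if (is.null(seed)) sample.int(nrow(distinct), k) else
    withr::with_seed(seed, sample.int(nrow(distinct), k))
  centers <- distinct[pick, , drop = FALSE]

  assign_prev <- rep(0L, nrow(X))
  for (iter in seq_len(100L)) {
    d2 <- sq_dist(X, centers)
    assign_cur <- max.col(-d2, ties.method = "first")
    point_d2 <- d2[cbind(seq_len(nrow(X)), assign_cur)]
    for (j in seq_len(k)) {
      if (!any(assign_cur == j)) {        # empty cluster: re-seed to the
        far <- which.max(point_d2)        # point farthest from its center
        assign_cur[far] <- j
        point_d2[far] <- 0
      }
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[assign_cur == j, , drop = FALSE])
    }
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
  }
  centers
}

sq_dist <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * tcrossprod(X, C)
  pmax(d2, 0)
}

#' Shared Gaussian width from the input dispersion
#'
#' The shared RBF width is the standard deviation of the input vectors
#' around their global mean, as a single scalar over all components:
#' `sigma = sqrt(mean(||x_i - xbar||^2) / p)` with `p` the input dimension.
#' On standardized features this is close to 1 by construction.
#'
#' @param X Numeric matrix (or data frame) of inputs, one row per vector.
#' @return A positive scalar width.
#' @export
rbf_sigma <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 input vectors", call. = FALSE)
  xbar <- colMeans(X)
  s2 <- mean(rowSums((X - rep(xbar, each = nrow(X)))^2)) / ncol(X)
  if (s2 == 0) stop("all input vectors identical: sigma would be 0", call. = FALSE)
  sqrt(s2)
}

#' Gaussian hidden-unit activations
#'
#' `phi_j(x) = exp(-||x - mu_j||^2 / (2 sigma^2))`, the Gaussian radial
#' basis activation of each hidden unit. Activations lie in `(0, 1]`, with
#' `phi_j = 1` exactly when `x` coincides with the center.
#'
#' @param X Input points, one row per point (a single vector is accepted).
#' @param centers Matrix of hidden-unit centers, one row per unit.
#' @param sigma Positive scalar width shared by all units.
#' @return An `n x k` matrix of activations.
#' @export
rbf_activations <- function(X, centers, sigma) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X); centers <- as.matrix(centers)
  if (!all(is.finite(X))) stop("inputs must be finite", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive finite scalar", call. = FALSE)
  }
  if (ncol(X) != ncol(centers)) stop("input/center dimensions disagree", call. = FALSE)
  exp(-sq_dist(X, centers) / (2 * sigma^2))
}

#' Output weights by the normalized least-mean-squares rule
#'
#' Trains the linear output layer sample-by-sample with the normalized LMS
#' update `w <- w + eta / (eps + ||phi||^2) * (d - w'phi) * phi`, weights
#' initialized to zero and the sample order reshuffled every epoch. The
#' normalization by the activation energy makes the rule stable for
#' `eta` in `(0, 2)`.
#'
#' @param Phi Activation matrix (`n x k`), one row per training sample.
#' @param d Desired outputs, length `n` (1 for reflux limbs, 0 for
#'   controls in the classification task).
#' @param eta Step size in the open interval `(0, 2)`.
#' @param epochs Number of passes over the data.
#' @param seed Optional integer seed for the per-epoch shuffles.
#' @param eps Regularizer in the energy normalization (default `1e-6`).
#' @return A list with `weights` (length `k`) and `mse_trace`, the mean
#'   squared output error after each epoch.
#' @export
nlms_train <- function(Phi, d, eta = 0.5, epochs = 200L, seed = NULL,
                       eps = 1e-6) {
  Phi <- as.matrix(Phi)
  if (length(d) != nrow(Phi)) stop("Phi rows must match length(d)", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta >= 2) {
    stop("eta must lie in the open interval (0, 2)", call. = FALSE)
  }
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be at least 1", call. = FALSE)
  run <- function() {
    w <- rep(0, ncol(Phi))
    mse_trace <- numeric(epochs)
    n <- nrow(Phi)
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        phi <- Phi[i, ]
        err <- d[i] - sum(w * phi)
        w <- w + (eta / (eps + sum(phi * phi))) * err * phi
      }
      mse_trace[e] <- mean((d - drop(Phi %*% w))^2)
    }
    list(weights = w, mse_trace = mse_trace)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' F-measure-optimal decision threshold
#'
#' Sweeps the decision threshold over the grid 0, 0.01, ..., 1.00,
#' predicting positive when the network output strictly exceeds the
#' threshold, and returns the threshold maximizing the F-measure (harmonic
#' mean of precision and recall, as a proportion in `[0, 1]`). Ties are
#' broken toward the smallest threshold. Thresholds at which no positive is
#' predicted score F = 0.
#'
#' @param scores Network outputs.
#' @param labels Binary labels (1 = positive class), both classes present.
#' @return A list with `threshold` and `f_measure`.
#' @export
select_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to select a threshold", call. = FALSE)
  }
  grid <- seq(0, 1, by = 0.01)
  f <- vapply(grid, function(th) f_measure_at(scores, labels, th), numeric(1))
  best <- which.max(f)                      # which.max takes the first maximum
  list(threshold = grid[best], f_measure = f[best])
}

f_measure_at <- function(scores, labels, threshold) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  if (tp == 0L) return(0)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Fit the radial basis function network classifier
#'
#' Composes the full training procedure on a feature table: optional
#' standardization, k-means placement of the hidden-unit centers, shared
#' Gaussian width from the input dispersion, normalized-LMS training of the
#' output weights against desired outputs 1 (reflux limb) / 0 (control
#' limb), and selection of the decision threshold - either a fixed value or
#' an F-measure sweep over `[0, 1]`. The whole fit is deterministic given
#' `seed`.
#'
#' @param features A [build_features()] table (columns: `subject_id`, six
#'   features, `label`).
#' @param k Number of hidden units (default 16).
#' @param eta NLMS step size (default 0.5).
#' @param epochs NLMS epochs (default 1000; the 41-sample kernel system
#'   needs a few thousand stochastic updates to converge).
#' @param seed Integer seed driving center initialization and the NLMS
#'   shuffles.
#' @param sigma Optional width override; default is [rbf_sigma()] of the
#'   (standardized) training inputs.
#' @param threshold Decision threshold: a number in `[0, 1]`, or `"sweep"`
#'   to maximize the training F-measure.
#' @param standardize Standardize features before the RBF layer (default
#'   `TRUE`; the six inputs mix mL, mL/s and unitless ratios).
#' @return An object of class `rbfnn` with components `centers`, `sigma`,
#'   `weights`, `threshold`, `standardizer` (or `NULL`), and a `training`
#'   list (scores, labels, per-epoch MSE trace, training F-measure).
#' @seealso [predict.rbfnn()], [select_threshold()]
#' @export
rbfnn_fit <- function(features, k = 16L, eta = 0.5, epochs = 1000L, seed = 1L,
                      sigma = NULL, threshold = "sweep", standardize = TRUE) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  d <- features$label
  if (!all(d %in% c(0L, 1L)) || length(unique(d)) < 2L) {
    stop("labels must be binary with both classes present", call. = FALSE)
  }
  std <- NULL
  feats <- features
  if (isTRUE(standardize)) {
    std <- fit_standardizer(features)
    feats <- apply_standardizer(features, std)
  }
  X <- feature_matrix(feats)
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  centers <- kmeans_centers(X, k, seed = sub_seeds[1])
  sigma <- sigma %||% rbf_sigma(X)
  Phi <- rbf_activations(X, centers, sigma)
  fit <- nlms_train(Phi, d, eta = eta, epochs = epochs, seed = sub_seeds[2])
  scores <- drop(Phi %*% fit$weights)
  if (identical(threshold, "sweep")) {
    sel <- select_threshold(scores, d)
    thr <- sel$threshold
    f_tr <- sel$f_measure
    policy <- "sweep"
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L,
              threshold >= 0, threshold <= 1)
    thr <- threshold
    f_tr <- f_measure_at(scores, d, thr)
    policy <- "fixed"
  }
  structure(list(
    centers = centers, sigma = sigma, weights = fit$weights,
    threshold = thr, threshold_policy = policy,
    standardizer = std,
    feature_names = colnames(X), k = as.integer(k),
    eta = eta, epochs = as.integer(epochs), seed = as.integer(seed),
    training = list(subject_id = features[["subject_id"]],
                    scores = scores, labels = d,
                    mse_trace = fit$mse_trace, f_measure = f_tr)
  ), class = "rbfnn")
}

#' Network outputs and class predictions
#'
#' The forward pass `y(x) = sum_j w_j phi_j(x)`: a plain linear combination
#' of the Gaussian activations, with no bias term; scores are not clipped
#' to `[0, 1]`. Class predictions are positive (reflux, 1) when the score
#' strictly exceeds the model's decision threshold.
#'
#' @param object An [rbfnn_fit()] model.
#' @param newdata A feature table containing the model's feature columns
#'   (on the original scale; the stored standardizer is applied), or a
#'   numeric matrix already on the model's input scale.
#' @param type `"score"` for raw network outputs, `"class"` for thresholded
#'   0/1 predictions.
#' @param ... Unused.
#' @return A numeric (or integer) vector, one value per row of `newdata`.
#' @export
predict.rbfnn <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    if (!is.null(object$standardizer)) {
      newdata <- apply_standardizer(newdata, object$standardizer)
    }
    X <- feature_matrix(newdata, object$feature_names)
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != ncol(object$centers)) {
      stop("newdata dimension does not match the model inputs", call. = FALSE)
    }
  }
  scores <- drop(rbf_activations(X, object$centers, object$sigma) %*% object$weights)
  if (type == "score") scores else as.integer(scores > object$threshold)
}

#' @export
print.rbfnn <- function(x, ...) {
  cat(sprintf(
    "<rbfnn> %d hidden units, sigma %.4f, threshold %.2f (%s)\n  trained on %d samples; training F-measure %.3f\n",
    x$k, x$sigma, x$threshold, x$threshold_policy,
    length(x$training$labels), x$training$f_measure))
  invisible(x)
}

#' Tidy the hidden units of a fitted RBF network
#'
#' @param x An `rbfnn` model.
#' @param ... Unused.
#' @return A tibble with one row per hidden unit: `unit`, its output
#'   `weight`, and the center coordinates (`center_*` columns).
#' @export
tidy.rbfnn <- function(x, ...) {
  ctr <- as_tibble(as.data.frame(x$centers))
  names(ctr) <- paste0("center_", x$feature_names)
  dplyr::bind_cols(tibble(unit = seq_len(x$k), weight = x$weights), ctr)
}

#' One-row summary of a fitted RBF network
#'
#' @param x An `rbfnn` model.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `sigma`, `threshold`, `eta`, `epochs`,
#'   `n_train`, `final_mse`, `training_f_measure`.
#' @export
glance.rbfnn <- function(x, ...) {
  tibble(k = x$k, sigma = x$sigma, threshold = x$threshold,
         eta = x$eta, epochs = x$epochs,
         n_train = length(x$training$labels),
         final_mse = x$training$mse_trace[length(x$training$mse_trace)],
         training_f_measure = x$training$f_measure)
}
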