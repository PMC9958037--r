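test_that("k-means degenerate cases hit their fixed points", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3)
  expect_equal(kmeans_centers(X, 1, seed = 1),
               matrix(colMeans(X), 1), ignore_attr = TRUE)
  P <- matrix(c(0, 0, 5, 5, -5, 5), 3, 2, byrow = TRUE)
  C <- kmeans_centers(P, 3, seed = 2)
  expect_equal(C[order(C[, 1]), ], P[order(P[, 1]), ], ignore_attr = TRUE)
  expect_error(kmeans_centers(P, 4, seed = 1), "distinct")
})

test_that("k-means recovers well-separated blob means, matching the
           reference implementation", {
  set.seed(22)
  X <- rbind(matrix(rnorm(120, 0, 0.2), 60, 2),
             matrix(rnorm(120, 5, 0.2), 60, 2))
  C <- kmeans_centers(X, 2, seed = 3)
  C <- C[order(C[, 1]), ]
  se3 <- 3 * 0.2 / sqrt(60)
  expect_true(all(abs(C[1, ] - colMeans(X[1:60, ])) < se3 + 1e-8))
  expect_true(all(abs(C[2, ] - colMeans(X[61:120, ])) < se3 + 1e-8))
  ref <- stats::kmeans(X, centers = 2, algorithm = "Lloyd", nstart = 5)
  refC <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(C, refC, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the shared width equals the input-vector standard deviation", {
  expect_equal(rbf_sigma(matrix(c(-1, 1), 2, 1)), 1)
  set.seed(23)
  X <- matrix(rnorm(35 * 4, 2, 3), 35, 4)
  xbar <- colMeans(X)
  direct <- sqrt(mean(apply(X, 1, function(x) sum((x - xbar)^2))) / 4)
  expect_equal(rbf_sigma(X), direct)
  expect_error(rbf_sigma(matrix(1, 5, 2)), "identical")
})

test_that("Gaussian activations match their closed form", {
  ctr <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  phi <- rbf_activations(c(0, 0), ctr, sigma = 1)
  expect_equal(phi[1, 1], 1)                      # at the center
  expect_equal(phi[1, 2], exp(-25 / 2))
  # distance sigma * sqrt(2) gives exactly exp(-1)
  s <- 0.7
  phi2 <- rbf_activations(c(s * sqrt(2), 0), matrix(c(0, 0), 1), sigma = s)
  expect_equal(phi2[1, 1], exp(-1))
  # random inputs against a direct double-loop evaluation
  set.seed(24)
  X <- matrix(rnorm(30), 10, 3)
  C <- matrix(rnorm(15), 5, 3)
  phi3 <- rbf_activations(X, C, sigma = 1.3)
  for (i in 1:10) for (j in 1:5) {
    expect_equal(phi3[i, j], exp(-sum((X[i, ] - C[j, ])^2) / (2 * 1.3^2)))
  }
  expect_true(all(phi3 > 0 & phi3 <= 1))
})

test_that("activations decrease strictly with distance from the center", {
  d <- seq(0, 5, by = 0.25)
  phi <- rbf_activations(matrix(d), matrix(0), sigma = 0.9)[, 1]
  expect_true(all(diff(phi) < 0))
})

test_that("NLMS one-step algebra and the null target are exact", {
  fit0 <- nlms_train(matrix(1, 4, 2), d = rep(0, 4), eta = 0.7, epochs = 5,
                     seed = 1)
  expect_identical(fit0$weights, c(0, 0))
  fit1 <- nlms_train(matrix(1, 1, 1), d = 1, eta = 1, epochs = 1)
  expect_equal(fit1$weights, 1 / (1 + 1e-6))
})

test_that("NLMS converges to the least-squares optimum on a 41x16 system", {
  set.seed(26)
  Phi <- matrix(runif(41 * 16), 41, 16)
  d <- rbinom(41, 1, 26 / 41)
  w_ls <- qr.solve(crossprod(Phi), crossprod(Phi, d))
  mse_ls <- mean((d - Phi %*% w_ls)^2)
  fit <- nlms_train(Phi, d, eta = 0.05, epochs = 2000, seed = 4)
  mse_nlms <- mean((d - Phi %*% fit$weights)^2)
  expect_lt(mse_nlms, 1.05 * mse_ls)
  expect_lt(fit$mse_trace[2000], fit$mse_trace[1])
})

test_that("the normalized update never amplifies the per-sample error", {
  set.seed(27)
  for (eta in c(0.1, 0.9, 1.9)) {
    for (i in 1:10) {
      phi <- rnorm(6)
      d <- rnorm(1)
      fit <- nlms_train(matrix(phi, 1), d, eta = eta, epochs = 1)
      a_priori <- abs(d)                      # zero-initialized weights
      a_post <- abs(d - sum(fit$weights * phi))
      expect_lte(a_post, a_priori + 1e-12)
    }
  }
  expect_error(nlms_train(matrix(1, 2, 1), c(1, 0), eta = 2), "\\(0, 2\\)")
  expect_error(nlms_train(matrix(1, 2, 1), c(1, 0), eta = -1), "\\(0, 2\\)")
})

test_that("threshold selection matches an exhaustive sweep", {
  sel <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sel$threshold, 0.2)    # smallest grid value separating classes
  expect_equal(sel$f_measure, 1)
  # all scores identical: everything predicted positive below the score
  sel2 <- select_threshold(rep(0.7, 10), c(rep(1, 6), rep(0, 4)))
  p <- 0.6
  expect_equal(sel2$f_measure, 2 * p / (1 + p))
  expect_equal(sel2$threshold, 0)
  # random scores against a brute-force sweep oracle
  set.seed(28)
  for (i in 1:10) {
    sc <- runif(30)
    lab <- rbinom(30, 1, 0.5)
    if (length(unique(lab)) < 2) next
    brute <- sapply(seq(0, 1, 0.01), function(th) {
      pred <- as.integer(sc > th)
      tp <- sum(pred & lab); fp <- sum(pred & !lab); fn <- sum(!pred & lab)
      if (tp == 0) 0 else {
        pr <- tp / (tp + fp); re <- tp / (tp + fn)
        2 * pr * re / (pr + re)
      }
    })
    sel3 <- select_threshold(sc, lab)
    expect_equal(sel3$f_measure, max(brute))
    expect_equal(sel3$threshold, seq(0, 1, 0.01)[which.max(brute)])
  }
  expect_error(select_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("the full fit separates the synthetic cohort and is deterministic", {
  co <- generate_cohort(seed = 19, render = FALSE)
  f <- build_features(batch_qflow(co))
  m1 <- rbfnn_fit(f, k = 16, seed = 19, threshold = "sweep")
  expect_gte(m1$training$f_measure, 0.9)
  expect_equal(dim(m1$centers), c(16L, 6L))
  expect_gt(m1$sigma, 0)
  m2 <- rbfnn_fit(f, k = 16, seed = 19, threshold = "sweep")
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  # forward pass equals the activation-times-weight summation
  X <- as.matrix(apply_standardizer(f, m1$standardizer)[, m1$feature_names])
  manual <- rbf_activations(X, m1$centers, m1$sigma) %*% m1$weights
  expect_equal(predict(m1, f, type = "score"), drop(manual))
  cls <- predict(m1, f, type = "class")
  expect_identical(cls, as.integer(predict(m1, f) > m1$threshold))
})

test_that("with one center per point the network interpolates the labels", {
  set.seed(29)
  X <- matrix(rnorm(20 * 3), 20, 3)
  f <- tibble::as_tibble(as.data.frame(X))
  attr(f, "feature_names") <- names(f)
  f$label <- rep(c(1L, 0L), 10)
  m <- rbfnn_fit(f, k = 20, epochs = 4000, seed = 5, threshold = "sweep",
                 standardize = FALSE)
  expect_equal(m$training$f_measure, 1)
  # stochastic NLMS approaches but does not exactly reach the interpolant
  # on the near-singular kernel system; the separation itself is perfect
  expect_lt(m$training$mse_trace[4000], 0.05)
})

test_that("forward pass handles degenerate weight settings", {
  m <- list(centers = matrix(0, 1, 2), sigma = 1, weights = 0,
            threshold = 0.5, standardizer = NULL, feature_names = c("a", "b"))
  class(m) <- "rbfnn"
  expect_equal(predict(m, matrix(rnorm(10), 5, 2)), rep(0, 5))
  m$weights <- 2
  expect_equal(predict(m, matrix(0, 1, 2))[1], 2)   # at the center, w = 2
  expect_error(predict(m, matrix(0, 1, 3)), "dimension")
})

test_that("tidy and glance summarize the fitted network", {
  co <- generate_cohort(tiny_cfg(), seed = 6, render = FALSE)
  f <- build_features(batch_qflow(co))
  m <- rbfnn_fit(f, k = 4, epochs = 50, seed = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 4L)
  expect_true(all(c("unit", "weight", "center_sv_gsv") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$k, 4L)
  expect_equal(gl$n_train, 10L)
})
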