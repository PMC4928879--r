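gauss_bump <- function(center, width = 4, height = 1) {
  height * exp(-((1:100) - center)^2 / (2 * width^2))
}

planted_2mode <- function(seed, n = 400) {
  truth <- structure(list(
    k = 2L, weights = c(0.5, 0.5),
    means = cbind(t = c(25, 70), a = c(0.8, 0.6)),
    covariances = list(diag(c(9, 0.0025)), diag(c(9, 0.0025)))),
    class = "gmm_model")
  set.seed(seed)
  list(truth = truth, X = sample_gmm(truth, n))
}

test_that("mode count comes from the mean curve's peaks", {
  expect_equal(estimate_num_modes(gauss_bump(30) + 0.7 * gauss_bump(70)), 2L)
  expect_equal(estimate_num_modes(gauss_bump(50)), 1L)
  expect_error(estimate_num_modes(rep(0.3, 100)), "no peaks")
})

test_that("temporal k-means matches exhaustive search on a toy set", {
  # all 2^4 assignments of {1,2,9,10} into two clusters, brute force
  x <- c(1, 2, 9, 10)
  best <- Inf
  for (code in 0:15) {
    a <- as.integer(intToBits(code)[1:4]) + 1L
    if (length(unique(a)) < 2L) next
    J <- sum(sapply(1:2, function(j)
      if (any(a == j)) sum((x[a == j] - mean(x[a == j]))^2) else 0))
    best <- min(best, J)
  }
  km <- kmeans_time(x, 2, seed = 1)
  expect_equal(km$objective, best)
  expect_equal(best, 1.0)
  expect_equal(km$assignments, c(1L, 1L, 2L, 2L))
  expect_equal(km$centers, c(1.5, 9.5))
})

test_that("k-means edge cases: k = n, k = 1, k too large, determinism", {
  x <- c(3, 17, 42, 80)
  expect_equal(kmeans_time(x, 4, seed = 2)$objective, 0)
  km1 <- kmeans_time(x, 1, seed = 2)
  expect_equal(km1$objective, sum((x - mean(x))^2))
  expect_error(kmeans_time(c(5, 5, 5), 2), "distinct")
  set.seed(99)
  y <- runif(60, 1, 100)
  expect_identical(kmeans_time(y, 4, seed = 7), kmeans_time(y, 4, seed = 7))
})

test_that("cluster-based initialization uses centroids, shares, epsilon", {
  X <- rbind(cbind(rnorm(5, 20, 0.1), rnorm(5, 0.8, 0.01)),
             cbind(rnorm(5, 70, 0.1), rnorm(5, 0.5, 0.01)))
  colnames(X) <- c("t", "a")
  cloud <- structure(list(X = X, cycle = rep(1:2, each = 5)),
                     class = "peak_cloud")
  km <- kmeans_time(X[, "t"], 2, seed = 1)
  init <- init_from_clusters(cloud, km)
  expect_equal(init$weights, c(0.5, 0.5))
  expect_equal(init$means[order(init$means[, 1]), 1],
               sapply(split(X[, 1], km$assignments), mean)[order(km$centers)],
               ignore_attr = TRUE)
  # identical points in a cluster: covariance falls back to epsilon * I
  Xd <- cbind(t = c(rep(10, 4), rep(60, 4)), a = rep(0.5, 8))
  cloudd <- structure(list(X = Xd, cycle = 1:8), class = "peak_cloud")
  initd <- init_from_clusters(cloudd, kmeans_time(Xd[, "t"], 2, seed = 1))
  expect_equal(initd$covariances[[1]], diag(1e-6, 2), ignore_attr = TRUE)
})

test_that("initial means land near the planted cluster centers", {
  set.seed(13)
  centers <- c(20, 50, 85)
  X <- cbind(t = rep(centers, each = 50) + rnorm(150, sd = 1),
             a = runif(150, 0.4, 0.9))
  cloud <- structure(list(X = X, cycle = rep(1:50, 3)),
                     class = "peak_cloud")
  init <- init_from_clusters(cloud, kmeans_time(X[, "t"], 3, seed = 3))
  expect_true(all(abs(sort(init$means[, "t"]) - centers) <= 1))
})

test_that("EM recovers a single bivariate Gaussian", {
  set.seed(31)
  R <- chol(matrix(c(16, 0.3, 0.3, 0.04), 2))
  X <- sweep(matrix(rnorm(1000), ncol = 2) %*% R, 2, c(50, 0.5), "+")
  colnames(X) <- c("t", "a")
  init <- list(k = 1L, weights = 1,
               means = matrix(c(45, 0.4), 1, dimnames = list(NULL, c("t", "a"))),
               covariances = list(diag(c(25, 0.01))))
  fit <- fit_em(X, init)
  expect_equal(fit$weights, 1)
  se <- sqrt(diag(cov(X)) / nrow(X))
  expect_true(all(abs(fit$means[1, ] - colMeans(X)) <= 3 * se))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("EM recovers two planted modes from a k-means start", {
  errs_t <- c()
  errs_w <- c()
  for (seed in 1:5) {
    d <- planted_2mode(seed)
    cloud <- structure(list(X = d$X, cycle = seq_len(nrow(d$X))),
                       class = "peak_cloud")
    init <- init_from_clusters(cloud, kmeans_time(d$X[, "t"], 2, seed = seed))
    fit <- fit_em(cloud, init)
    ord <- order(fit$means[, "t"])
    errs_t <- c(errs_t, abs(fit$means[ord, "t"] - c(25, 70)))
    errs_w <- c(errs_w, abs(fit$weights[ord] - c(0.5, 0.5)))
  }
  expect_lte(median(errs_t), 1.5)
  expect_lte(median(errs_w), 0.05)
})

test_that("EM started at the optimum stays there", {
  # symmetric, well-separated toy set whose ML solution is the per-cluster
  # moment fit
  X <- rbind(cbind(c(19, 21, 20, 20), c(0.8, 0.8, 0.79, 0.81)),
             cbind(c(79, 81, 80, 80), c(0.4, 0.4, 0.39, 0.41)))
  colnames(X) <- c("t", "a")
  grp <- rep(1:2, each = 4)
  init <- list(k = 2L, weights = c(0.5, 0.5),
               means = rbind(colMeans(X[grp == 1, ]), colMeans(X[grp == 2, ])),
               covariances = lapply(1:2, function(j)
                 cov(X[grp == j, ]) * 3 / 4 + diag(1e-6, 2)))
  fit <- fit_em(X, init, tol = 1e-9)
  expect_equal(fit$means, init$means, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$weights, init$weights, tolerance = 1e-6)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  d <- planted_2mode(77, n = 300)
  cloud <- structure(list(X = d$X, cycle = seq_len(nrow(d$X))),
                     class = "peak_cloud")
  init <- init_from_clusters(cloud, kmeans_time(d$X[, "t"], 2, seed = 1))
  fit <- fit_em(cloud, init, tol = 1e-9)
  mc <- mclust::Mclust(d$X, G = 2, modelNames = "VVV", verbose = FALSE)
  ours <- fit$means[order(fit$means[, 1]), ]
  theirs <- t(mc$parameters$mean)[order(mc$parameters$mean[1, ]), ]
  expect_equal(ours, theirs, tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("EM input validation", {
  d <- planted_2mode(5, n = 2)
  init <- list(k = 2L, weights = c(0.5, 0.5),
               means = cbind(t = c(25, 70), a = c(0.8, 0.6)),
               covariances = list(diag(2), diag(2)))
  expect_error(fit_em(d$X, init), "more points than modes")
})

test_that("full-data fit shares the bump location with the peak fit", {
  # centered bump: the baseline samples surrounding it are symmetric, so
  # both fits estimate the same time location
  m <- vapply(1:20, function(i) normalize_cycle(gauss_bump(50)),
              numeric(100L))
  pm <- fit_peak_model(m, seed = 1)
  full <- fit_full_data_model(m, pm$init)
  peak_t <- pm$model$means[which.max(pm$model$weights), "t"]
  full_t <- full$means[which.max(full$weights), "t"]
  expect_lte(abs(peak_t - full_t), 2)
  expect_error(fit_full_data_model(matrix(0, 100, 10), pm$init),
               "degenerate")
})

test_that("noise baseline is deterministic under its seed", {
  init <- list(k = 2L, weights = c(0.5, 0.5),
               means = cbind(t = c(25, 70), a = c(0.8, 0.6)),
               covariances = list(diag(c(9, 0.01)), diag(c(9, 0.01))))
  a <- fit_noise_baseline(12, init, seed = 4)
  b <- fit_noise_baseline(12, init, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, fit_noise_baseline(12, init, seed = 5)))
})

test_that("mode ranking orders by weight with frame tie-break and pads", {
  gmm <- structure(list(
    k = 2L, weights = c(0.3, 0.7),
    means = cbind(t = c(20, 60), a = c(0.9, 0.5)),
    covariances = list(diag(c(4, 0.01)), diag(c(4, 0.01))),
    covariance_type = "full"), class = "gmm_model")
  ref <- gauss_bump(20) + 0.6 * gauss_bump(60)
  rk <- rank_modes(gmm, ref)
  expect_equal(nrow(rk), 5L)
  expect_equal(rk$WhMC[1], 60)
  expect_equal(rk$WhMC[2], 20)
  expect_true(all(is.na(rk$WhMC[3:5])))
  expect_equal(rk$HhMC[1:2], c(20, 60))
  expect_true(all(is.na(rk$HhMC[3:5])))
  # equal weights: earlier frame ranks first
  gmm$weights <- c(0.5, 0.5)
  expect_equal(rank_modes(gmm, ref)$WhMC[1], 20)
})
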