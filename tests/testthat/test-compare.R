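test_that("gaussian overlap has the closed-form value for standard normals", {
  I2 <- diag(2)
  expect_equal(gaussian_overlap(c(0, 0), I2, c(0, 0), I2), 1 / (4 * pi),
               tolerance = 1e-12)
  # far-apart means underflow to zero but stay finite in log space
  lv <- gaussian_overlap(c(0, 0), I2, c(100, 0), I2, log = TRUE)
  expect_lt(lv, -600)
  expect_equal(gaussian_overlap(c(0, 0), I2, c(100, 0), I2), 0)
  expect_error(gaussian_overlap(c(0, 0), matrix(c(1, 2, 2, 1), 2),
                                c(0, 0), I2), "positive definite")
})

test_that("gaussian overlap matches Monte-Carlo integration", {
  set.seed(15)
  for (i in 1:5) {
    S1 <- random_pd_cov(scale = c(2, 1))
    S2 <- random_pd_cov(scale = c(2, 1))
    mu1 <- runif(2, -2, 2)
    mu2 <- runif(2, -2, 2)
    n <- 2e5
    R <- chol(S1)
    x <- sweep(matrix(rnorm(2 * n), ncol = 2) %*% R, 2, mu1, "+")
    vals <- exp(emgmm:::log_dmvnorm2(x, mu2, S2))
    expect_lt(abs(gaussian_overlap(mu1, S1, mu2, S2) - mean(vals)),
              3 * sd(vals) / sqrt(n) + 1e-12)
  }
})

test_that("cauchy-schwarz distance is a symmetric premetric on mixtures", {
  set.seed(8)
  for (i in 1:10) {
    P <- random_gmm()
    Q <- random_gmm()
    expect_lt(cauchy_schwarz_distance(P, P)$dist, 1e-10)
    dpq <- suppressWarnings(cauchy_schwarz_distance(P, Q)$dist)
    expect_gte(dpq, 0)
    expect_equal(dpq, suppressWarnings(cauchy_schwarz_distance(Q, P)$dist),
                 tolerance = 1e-12)
  }
})

test_that("unit-isotropic single modes at separation d give d^2/4", {
  mk <- function(mu) structure(list(k = 1L, weights = 1,
                                    means = matrix(mu, 1),
                                    covariances = list(diag(2))),
                               class = "gmm_model")
  expect_equal(cauchy_schwarz_distance(mk(c(0, 0)), mk(c(2, 0)))$dist, 1,
               tolerance = 1e-12)
  expect_equal(cauchy_schwarz_distance(mk(c(3, 4)), mk(c(3, 7)))$dist,
               9 / 4, tolerance = 1e-12)
})

test_that("closed form matches the Monte-Carlo oracle on random mixtures", {
  set.seed(23)
  for (i in 1:5) {
    P <- random_gmm()
    Q <- random_gmm()
    cf <- suppressWarnings(cauchy_schwarz_distance(P, Q)$dist)
    mc <- mc_cs_distance(P, Q, n = 2e5)
    expect_lt(abs(cf - mc$dist), 3 * mc$se + 1e-6)
  }
})

test_that("distance is invariant under a shared affine amplitude map", {
  # rescaling the amplitude axis of both mixtures by y -> c*y + b scales
  # every overlap integral by 1/c, which cancels in the normalized ratio
  rescale <- function(m, c0, b0) {
    m$means[, 2] <- c0 * m$means[, 2] + b0
    m$covariances <- lapply(m$covariances, function(S) {
      S[2, ] <- c0 * S[2, ]
      S[, 2] <- c0 * S[, 2]
      S
    })
    m
  }
  set.seed(41)
  P <- random_gmm(k = 2)
  Q <- random_gmm(k = 2)
  d0 <- cauchy_schwarz_distance(P, Q)$dist
  d1 <- cauchy_schwarz_distance(rescale(P, 3.7, -1), rescale(Q, 3.7, -1))$dist
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("zero-weight modes are dropped, unequal counts warn", {
  P <- random_gmm(k = 2)
  P0 <- P
  P0$k <- 3L
  P0$weights <- c(P$weights, 0)
  P0$means <- rbind(P$means, c(50, 0.5))
  P0$covariances <- c(P$covariances, list(diag(2)))
  expect_equal(cauchy_schwarz_distance(P0, P)$dist, 0, tolerance = 1e-10)
  Q <- random_gmm(k = 3)
  expect_warning(cauchy_schwarz_distance(P, Q), "mode counts differ")
})

test_that("model agreement report distances and ratio semantics", {
  P <- random_gmm(k = 2)
  rep0 <- model_agreement_report(P, P, P)
  expect_equal(rep0$dist_full, 0)
  expect_equal(rep0$dist_noise, 0)
  expect_true(is.na(rep0$ratio))
  Q <- random_gmm(k = 2)
  rep1 <- model_agreement_report(P, P, Q)
  expect_true(is.infinite(rep1$ratio))
  expect_error(model_agreement_report(P, P, random_gmm(k = 3)),
               "mode counts differ")
})

test_that("peak model sits closer to the full-data model than to noise", {
  # structured corpora: the paper-style separation direction should hold for
  # the large majority of groups
  ok <- c()
  for (seed in c(3, 42, 101)) for (sensor in c("GML1", "GMR2")) {
    rec <- generate_trial(synthetic_truth("walk", seed = seed))
    cs <- pipeline_cycles(rec, sensor, min_stance_s = 0.2)
    pm <- fit_peak_model(cs, seed = 1)
    full <- fit_full_data_model(cs, pm$init)
    nb <- fit_noise_baseline(ncol(cs$normalized), pm$init, seed = seed + 1,
                             cycle_s = 1)
    ag <- model_agreement_report(pm$model, full, nb)
    ok <- c(ok, ag$dist_full < ag$dist_noise)
  }
  expect_gte(mean(ok), 5 / 6)
})
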