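ramp_cycle <- normalize_cycle(seq(0, 1, length.out = 60))

test_that("identical cycles give zero deviation and zero variability", {
  m <- matrix(rep(ramp_cycle, 8), ncol = 8)
  d <- deviation_stats(m)
  expect_equal(c(d$v, d$mean_dev, d$mad), c(0, 0, 0))
  expect_equal(variance_to_mean_ratio(m)$cv, 0)
  # the min-max normalized ramp has a zero frame, excluded from cv_t
  cv_t <- variance_to_mean_ratio(m)$cv_t
  expect_equal(cv_t[!is.na(cv_t)], rep(0, 99))
  expect_equal(variability_ratio(m), 0)
  expect_equal(cqv(m)$cqv, 0)
  r <- variability_report(m)
  expect_equal(unlist(r[c("mad", "cv", "vr", "cqv")]),
               c(mad = 0, cv = 0, vr = 0, cqv = 0))
})

test_that("a constant offset cycle has the closed-form deviations", {
  ref <- ramp_cycle
  m <- matrix(ref + 0.1, ncol = 1)
  d <- deviation_stats(m, reference = ref)
  expect_equal(d$v, 0.1 * sqrt(100))  # l2 over 100 frames
  expect_equal(d$mean_dev, 1.0)
  expect_equal(d$mad, 0.1)
})

test_that("variance-to-mean ratio follows the stated variance convention", {
  m <- cbind(rep(0.4, 100), rep(0.6, 100))
  expect_equal(variance_to_mean_ratio(m)$cv, 0.02 / 0.5)          # sample
  expect_equal(variance_to_mean_ratio(m, population = TRUE)$cv,
               0.01 / 0.5)
  expect_error(variance_to_mean_ratio(matrix(0, 100, 3)), "undefined")
})

test_that("per-frame CV excludes zero-mean frames with a count", {
  m <- rbind(matrix(0, 10, 4), matrix(c(0.4, 0.6), 90, 4))
  vm <- variance_to_mean_ratio(m)
  expect_equal(vm$n_excluded, 10L)
  expect_true(all(is.na(vm$cv_t[1:10])))
})

test_that("CV approaches the analytic value for known noise", {
  set.seed(3)
  mu <- 0.5
  sigma <- 0.1
  m <- matrix(rnorm(100 * 200, mean = mu, sd = sigma), 100, 200)
  vm <- variance_to_mean_ratio(m)
  expect_equal(vm$cv, sigma^2 / mu, tolerance = 0.1)
  expect_equal(vm$mean_cv, sigma / mu, tolerance = 0.1)
})

test_that("variability ratio matches a brute-force double-loop oracle", {
  vr_oracle <- function(m) {
    n <- nrow(m)
    mm <- ncol(m)
    num <- 0
    for (i in seq_len(n)) for (j in seq_len(mm))
      num <- num + (m[i, j] - mean(m[i, ]))^2
    den <- 0
    for (i in seq_len(n)) for (j in seq_len(mm))
      den <- den + (m[i, j] - mean(m))^2
    (num / (n * (mm - 1))) / (den / (n * mm - 1))
  }
  set.seed(17)
  for (i in 1:5) {
    m <- matrix(runif(100 * 7), 100, 7)
    expect_equal(variability_ratio(m), vr_oracle(m), tolerance = 1e-12)
  }
  expect_error(variability_ratio(matrix(0.2, 100, 4)), "zero total variance")
})

test_that("structureless noise drives the variability ratio to one", {
  set.seed(5)
  m <- matrix(rnorm(100 * 500, mean = 0.5, sd = 0.1), 100, 500)
  expect_lt(abs(variability_ratio(m) - 1), 0.05)
})

test_that("inter-quartile coefficient uses interpolated quartiles", {
  m <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = 100), 100, 4)
  r <- cqv(m)
  expect_equal(r$cqv_t, rep(0.3, 100))  # (0.65 - 0.35) / (0.65 + 0.35)
  expect_equal(r$cqv, 0.3)
  # frames whose quartiles sum to zero are flagged and skipped
  m2 <- rbind(matrix(0, 30, 4), m[31:100, ])
  r2 <- cqv(m2)
  expect_equal(r2$n_invalid, 30L)
  expect_equal(r2$cqv, 0.3)
})

test_that("statistics are invariant under cycle reordering", {
  set.seed(29)
  m <- matrix(runif(100 * 9), 100, 9)
  p <- m[, sample(9)]
  expect_equal(variability_report(m), variability_report(p))
})

test_that("duplicating the cycle set doubles v and preserves the ratios", {
  # population-variance statistics are exactly duplication-invariant; the
  # sample-variance and interpolated-quartile versions converge to
  # invariance as the cycle count grows
  set.seed(30)
  m <- matrix(runif(100 * 60, 0.1, 0.9), 100, 60)
  m2 <- cbind(m, m)
  expect_equal(deviation_stats(m2)$v, 2 * deviation_stats(m)$v)
  expect_equal(deviation_stats(m2)$mad, deviation_stats(m)$mad)
  expect_equal(variance_to_mean_ratio(m2, population = TRUE)$cv,
               variance_to_mean_ratio(m, population = TRUE)$cv)
  expect_equal(variability_ratio(m2), variability_ratio(m), tolerance = 0.02)
  expect_equal(cqv(m2)$cqv, cqv(m)$cqv, tolerance = 0.02)
})

test_that("inter-subject statistics mirror the intra formulas on mean curves", {
  same <- matrix(rep(ramp_cycle, 5), ncol = 5)
  r <- inter_subject_stats(same)
  expect_equal(unlist(r[c("mean_dev", "mad", "cv", "vr", "cqv")]),
               c(mean_dev = 0, mad = 0, cv = 0, vr = 0, cqv = 0))
  expect_error(inter_subject_stats(matrix(ramp_cycle, ncol = 1)),
               "at least 2")
  # mean deviation grows monotonically with the between-subject offset
  set.seed(19)
  base <- ramp_cycle
  devs <- sapply(c(0.02, 0.05, 0.1), function(s) {
    curves <- vapply(1:6, function(i) base + rnorm(100, sd = s),
                     numeric(100L))
    inter_subject_stats(curves)$mean_dev
  })
  expect_true(all(diff(devs) > 0))
})
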