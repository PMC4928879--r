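gauss_bump <- function(center, width = 4, height = 1) {
  height * exp(-((1:100) - center)^2 / (2 * width^2))
}

test_that("find_peaks locates isolated maxima", {
  one <- find_peaks(gauss_bump(40))
  expect_equal(one$t, 40L)
  expect_equal(one$a, max(gauss_bump(40)))
  expect_equal(nrow(find_peaks(seq(0, 1, length.out = 100))), 0L)
  two <- find_peaks(0.6 * gauss_bump(25) + 0.9 * gauss_bump(70))
  expect_equal(two$t, c(25L, 70L))
})

test_that("find_peaks agrees with an exhaustive local-maximum scan", {
  naive_peaks <- function(curve) {
    which(vapply(2:99, function(t)
      curve[t] > curve[t - 1] && curve[t] >= curve[t + 1], logical(1L))) + 1L
  }
  set.seed(4)
  for (i in 1:20) {
    curve <- as.numeric(stats::filter(rnorm(120), rep(1 / 7, 7),
                                      sides = 2))[11:110]
    got <- find_peaks(curve, min_prominence = 0, min_separation = 1L)
    expect_identical(got$t, as.integer(naive_peaks(curve)))
  }
})

test_that("prominence and separation filters behave as documented", {
  # a tiny wiggle on a big bump is discarded at the default prominence
  curve <- gauss_bump(40) + 0.01 * gauss_bump(80, width = 2)
  expect_equal(find_peaks(curve)$t, 40L)
  # among close peaks the higher one wins and gaps respect min_separation
  set.seed(11)
  for (i in 1:10) {
    curve <- as.numeric(stats::filter(rnorm(110), rep(0.2, 5),
                                      sides = 2))[6:105]
    p <- find_peaks(curve, min_prominence = 0, min_separation = 5L)
    if (nrow(p) > 1L) expect_true(all(diff(p$t) >= 5))
  }
  # plateau: leftmost frame wins
  flat <- c(rep(0, 40), rep(1, 5), rep(0, 55))
  expect_equal(find_peaks(flat)$t, 41L)
})

test_that("circular distance takes the shortest route around the cycle", {
  expect_equal(circular_distance(1, 100), 1)
  expect_equal(circular_distance(10, 30), 20)
  expect_equal(circular_distance(20, 70), 50)
  expect_error(circular_distance(0, 10), "frames")
  grid <- expand.grid(a = seq(1, 100, by = 7), b = seq(1, 100, by = 11))
  d <- circular_distance(grid$a, grid$b)
  expect_equal(d, circular_distance(grid$b, grid$a))
  expect_true(all(d <= 50) && all(d >= 0))
  expect_identical(d == 0, grid$a == grid$b)
})

test_that("peak clouds pool per-cycle maxima", {
  cyc <- gauss_bump(35)
  m <- matrix(rep(cyc, 10), ncol = 10)
  cloud <- extract_peak_cloud(m)
  expect_equal(nrow(cloud$X), 10L)
  expect_true(all(cloud$X[, "t"] == 35))
  expect_equal(cloud$cycle, 1:10)
  m[, 4] <- 0  # a silent cycle contributes nothing
  cloud2 <- extract_peak_cloud(m)
  expect_false(4L %in% cloud2$cycle)
  expect_error(extract_peak_cloud(matrix(0, 100, 5)), "no peaks")
})

test_that("detected peak times track the planted bump under mild noise", {
  set.seed(2)
  m <- vapply(1:200, function(i)
    normalize_cycle(gauss_bump(47) + rnorm(100, sd = 0.02)), numeric(100L))
  cloud <- extract_peak_cloud(m)
  top <- vapply(split(seq_len(nrow(cloud$X)), cloud$cycle), function(idx) {
    rows <- cloud$X[idx, , drop = FALSE]
    rows[which.max(rows[, "a"]), "t"]
  }, numeric(1L))
  expect_gte(mean(abs(top - 47) <= 2), 0.95)
})

test_that("two-peak distance histogram bins per-subject means", {
  cyc <- 0.8 * gauss_bump(10) + gauss_bump(55)
  sets <- list(A = matrix(rep(cyc, 5), ncol = 5),
               B = matrix(rep(cyc, 5), ncol = 5))
  h <- two_peak_distance_histogram(sets)
  expect_equal(unname(h$counts), c(0L, 0L, 0L, 2L))  # distance 45
  expect_equal(unname(h$subject_means), c(45, 45))
  # subject without a two-peak cycle is excluded with a warning
  sets$C <- matrix(rep(gauss_bump(30), 4), ncol = 4)
  expect_warning(h2 <- two_peak_distance_histogram(sets), "C")
  expect_equal(sum(h2$counts), 2L)
  # wrap-around gap: peaks at 95 and 10 are 15 frames apart
  wrap <- gauss_bump(95, width = 3) + 0.9 * gauss_bump(10, width = 3)
  h3 <- two_peak_distance_histogram(list(W = matrix(rep(wrap, 3), ncol = 3)))
  expect_equal(unname(h3$counts), c(1L, 0L, 0L, 0L))
})

test_that("planted cohort gaps land in the planted histogram bins", {
  set.seed(6)
  mk <- function(gap, n) {
    lapply(seq_len(n), function(i) {
      cyc <- gauss_bump(20, width = 3) + 0.85 * gauss_bump(20 + gap, width = 3)
      m <- vapply(1:6, function(j)
        normalize_cycle(cyc + rnorm(100, sd = 0.01)), numeric(100L))
      m
    })
  }
  sets <- c(mk(15, 3), mk(35, 4))
  names(sets) <- paste0("S", 1:7)
  h <- two_peak_distance_histogram(sets)
  expect_equal(unname(h$counts), c(3L, 0L, 4L, 0L))
})
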