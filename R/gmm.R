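#' Number of mixture modes from the mean curve
#'
#' The mode count of the per-sensor mixture is fixed a priori as the number
#' of peaks of the mean reference curve, which is a robust summary of the
#' individual noisy cycles.
#'
#' @param reference_curve length-100 mean curve, or the list returned by
#'   [reference_curves()].
#' @inheritParams find_peaks
#' @return integer k >= 1.
#' @export
estimate_num_modes <- function(reference_curve, min_prominence = 0.05,
                               min_separation = 3L) {
  if (is.list(reference_curve)) reference_curve <- reference_curve$mean_curve
  p <- find_peaks(reference_curve, min_prominence, min_separation)
  if (nrow(p) == 0L) stop("mean curve has no peaks; cannot choose a mode count")
  nrow(p)
}

#' k-means on the time coordinate of peak locations
#'
#' Temporal pre-clustering of peak frames used to initialize the mixture fit.
#' Lloyd's algorithm on the 1-D time coordinate with seeded greedy
#' farthest-point initialization; the best of `n_restarts` runs (lowest total
#' intra-cluster sum of squared distances J) is kept. Deterministic given
#' `seed`.
#'
#' @param peak_times numeric vector of peak frames.
#' @param k number of clusters; must not exceed the number of distinct times.
#' @param seed integer seed.
#' @param n_restarts restarts with different random first centers
#'   (default 10).
#' @return list with `k`, `assignments` (cluster index per point, clusters
#'   numbered in increasing center order), `centers` (sorted), `objective`
#'   (J, the total intra-cluster sum of squared distances).
#' @export
kmeans_time <- function(peak_times, k, seed = 1L, n_restarts = 10L) {
  x <- as.numeric(peak_times)
  ux <- unique(x)
  if (k > length(ux)) stop("k exceeds the number of distinct peak times")
  if (k < 1L) stop("k must be >= 1")
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    centers <- farthest_point_centers(ux, k)
    fit <- lloyd_1d(x, centers)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  ord <- order(best$centers)
  list(k = k,
       assignments = match(best$assignments, ord),
       centers = best$centers[ord],
       objective = best$objective)
}

# Greedy farthest-point seeding over distinct values: random first center,
# then repeatedly the value farthest from the chosen set.
farthest_point_centers <- function(ux, k) {
  centers <- ux[sample.int(length(ux), 1L)]
  while (length(centers) < k) {
    d <- vapply(ux, function(v) min(abs(v - centers)), numeric(1L))
    centers <- c(centers, ux[which.max(d)])
  }
  centers
}

lloyd_1d <- function(x, centers, max_iter = 100L) {
  k <- length(centers)
  assign_pts <- function(cen)
    max.col(-abs(outer(x, cen, "-")), ties.method = "first")
  a <- assign_pts(centers)
  for (i in seq_len(max_iter)) {
    new_centers <- vapply(seq_len(k), function(j) {
      if (any(a == j)) mean(x[a == j]) else centers[j]
    }, numeric(1L))
    new_a <- assign_pts(new_centers)
    done <- identical(new_a, a)
    centers <- new_centers
    a <- new_a
    if (done) break
  }
  list(assignments = a, centers = centers,
       objective = sum((x - centers[a])^2))
}

#' Initial mixture parameters from a temporal clustering
#'
#' Each k-means cluster seeds one mode: the initial mean is the 2-D centroid
#' of its member peaks, the initial covariance is the member covariance plus
#' `epsilon` times the identity (a singleton or degenerate cluster therefore
#' gets `epsilon * I`), and the initial weight is the cluster's share of the
#' points.
#'
#' @param peak_cloud a `peak_cloud` from [extract_peak_cloud()].
#' @param kmeans_result output of [kmeans_time()] on the cloud's times.
#' @param epsilon covariance regularizer (default 1e-6).
#' @return list with `weights`, `means` (k x 2), `covariances`
#'   (list of 2 x 2), `k`.
#' @export
init_from_clusters <- function(peak_cloud, kmeans_result, epsilon = 1e-6) {
  X <- peak_cloud$X
  a <- kmeans_result$assignments
  k <- kmeans_result$k
  if (length(a) != nrow(X)) stop("assignment length does not match the cloud")
  means <- matrix(0, k, 2L, dimnames = list(NULL, c("t", "a")))
  covs <- vector("list", k)
  w <- numeric(k)
  for (j in seq_len(k)) {
    pts <- X[a == j, , drop = FALSE]
    if (nrow(pts) == 0L) stop(sprintf("cluster %d is empty", j))
    means[j, ] <- colMeans(pts)
    cv <- if (nrow(pts) > 1L) unname(stats::cov(pts)) else matrix(0, 2L, 2L)
    cv[!is.finite(cv)] <- 0
    covs[[j]] <- cv + diag(epsilon, 2L)
    w[j] <- nrow(pts) / nrow(X)
  }
  list(weights = w, means = means, covariances = covs, k = k)
}

# Rows of log N(x; mu, Sigma) for an n x 2 matrix, via Cholesky.
log_dmvnorm2 <- function(X, mu, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(rep(-Inf, nrow(X)))
  centered <- sweep(X, 2L, mu)
  z <- backsolve(R, t(centered), transpose = TRUE)
  -log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

log_sum_exp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Fit a bivariate Gaussian mixture by expectation maximization
#'
#' Maximizes the mixture log-likelihood over weights, means and covariances
#' by EM from the supplied initialization. The E-step computes
#' responsibilities in log space; the M-step re-estimates the weighted
#' moments, adds `epsilon * I` to every covariance, and renormalizes the
#' weights. Iteration stops when the relative log-likelihood improvement
#' drops below `tol` or after `max_iter` iterations. A mode whose
#' responsibility mass collapses (below `1e-8 * N`) is re-seeded at the point
#' the current model explains worst.
#'
#' @param X N x 2 matrix of points (a `peak_cloud` is accepted), N > number
#'   of modes.
#' @param init initialization as returned by [init_from_clusters()].
#' @param tol relative log-likelihood tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param covariance `"full"` (default) for general 2 x 2 covariances, or
#'   `"isotropic"` for per-mode spherical covariances (one shared variance
#'   across both coordinates).
#' @param epsilon covariance regularizer added every M-step (default 1e-6).
#' @return A `gmm_model`: list with `k`, `weights`, `means`, `covariances`,
#'   `loglik` (final), `loglik_trace`, `converged`, `n_iter`, `n_points`,
#'   `covariance_type`.
#' @export
fit_em <- function(X, init, tol = 1e-6, max_iter = 500L,
                   covariance = c("full", "isotropic"), epsilon = 1e-6) {
  covariance <- match.arg(covariance)
  if (inherits(X, "peak_cloud")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != 2L) stop("X must have 2 columns")
  N <- nrow(X)
  k <- init$k
  if (N <= k) stop("need more points than modes")
  w <- init$weights / sum(init$weights)
  mu <- as.matrix(init$means)
  covs <- init$covariances
  trace <- numeric(0)
  converged <- FALSE
  prev_ll <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step in log space
    log_comp <- vapply(seq_len(k), function(j)
      log(w[j]) + log_dmvnorm2(X, mu[j, ], covs[[j]]), numeric(N))
    log_comp <- matrix(log_comp, nrow = N)
    lse <- log_sum_exp_rows(log_comp)
    ll <- sum(lse)
    if (!is.finite(ll))
      stop(sprintf("non-finite log-likelihood at iteration %d", iter))
    trace <- c(trace, ll)
    if (iter > 1L && abs(ll - prev_ll) <= tol * abs(prev_ll)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    prev_ll <- ll
    resp <- exp(log_comp - lse)
    Nk <- colSums(resp)
    # re-seed collapsed modes at the worst-explained points (distinct per
    # mode; capped loop since stealing a point can empty another mode)
    guard <- 0L
    while (any(Nk < 1e-8 * N) && guard < k) {
      guard <- guard + 1L
      empty <- which(Nk < 1e-8 * N)
      worst <- order(lse)
      for (m in seq_along(empty)) {
        i <- worst[m]
        resp[i, ] <- 0
        resp[i, empty[m]] <- 1
      }
      Nk <- colSums(resp)
    }
    # M-step
    w <- Nk / N
    w <- w / sum(w)
    for (j in seq_len(k)) {
      rj <- resp[, j]
      if (Nk[j] <= 0) {
        # pathological: pin the mode at the least-explained point
        i <- which.min(lse)
        mu[j, ] <- X[i, ]
        covs[[j]] <- diag(epsilon, 2L)
        next
      }
      mu[j, ] <- colSums(X * rj) / Nk[j]
      centered <- sweep(X, 2L, mu[j, ])
      S <- crossprod(centered * sqrt(rj)) / Nk[j]
      if (covariance == "isotropic") {
        s2 <- mean(diag(S))
        S <- diag(s2, 2L)
      }
      if (!all(is.finite(S))) S <- matrix(0, 2L, 2L)
      covs[[j]] <- S + diag(epsilon, 2L)
    }
  }
  structure(list(k = k, weights = w, means = mu, covariances = covs,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 converged = converged, n_iter = iter, n_points = N,
                 covariance_type = covariance),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> %d modes, %s covariance, loglik %.4f (%s in %d iter)\n",
              x$k, x$covariance_type, x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  ord <- order(-x$weights)
  for (j in ord)
    cat(sprintf("  mode @ frame %5.1f, amp %.3f, weight %.3f\n",
                x$means[j, 1L], x$means[j, 2L], x$weights[j]))
  invisible(x)
}

#' Fit the peak-based mixture of one sensor
#'
#' Convenience wrapper for the whole per-sensor modeling chain: mean-curve
#' mode count, temporal k-means, cluster-based initialization, EM.
#'
#' @param cycleset normalized `cycle_set` of one sensor.
#' @param seed seed for the k-means restarts.
#' @param k mode count; default is estimated from the mean curve.
#' @param ... passed to [fit_em()].
#' @return list with `model` (`gmm_model`), `init`, `kmeans`, `cloud`, `k`,
#'   `reference` (from [reference_curves()]).
#' @export
fit_peak_model <- function(cycleset, seed = 1L, k = NULL, ...) {
  ref <- reference_curves(cycleset)
  if (is.null(k)) k <- estimate_num_modes(ref$mean_curve)
  cloud <- extract_peak_cloud(cycleset)
  k <- min(k, length(unique(cloud$X[, "t"])), nrow(cloud$X) - 1L)
  if (k < 1L) stop("too few peaks to fit a mixture")
  km <- kmeans_time(cloud$X[, "t"], k, seed = seed)
  init <- init_from_clusters(cloud, km)
  model <- fit_em(cloud, init, ...)
  list(model = model, init = init, kmeans = km, cloud = cloud, k = k,
       reference = ref)
}

#' Fit the same mixture to the full normalized samples
#'
#' Fits a mixture with the identical initialization as the peak-based model
#' to every (frame, value) sample of every normalized cycle, for a direct
#' comparison of peak-based against full-data modeling.
#'
#' @param cycleset normalized `cycle_set`.
#' @param init initialization of the peak-based model (same mode count).
#' @param ... passed to [fit_em()].
#' @return a `gmm_model`.
#' @export
fit_full_data_model <- function(cycleset, init, ...) {
  m <- normalized_matrix(cycleset)
  if (diff(range(m)) <= 0) stop("degenerate cycles: no amplitude structure")
  X <- cbind(t = rep.int(seq_len(100L), ncol(m)), a = as.numeric(m))
  fit_em(X, init, ...)
}

#' Fit the noise baseline mixture
#'
#' Fits a mixture with the same initialization to pseudo-peaks extracted
#' from a stream of white Gaussian noise pushed through the identical
#' processing chain as real EMG (rectification, rate reduction, envelope
#' low-pass, segmentation into a matched number of cycles, normalization,
#' peak extraction). Its distance to the peak-based model calibrates how
#' large a mixture distance "no temporal structure" produces.
#'
#' @param n_cycles number of noise cycles (match the real cycle count).
#' @param init initialization of the peak-based model.
#' @param seed integer seed; the same seed reproduces the identical model.
#' @param cycle_s pseudo-cycle duration in seconds (default 0.8).
#' @param emg_rate,target_rate processing rates in Hz (defaults 4000 / 120).
#' @param ... passed to [fit_em()].
#' @return a `gmm_model`.
#' @export
fit_noise_baseline <- function(n_cycles, init, seed = 1L, cycle_s = 0.8,
                               emg_rate = 4000, target_rate = 120, ...) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  n <- ceiling((n_cycles + 0.5) * cycle_s * emg_rate)
  stream <- emg_signal(stats::rnorm(n), emg_rate)
  pp <- preprocess_emg(stream, target_rate = target_rate)
  onsets <- round(seq(1, by = cycle_s * target_rate,
                      length.out = n_cycles + 1L))
  cs <- normalize_cycles(segment_cycles(pp, onsets))
  cloud <- extract_peak_cloud(cs)
  fit_em(cloud, init, ...)
}

#' Rank mixture modes by contribution and pair them with raw curve peaks
#'
#' Modes are ranked by mixing weight (ties broken by earlier frame). For each
#' of the top `top` ranks the table reports the mode's relative temporal
#' position among all modes (`WhRelValue`, time-sorted index / mode count),
#' its frame (`WhMC`), and the mixture density at its mean (`WhValue`);
#' alongside, the frames and heights of the reference curve's `top` highest
#' raw peaks (`HhMC`, `HhValue`). Missing ranks are padded with `NA`.
#'
#' @param gmm a fitted `gmm_model`.
#' @param reference_curve length-100 mean curve (or [reference_curves()]
#'   output).
#' @param top number of ranks to report (default 5).
#' @return data.frame with columns `rank`, `WhRelValue`, `WhMC`, `WhValue`,
#'   `HhMC`, `HhValue`.
#' @export
rank_modes <- function(gmm, reference_curve, top = 5L) {
  stopifnot(inherits(gmm, "gmm_model"))
  if (is.list(reference_curve)) reference_curve <- reference_curve$mean_curve
  ord <- order(-gmm$weights, gmm$means[, 1L])
  time_rank <- rank(gmm$means[, 1L], ties.method = "first")
  dens_at <- function(x) {
    sum(vapply(seq_len(gmm$k), function(j)
      gmm$weights[j] *
        exp(log_dmvnorm2(matrix(x, 1L), gmm$means[j, ], gmm$covariances[[j]])),
      numeric(1L)))
  }
  curve_peaks <- find_peaks(reference_curve)
  hp <- curve_peaks[order(-curve_peaks$a, curve_peaks$t), , drop = FALSE]
  out <- data.frame(rank = seq_len(top), WhRelValue = NA_real_,
                    WhMC = NA_real_, WhValue = NA_real_,
                    HhMC = NA_real_, HhValue = NA_real_)
  for (i in seq_len(min(top, gmm$k))) {
    j <- ord[i]
    out$WhRelValue[i] <- time_rank[j] / gmm$k
    out$WhMC[i] <- gmm$means[j, 1L]
    out$WhValue[i] <- dens_at(gmm$means[j, ])
  }
  for (i in seq_len(min(top, nrow(hp)))) {
    out$HhMC[i] <- hp$t[i]
    out$HhValue[i] <- hp$a[i]
  }
  out
}
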