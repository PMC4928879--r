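# Shared test helpers: random mixture models, mixture sampling, and a
# Monte-Carlo estimator of the Cauchy-Schwarz distance used as the
# independent oracle for the closed form.

random_pd_cov <- function(scale = c(5, 0.1)) {
  A <- matrix(stats::rnorm(4), 2L)
  S <- crossprod(A) + diag(0.3, 2L)
  D <- diag(scale)
  D %*% S %*% D / 2
}

random_gmm <- function(k = sample(1:3, 1L), t_range = c(10, 90),
                       cov_scale = c(5, 0.1)) {
  w <- stats::runif(k, 0.2, 1)
  means <- cbind(t = stats::runif(k, t_range[1L], t_range[2L]),
                 a = stats::runif(k, 0.2, 0.9))
  structure(list(k = k, weights = w / sum(w), means = means,
                 covariances = replicate(k, random_pd_cov(cov_scale),
                                         simplify = FALSE),
                 covariance_type = "full"),
            class = "gmm_model")
}

# Random mixtures whose modes genuinely overlap: mode separations stay
# within a few standard deviations, so plain Monte-Carlo integration of the
# overlap integrals is well-conditioned (no rare-event estimates).
random_gmm_overlapping <- function(k = sample(1:3, 1L)) {
  random_gmm(k, t_range = c(35, 65), cov_scale = c(10, 0.35))
}

sample_gmm <- function(model, n) {
  comp <- sample.int(model$k, n, replace = TRUE, prob = model$weights)
  X <- matrix(0, n, 2L, dimnames = list(NULL, c("t", "a")))
  for (j in seq_len(model$k)) {
    idx <- which(comp == j)
    if (!length(idx)) next
    R <- chol(model$covariances[[j]])
    Z <- matrix(stats::rnorm(2L * length(idx)), ncol = 2L)
    X[idx, ] <- sweep(Z %*% R, 2L, model$means[j, ], "+")
  }
  X
}

gmm_density <- function(model, X) {
  out <- numeric(nrow(X))
  for (j in seq_len(model$k)) {
    out <- out + model$weights[j] *
      exp(emgmm:::log_dmvnorm2(X, model$means[j, ], model$covariances[[j]]))
  }
  out
}

# Monte-Carlo estimate of the Cauchy-Schwarz distance: each integral
# int f g is estimated as the mean of g over draws from f; the standard
# error of the assembled distance follows by the delta method (the three
# estimates use independent samples).
mc_cs_distance <- function(P, Q, n = 1e6) {
  est <- function(from, dens_of) {
    v <- gmm_density(dens_of, sample_gmm(from, n))
    c(mean = mean(v), se = stats::sd(v) / sqrt(n))
  }
  cross <- est(P, Q)
  self_p <- est(P, P)
  self_q <- est(Q, Q)
  dist <- -(log(cross["mean"]) -
              0.5 * (log(self_p["mean"]) + log(self_q["mean"])))
  se <- sqrt((cross["se"] / cross["mean"])^2 +
               0.25 * (self_p["se"] / self_p["mean"])^2 +
               0.25 * (self_q["se"] / self_q["mean"])^2)
  list(dist = unname(dist), se = unname(se))
}

# single-sensor synthetic template, keeps trial generation cheap in tests
one_sensor_modes <- function(centers, widths, heights, sensor = "LDL") {
  out <- list(data.frame(center = centers, width = widths, height = heights))
  names(out) <- sensor
  out
}

# pooled normalized cycles of one channel of one synthetic trial
pipeline_cycles <- function(rec, sensor = "LDL", min_stance_s = 0.1) {
  kin <- preprocess_kinematics(rec$hoof_y)
  onsets <- detect_stance_onsets(kin, min_stance_s = min_stance_s)
  emg <- preprocess_emg(rec$channels[[sensor]])
  normalize_cycles(segment_cycles(emg, onsets))
}
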