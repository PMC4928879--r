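#' Overlap integral of two Gaussian densities
#'
#' Computes `integral N(x; mu1, S1) N(x; mu2, S2) dx`, which equals the
#' Gaussian density of `mu1 - mu2` at zero with covariance `S1 + S2`.
#' Returned in log space, since the overlap underflows for well-separated
#' modes.
#'
#' @param mu1,mu2 length-2 mean vectors.
#' @param Sigma1,Sigma2 positive-definite 2 x 2 covariances.
#' @param log return the log overlap (default `FALSE`).
#' @return the overlap integral (or its log).
#' @export
gaussian_overlap <- function(mu1, Sigma1, mu2, Sigma2, log = FALSE) {
  for (S in list(Sigma1, Sigma2)) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariances must be positive definite")
  }
  R <- chol(Sigma1 + Sigma2)
  d <- as.numeric(mu1) - as.numeric(mu2)
  z <- backsolve(R, d, transpose = TRUE)
  lv <- -log(2 * pi) - sum(base::log(diag(R))) - 0.5 * sum(z^2)
  if (log) lv else exp(lv)
}

# log of sum_ij w1_i w2_j overlap(i, j) over two mixtures, via log-sum-exp.
log_cross_term <- function(P, Q) {
  terms <- numeric(0)
  for (i in seq_len(P$k)) for (j in seq_len(Q$k)) {
    terms <- c(terms,
               log(P$weights[i]) + log(Q$weights[j]) +
                 gaussian_overlap(P$means[i, ], P$covariances[[i]],
                                  Q$means[j, ], Q$covariances[[j]],
                                  log = TRUE))
  }
  mx <- max(terms)
  mx + log(sum(exp(terms - mx)))
}

drop_zero_modes <- function(P) {
  keep <- P$weights > 0
  if (all(keep)) return(P)
  P$weights <- P$weights[keep] / sum(P$weights[keep])
  P$means <- P$means[keep, , drop = FALSE]
  P$covariances <- P$covariances[keep]
  P$k <- sum(keep)
  P
}

#' Cauchy-Schwarz distance between two Gaussian mixtures
#'
#' The Cauchy-Schwarz distance between densities P and Q is
#' `-log( int PQ / sqrt(int P^2 * int Q^2) )`: a symmetric, non-negative
#' divergence that is zero iff P = Q and, unlike the Kullback-Leibler
#' divergence, has a closed form for Gaussian mixtures. All three integrals
#' reduce to double sums of pairwise Gaussian overlaps, accumulated in log
#' space.
#'
#' @param P,Q fitted `gmm_model`s (any objects with `k`, `weights`, `means`,
#'   `covariances`). Zero-weight modes are dropped. Unequal mode counts are
#'   allowed (the formula is well-defined) but produce a warning, since the
#'   distance is designed for models sharing a mode count.
#' @return list with `dist` (non-negative), and the log-space terms
#'   `log_cross`, `log_self_p`, `log_self_q`.
#' @export
cauchy_schwarz_distance <- function(P, Q) {
  P <- drop_zero_modes(P)
  Q <- drop_zero_modes(Q)
  if (P$k != Q$k)
    warning("mode counts differ; the distance remains well-defined")
  log_cross <- log_cross_term(P, Q)
  log_self_p <- log_cross_term(P, P)
  log_self_q <- log_cross_term(Q, Q)
  d <- -(log_cross - 0.5 * (log_self_p + log_self_q))
  list(dist = max(d, 0) + 0, log_cross = log_cross,
       log_self_p = log_self_p, log_self_q = log_self_q)
}

#' Compare peak-based, full-data and noise-baseline mixtures
#'
#' For one group (subject x gait x sensor) with its three fitted models,
#' reports the Cauchy-Schwarz distance of the peak-based model to the
#' full-data model and to the noise baseline, and their ratio. A ratio well
#' above 1 means the full-data model is much closer to the peak-based model
#' than unstructured noise is.
#'
#' @param peak_model,full_model,noise_model fitted `gmm_model`s sharing one
#'   mode count.
#' @return one-row data.frame: `dist_full`, `dist_noise`, `ratio`
#'   (`Inf` when `dist_full` is 0 but `dist_noise` is not; `NA` when both
#'   are 0).
#' @export
model_agreement_report <- function(peak_model, full_model, noise_model) {
  ks <- c(peak_model$k, full_model$k, noise_model$k)
  if (length(unique(ks)) != 1L)
    stop(sprintf("mode counts differ (%s); models are not comparable",
                 paste(ks, collapse = "/")))
  df <- cauchy_schwarz_distance(peak_model, full_model)$dist
  dn <- cauchy_schwarz_distance(peak_model, noise_model)$dist
  ratio <- if (df > 0) dn / df else if (dn > 0) Inf else NA_real_
  data.frame(dist_full = df, dist_noise = dn, ratio = ratio)
}
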