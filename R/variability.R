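#' Cumulative and mean deviations of cycles from a reference curve
#'
#' The cumulative deviation `v` is the sum over cycles of the Euclidean
#' (l2) norm, taken over the 100 frames, of the difference between the
#' reference curve and each cycle. `mean_dev` is `v` divided by the number
#' of cycles, and `MAD` is the mean over cycles of the mean absolute
#' frame-wise deviation.
#'
#' @param cycles normalized cycles: a `cycle_set` or 100-row matrix.
#' @param reference length-100 reference curve; defaults to the mean curve
#'   of `cycles` (intra-subject use). Pass a global mean curve for
#'   inter-subject deviations.
#' @return list with `v`, `mean_dev`, `mad`, `n_cycles`.
#' @export
deviation_stats <- function(cycles, reference = NULL) {
  m <- normalized_matrix(cycles)
  if (is.null(reference)) reference <- rowMeans(m)
  if (length(reference) != 100L) stop("reference must have 100 frames")
  resid <- m - reference
  per_cycle_l2 <- sqrt(colSums(resid^2))
  list(v = sum(per_cycle_l2),
       mean_dev = mean(per_cycle_l2),
       mad = mean(colMeans(abs(resid))),
       n_cycles = ncol(m))
}

#' Variance-to-mean ratio and per-frame coefficient of variation
#'
#' `CV` is the ratio of the frame-averaged variance to the frame-averaged
#' mean of the cycle ensemble. `CV_t` gives the per-frame coefficient of
#' variation (frame standard deviation over frame mean); `meanCV` is its
#' mean over the frames with nonzero mean (excluded frames are counted in
#' `n_excluded`). Sample (m-1) variance is used by default.
#'
#' @param cycles normalized cycles: a `cycle_set` or 100-row matrix with at
#'   least 2 columns.
#' @param population use population (1/m) instead of sample variance
#'   (default `FALSE`).
#' @return list with `cv`, `cv_t` (length 100, `NA` at zero-mean frames),
#'   `mean_cv`, `n_excluded`.
#' @export
variance_to_mean_ratio <- function(cycles, population = FALSE) {
  m <- normalized_matrix(cycles)
  if (ncol(m) < 2L) stop("need at least 2 cycles")
  mu <- rowMeans(m)
  va <- apply(m, 1L, stats::var)
  if (population) va <- va * (ncol(m) - 1L) / ncol(m)
  if (mean(mu) <= 0) stop("undefined ratio: all-zero data")
  cv_t <- ifelse(mu > 0, sqrt(va) / mu, NA_real_)
  list(cv = mean(va) / mean(mu),
       cv_t = cv_t,
       mean_cv = mean(cv_t, na.rm = TRUE),
       n_excluded = sum(is.na(cv_t)))
}

#' Variability ratio of a cycle ensemble
#'
#' The ratio of the pointwise residual variance (deviations from the
#' per-frame means, n(m-1) denominator) to the total variance (deviations
#' from the grand mean, nm-1 denominator). It is 0 when all cycles are
#' identical and approaches 1 for structureless i.i.d. data, so it measures
#' how much of the total variance is *not* explained by the common
#' activation shape.
#'
#' @param cycles normalized cycles: a `cycle_set` or 100-row matrix, >= 2
#'   columns.
#' @return the variability ratio (non-negative scalar).
#' @export
variability_ratio <- function(cycles) {
  m <- normalized_matrix(cycles)
  if (ncol(m) < 2L) stop("need at least 2 cycles")
  n <- nrow(m)
  mm <- ncol(m)
  frame_means <- rowMeans(m)
  num <- sum((m - frame_means)^2) / (n * (mm - 1L))
  den <- sum((m - mean(m))^2) / (n * mm - 1L)
  if (den <= 0) stop("zero total variance: all values identical")
  num / den
}

#' Inter-quartile coefficient of variation per frame
#'
#' Per frame, `(Q3 - Q1) / (Q3 + Q1)` of the cycle values, with quartiles by
#' linear interpolation of the order statistics; the summary `CQV` is the
#' median over frames. Frames where `Q3 + Q1 = 0` are flagged invalid and
#' excluded from the median.
#'
#' @param cycles normalized cycles: a `cycle_set` or 100-row matrix.
#' @return list with `cqv_t` (length 100, `NA` at invalid frames), `cqv`
#'   (median over valid frames), `n_invalid`.
#' @export
cqv <- function(cycles) {
  m <- normalized_matrix(cycles)
  q <- apply(m, 1L, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  s <- q[1L, ] + q[2L, ]
  cqv_t <- ifelse(s > 0, (q[2L, ] - q[1L, ]) / s, NA_real_)
  list(cqv_t = cqv_t,
       cqv = stats::median(cqv_t, na.rm = TRUE),
       n_invalid = sum(is.na(cqv_t)))
}

#' Full intra-subject variability report for one cycle ensemble
#'
#' @param cycles normalized cycles: a `cycle_set` or 100-row matrix.
#' @param reference optional reference curve for the deviation statistics.
#' @return one-row data.frame: `n_cycles`, `v`, `mean_dev`, `mad`, `cv`,
#'   `mean_cv`, `vr`, `cqv`.
#' @export
variability_report <- function(cycles, reference = NULL) {
  m <- normalized_matrix(cycles)
  dev <- deviation_stats(m, reference)
  vm <- variance_to_mean_ratio(m)
  data.frame(n_cycles = ncol(m), v = dev$v, mean_dev = dev$mean_dev,
             mad = dev$mad, cv = vm$cv, mean_cv = vm$mean_cv,
             vr = variability_ratio(m), cqv = cqv(m)$cqv)
}

#' Inter-subject variability from per-subject mean curves
#'
#' Applies the same statistics with the subjects' mean curves in the role of
#' cycles and their global mean curve as the reference.
#'
#' @param mean_curves 100 x n_subjects matrix (or named list) of per-subject
#'   mean curves for one sensor; >= 2 subjects.
#' @return as [variability_report()], plus attribute-free column
#'   `n_subjects` replacing `n_cycles`.
#' @export
inter_subject_stats <- function(mean_curves) {
  if (is.list(mean_curves) && !is.matrix(mean_curves))
    mean_curves <- do.call(cbind, mean_curves)
  m <- as.matrix(mean_curves)
  if (ncol(m) < 2L) stop("need at least 2 subjects")
  out <- variability_report(m, reference = rowMeans(m))
  names(out)[names(out) == "n_cycles"] <- "n_subjects"
  out
}
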