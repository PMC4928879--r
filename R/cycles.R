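#' Detect stance onsets from a hoof's vertical trajectory
#'
#' Ground contacts of the reference hoof show up as the starts of flat
#' episodes of its vertical coordinate. The detector computes the absolute
#' frame-to-frame velocity of the (already filtered, gap-free) trajectory and
#' marks maximal runs where it falls below `vel_threshold` times the 95th
#' percentile of the velocity, provided the run lasts at least `min_stance_s`
#' seconds. Because low-pass filtering smears the touchdown corner
#' symmetrically, each run start is then refined to the frame where the
#' decaying swing velocity crosses half of its local maximum, which for a
#' symmetrically smoothed corner coincides with the true corner.
#'
#' @param hoof_y filtered vertical hoof trajectory ([emg_signal], gap-free).
#' @param min_stance_s minimum stance duration in seconds (default 0.1;
#'   use about 0.2 for walk, 0.1 for trot).
#' @param vel_threshold fraction of the 95th velocity percentile below which
#'   the hoof counts as stationary (default 0.1). Scale-free, so the
#'   trajectory's length unit does not matter.
#' @return integer vector of strictly increasing onset sample indices.
#' @export
detect_stance_onsets <- function(hoof_y, min_stance_s = 0.1,
                                 vel_threshold = 0.1) {
  stopifnot(inherits(hoof_y, "emg_signal"))
  if (anyNA(hoof_y$values)) stop("hoof trajectory contains gaps")
  v <- abs(diff(hoof_y$values))
  scale <- stats::quantile(v, 0.95, names = FALSE)
  if (scale <= .Machine$double.eps * max(abs(hoof_y$values), 1))
    stop("no gait structure: trajectory is (near-)constant")
  flat <- v < vel_threshold * scale
  min_run <- max(1L, ceiling(min_stance_s * hoof_y$rate))
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  onsets <- starts[keep]
  # refine each onset to the half-maximum crossing of the preceding
  # swing-velocity peak
  win <- max(3L, round(0.25 * hoof_y$rate))
  onsets <- vapply(onsets, function(s) {
    w <- max(1L, s - win):max(1L, s - 1L)
    vm_idx <- w[which.max(v[w])]
    vm <- v[vm_idx]
    i <- vm_idx
    while (i < s && v[i] >= 0.5 * vm) i <- i + 1L
    i
  }, integer(1L))
  onsets <- sort(unique(onsets))
  if (length(onsets) < 2L)
    stop("fewer than 2 stance onsets detected; cannot segment cycles")
  as.integer(onsets)
}

#' Cut a channel into gait cycles at stance onsets
#'
#' Consecutive onset pairs delimit one complete cycle each. Samples before
#' the first onset and after the last onset belong to incomplete cycles and
#' are flagged but excluded from analysis. Onsets are given on the kinematic
#' time base and mapped to the channel's time base via the rate ratio.
#'
#' @param channel an [emg_signal] (typically preprocessed EMG).
#' @param onsets strictly increasing onset indices from
#'   [detect_stance_onsets()].
#' @param onset_rate sampling rate (Hz) of the stream the onsets refer to;
#'   defaults to `channel$rate` (the identity mapping when both streams run
#'   at the same rate after preprocessing).
#' @return A `cycle_set`: list with `cycles` (list of numeric vectors, one per
#'   complete cycle), `durations` (seconds), `normalized` (filled by
#'   [normalize_cycles()]), `onsets` (channel time base), `rate`, and
#'   `incomplete` (head/tail sample counts trimmed).
#' @export
segment_cycles <- function(channel, onsets, onset_rate = channel$rate) {
  stopifnot(inherits(channel, "emg_signal"))
  onsets <- as.integer(onsets)
  if (length(onsets) < 2L) stop("need at least 2 onsets to form a cycle")
  if (any(diff(onsets) <= 0L)) stop("onsets must be strictly increasing")
  idx <- as.integer(round((onsets - 1L) * channel$rate / onset_rate)) + 1L
  idx <- pmin(pmax(idx, 1L), channel$n)
  idx <- unique(idx)
  if (length(idx) < 2L) stop("onsets collapse onto fewer than 2 samples")
  m <- length(idx) - 1L
  cycles <- vector("list", m)
  for (j in seq_len(m)) cycles[[j]] <- channel$values[idx[j]:(idx[j + 1L] - 1L)]
  structure(list(
    cycles = cycles,
    durations = diff(idx) / channel$rate,
    normalized = NULL,
    onsets = idx,
    rate = channel$rate,
    incomplete = c(head = idx[1L] - 1L, tail = channel$n - idx[m + 1L] + 1L)
  ), class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d complete cycles @ %g Hz, mean duration %.3f s\n",
              length(x$cycles), x$rate, mean(x$durations)))
  invisible(x)
}

#' Map one cycle onto the 100-point cycle-percent scale in [0, 1]
#'
#' Time-normalizes by linear interpolation onto 100 equally spaced points
#' (both endpoints included) and amplitude-normalizes per cycle so the
#' minimum maps to 0 and the maximum to 1. A constant (zero-range) cycle maps
#' to 100 zeros by convention, since rectified EMG can be silent.
#'
#' @param cycle numeric vector, length >= 2.
#' @return numeric vector of length 100 with values in [0, 1].
#' @export
normalize_cycle <- function(cycle) {
  cycle <- as.numeric(cycle)
  if (length(cycle) < 2L) stop("cycle must have at least 2 samples")
  y <- stats::approx(seq_along(cycle), cycle, n = 100L)$y
  rng <- range(y)
  if (rng[2L] - rng[1L] <= 0) return(rep(0, 100L))
  (y - rng[1L]) / (rng[2L] - rng[1L])
}

#' Normalize every cycle of a cycle set
#'
#' @param cycleset a `cycle_set` from [segment_cycles()].
#' @return the `cycle_set` with `normalized` filled: a 100-row matrix, one
#'   column per complete cycle.
#' @export
normalize_cycles <- function(cycleset) {
  stopifnot(inherits(cycleset, "cycle_set"))
  cycleset$normalized <- vapply(cycleset$cycles, normalize_cycle, numeric(100L))
  cycleset
}

#' Pointwise mean and median reference curves
#'
#' The mean curve over all normalized cycles is the reference used to choose
#' the number of mixture modes and to measure intra-subject deviations; the
#' median curve is reported alongside it.
#'
#' @param cycleset a normalized `cycle_set`, or a 100-row matrix of
#'   normalized cycles (one column per cycle).
#' @return list with `mean_curve`, `median_curve` (length-100 numerics) and
#'   `n_cycles`.
#' @export
reference_curves <- function(cycleset) {
  m <- normalized_matrix(cycleset)
  list(mean_curve = rowMeans(m),
       median_curve = apply(m, 1L, stats::median),
       n_cycles = ncol(m))
}

# Accept either a normalized cycle_set or a bare 100 x m matrix.
normalized_matrix <- function(x) {
  if (inherits(x, "cycle_set")) {
    if (is.null(x$normalized)) x <- normalize_cycles(x)
    m <- x$normalized
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) != 100L) stop("normalized cycles must have exactly 100 frames")
  if (ncol(m) < 1L) stop("no cycles available")
  m
}

#' Per-cycle duration and amplitude range
#'
#' @param cycleset a `cycle_set`.
#' @return data.frame with one row per complete cycle: `cycle_index`,
#'   `duration_s`, `value_range`.
#' @export
cycle_characteristics <- function(cycleset) {
  stopifnot(inherits(cycleset, "cycle_set"))
  data.frame(
    cycle_index = seq_along(cycleset$cycles),
    duration_s = cycleset$durations,
    value_range = vapply(cycleset$cycles,
                         function(c) diff(range(c)), numeric(1L))
  )
}
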