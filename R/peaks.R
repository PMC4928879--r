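#' Find local maxima of a normalized cycle or reference curve
#'
#' A frame t is a candidate peak when `curve[t] > curve[t-1]` and
#' `curve[t] >= curve[t+1]` (the leftmost frame of a flat maximum wins).
#' Candidates whose topographic prominence falls below
#' `min_prominence * (max - min)` of the curve are discarded, and among
#' candidates closer than `min_separation` frames the higher one is kept.
#' The combination suppresses noise maxima while retaining every recurring
#' activation burst.
#'
#' @param curve numeric vector of length 100 (cycle-percent scale).
#' @param min_prominence minimum prominence as a fraction of the curve's
#'   range (default 0.05).
#' @param min_separation minimum frame gap between reported peaks
#'   (default 3).
#' @return data.frame with columns `t` (frame, strictly increasing) and `a`
#'   (amplitude); zero rows when no peak passes the filters.
#' @export
find_peaks <- function(curve, min_prominence = 0.05, min_separation = 3L) {
  curve <- as.numeric(curve)
  n <- length(curve)
  if (n != 100L) stop("curve must have exactly 100 frames")
  rng <- diff(range(curve))
  empty <- data.frame(t = integer(0), a = numeric(0))
  if (rng <= 0) return(empty)
  interior <- 2:(n - 1L)
  cand <- interior[curve[interior] > curve[interior - 1L] &
                   curve[interior] >= curve[interior + 1L]]
  if (length(cand) == 0L) return(empty)
  prom <- vapply(cand, peak_prominence, numeric(1L), curve = curve)
  cand <- cand[prom >= min_prominence * rng]
  if (length(cand) == 0L) return(empty)
  # greedy suppression: highest first (earlier frame breaks ties)
  ord <- order(-curve[cand], cand)
  kept <- integer(0)
  for (t in cand[ord]) {
    if (all(abs(kept - t) >= min_separation)) kept <- c(kept, t)
  }
  kept <- sort(kept)
  data.frame(t = as.integer(kept), a = curve[kept])
}

# Topographic prominence of the candidate at frame t: walk outwards on each
# side until a strictly higher sample (or the edge) is met, track the lowest
# point passed; prominence is the drop to the higher of the two side minima.
peak_prominence <- function(t, curve) {
  h <- curve[t]
  left_min <- h
  i <- t - 1L
  while (i >= 1L && curve[i] <= h) {
    if (curve[i] < left_min) left_min <- curve[i]
    i <- i - 1L
  }
  right_min <- h
  i <- t + 1L
  while (i <= length(curve) && curve[i] <= h) {
    if (curve[i] < right_min) right_min <- curve[i]
    i <- i + 1L
  }
  h - max(left_min, right_min)
}

#' Collect the peak cloud of a cycle set
#'
#' Unions the local maxima of every normalized cycle of one sensor into the
#' N x 2 point set in cycle-percent x amplitude space that the mixture model
#' is fitted to.
#'
#' @param cycleset a normalized `cycle_set` or 100-row matrix.
#' @inheritParams find_peaks
#' @return A `peak_cloud`: list with `X` (N x 2 matrix, columns `t`, `a`)
#'   and `cycle` (originating cycle index per row).
#' @export
extract_peak_cloud <- function(cycleset, min_prominence = 0.05,
                               min_separation = 3L) {
  m <- normalized_matrix(cycleset)
  per_cycle <- lapply(seq_len(ncol(m)), function(j) {
    p <- find_peaks(m[, j], min_prominence, min_separation)
    if (nrow(p)) cbind(t = p$t, a = p$a, cycle = j)
  })
  rows <- do.call(rbind, per_cycle)
  if (is.null(rows) || nrow(rows) == 0L)
    stop("no peaks: every cycle is flat or below the prominence threshold")
  structure(list(X = rows[, c("t", "a"), drop = FALSE],
                 cycle = as.integer(rows[, "cycle"])),
            class = "peak_cloud")
}

#' @export
print.peak_cloud <- function(x, ...) {
  cat(sprintf("<peak_cloud> %d peaks from %d cycles\n",
              nrow(x$X), length(unique(x$cycle))))
  invisible(x)
}

#' Circular distance on the 100-frame cycle
#'
#' Frames live on a cycle, so the shortest route may wrap around the
#' 100/1 boundary: the distance between frames 1 and 100 is 1, not 99.
#'
#' @param t1,t2 frames in [1, 100] (vectorized).
#' @param period cycle length in frames (default 100).
#' @return `min(|t1 - t2|, period - |t1 - t2|)`, in [0, period/2].
#' @export
circular_distance <- function(t1, t2, period = 100) {
  if (any(t1 < 1 | t1 > period) || any(t2 < 1 | t2 > period))
    stop(sprintf("frames must lie in [1, %d]", period))
  d <- abs(t1 - t2)
  pmin(d, period - d)
}

#' Histogram of two-highest-peak distances across subjects
#'
#' For each subject, every cycle with at least two detected peaks contributes
#' the circular distance between its two highest peaks; the per-subject
#' statistic is the mean of these distances, binned into the half-open
#' intervals [10,20), [20,30), [30,40), [40,50). Subjects with no two-peak
#' cycle are excluded with a warning; subjects whose mean falls outside all
#' bins are not counted (so counts may sum to less than the cohort size).
#'
#' @param cyclesets named list (by subject id) of normalized `cycle_set`s for
#'   one sensor and gait.
#' @param breaks bin edges (default `c(10, 20, 30, 40, 50)`).
#' @inheritParams find_peaks
#' @return list with `counts` (named integer vector per bin) and
#'   `subject_means` (named numeric vector of per-subject mean distances).
#' @export
two_peak_distance_histogram <- function(cyclesets,
                                        breaks = c(10, 20, 30, 40, 50),
                                        min_prominence = 0.05,
                                        min_separation = 3L) {
  stopifnot(is.list(cyclesets), length(cyclesets) >= 1L)
  means <- vapply(cyclesets, function(cs) {
    m <- normalized_matrix(cs)
    d <- vapply(seq_len(ncol(m)), function(j) {
      p <- find_peaks(m[, j], min_prominence, min_separation)
      if (nrow(p) < 2L) return(NA_real_)
      top2 <- p[order(-p$a, p$t)[1:2], ]
      circular_distance(top2$t[1L], top2$t[2L])
    }, numeric(1L))
    d <- d[!is.na(d)]
    if (length(d) == 0L) NA_real_ else mean(d)
  }, numeric(1L))
  if (anyNA(means)) {
    warning(sprintf("excluded subject(s) with no two-peak cycle: %s",
                    paste(names(means)[is.na(means)], collapse = ", ")))
    means <- means[!is.na(means)]
  }
  nb <- length(breaks) - 1L
  counts <- integer(nb)
  names(counts) <- paste0(breaks[-length(breaks)], "-", breaks[-1L])
  for (x in means) {
    b <- which(x >= breaks[-length(breaks)] & x < breaks[-1L])
    if (length(b) == 1L) counts[b] <- counts[b] + 1L
  }
  list(counts = counts, subject_means = means)
}
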