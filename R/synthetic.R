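#' Ground-truth description of a synthetic locomotion trial
#'
#' Describes one synthetic trial of cyclic muscle activation with
#' synchronized hoof kinematics. Per sensor, each gait cycle's activation
#' envelope is a sum of Gaussian bumps at known cycle-percent locations plus
#' smooth, cycle-local Gaussian activation noise (drawn at knots every 2.5
#' cycle-percent and interpolated), which mimics the cycle-to-cycle
#' variability and the many secondary local maxima of real sEMG envelopes. The
#' emitted EMG is zero-mean noise amplitude-modulated by that envelope (so
#' rectification and low-pass filtering recover it), plus a small additive
#' instrument-noise floor.
#' The hoof's vertical trajectory has a flat stance plateau starting at each
#' cycle onset and a smooth swing arc in between. Defaults mirror a
#' treadmill protocol: 10-second trials, EMG at 4000 Hz, kinematics at
#' 120 Hz, and gait-typical cycle durations and stance fractions (walk:
#' 1.0 s cycles, 60 % stance; trot: 0.66 s cycles, 40 % stance).
#'
#' @param gait `"walk"` or `"trot"`.
#' @param modes named list (by sensor label) of data.frames with columns
#'   `center` (frame 1-100), `width` (frames), `height` (0-1]. Default: a
#'   two-burst pattern on every sensor.
#' @param trial_s trial length in seconds (default 10).
#' @param cycle_duration_s mean cycle duration; default by gait.
#' @param duration_jitter multiplicative log-normal jitter of cycle
#'   durations (sd on the log scale, default 0.05).
#' @param stance_fraction stance share of the cycle; default by gait.
#' @param noise_sd standard deviation of the smooth per-cycle activation
#'   noise, on the envelope's unit scale (default 0.25).
#' @param emg_rate,kin_rate sampling rates in Hz (defaults 4000 / 120).
#' @param seed integer seed; the same seed reproduces identical trials.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(gait = c("trot", "walk"), modes = NULL,
                            trial_s = 10, cycle_duration_s = NULL,
                            duration_jitter = 0.05, stance_fraction = NULL,
                            noise_sd = 0.25, emg_rate = 4000, kin_rate = 120,
                            seed = 1L) {
  gait <- match.arg(gait)
  if (is.null(cycle_duration_s))
    cycle_duration_s <- if (gait == "trot") 0.66 else 1.0
  if (is.null(stance_fraction))
    stance_fraction <- if (gait == "trot") 0.40 else 0.60
  if (is.null(modes)) modes <- default_sensor_modes()
  for (s in names(modes)) {
    md <- modes[[s]]
    if (any(md$center < 1 | md$center > 100))
      stop(sprintf("sensor %s: mode centers must lie in [1, 100]", s))
    if (any(md$height <= 0 | md$height > 1))
      stop(sprintf("sensor %s: mode heights must lie in (0, 1]", s))
  }
  structure(list(gait = gait, modes = modes, trial_s = trial_s,
                 cycle_duration_s = cycle_duration_s,
                 duration_jitter = duration_jitter,
                 stance_fraction = stance_fraction, noise_sd = noise_sd,
                 emg_rate = emg_rate, kin_rate = kin_rate,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Per-sensor activation templates: every sensor shares a dominant burst
# pair (the two-peak pattern seen in mean activation curves) and adds
# sensor-specific minor bursts, giving the uneven multi-burst cycles that
# real sEMG envelopes show.
default_sensor_modes <- function(centers = c(25, 65), widths = c(4, 5),
                                 heights = c(1, 0.75)) {
  dominant <- data.frame(center = centers, width = widths, height = heights)
  minor <- list(
    LDL  = data.frame(center = 48, width = 5, height = 0.3),
    LDR  = data.frame(center = 50, width = 5, height = 0.3),
    GML1 = data.frame(center = c(8, 85), width = c(3, 5),
                      height = c(0.25, 0.35)),
    GML2 = data.frame(center = 90, width = 5, height = 0.4),
    GML3 = data.frame(center = c(12, 80), width = c(4, 5),
                      height = c(0.3, 0.3)),
    GMR1 = data.frame(center = c(10, 88), width = c(3, 5),
                      height = c(0.3, 0.3)),
    GMR2 = data.frame(center = 82, width = 6, height = 0.4),
    GMR3 = data.frame(center = c(5, 78), width = c(3, 6),
                      height = c(0.25, 0.35)))
  out <- lapply(ALL_SENSORS, function(s) rbind(dominant, minor[[s]]))
  names(out) <- ALL_SENSORS
  out
}

# Activation envelope at cycle phase phi in [0,1) (vectorized, wraps
# circularly). Phase maps to the frame axis as f = 100*phi + 1, so a mode
# centered at frame c peaks at frame c of the normalized cycle.
envelope_at <- function(phi, modes, baseline = 0.1) {
  f <- phi * 100 + 1
  env <- rep(baseline, length(f))
  for (i in seq_len(nrow(modes))) {
    for (shift in c(-100, 0, 100)) {
      env <- env + modes$height[i] *
        exp(-((f - modes$center[i] + shift)^2) / (2 * modes$width[i]^2))
    }
  }
  env
}

#' Generate one synthetic trial
#'
#' @param truth a [synthetic_truth()].
#' @return A `raw_recording`: list with `channels` (named list of raw EMG
#'   [emg_signal]s at `emg_rate`), `hoof_y` ([emg_signal] at `kin_rate`),
#'   and `truth` augmented with the realized `onsets_kin` (kinematic sample
#'   indices), `cycle_durations_s` and `n_cycles`.
#' @export
generate_trial <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(truth$seed)
  s <- truth$duration_jitter
  # draw enough jittered cycles to cover the trial, starting mid-swing so
  # the first and last cycles are incomplete
  durations <- numeric(0)
  lead_in <- 0.4 * truth$cycle_duration_s
  total <- lead_in
  while (total < truth$trial_s + truth$cycle_duration_s) {
    d <- truth$cycle_duration_s *
      stats::rlnorm(1L, meanlog = -s^2 / 2, sdlog = s)
    durations <- c(durations, d)
    total <- total + d
  }
  onset_times <- lead_in + cumsum(c(0, durations[-length(durations)]))
  phase_of <- function(t) {
    # cycle phase in [0,1) and cycle index at absolute time t; before the
    # first onset the tail of a virtual previous cycle (index 0) is used,
    # after the last full cycle a virtual next one
    ph <- numeric(length(t))
    cyc <- integer(length(t))
    prev_dur <- truth$cycle_duration_s
    pre <- t < onset_times[1L]
    ph[pre] <- 1 - (onset_times[1L] - t[pre]) / prev_dur
    cyc[pre] <- 0L
    for (j in seq_along(onset_times)) {
      d <- durations[j]
      endt <- onset_times[j] + d
      in_c <- t >= onset_times[j] & t < endt
      ph[in_c] <- (t[in_c] - onset_times[j]) / d
      cyc[in_c] <- j
    }
    last_end <- onset_times[length(onset_times)] +
      durations[length(durations)]
    after <- t >= last_end
    ph[after] <- (t[after] - last_end) / truth$cycle_duration_s
    cyc[after] <- length(onset_times) + 1L
    list(phase = ph - floor(ph), cycle = cyc)
  }
  n_virtual <- length(onset_times) + 2L  # incl. virtual head/tail cycles
  # hoof vertical trajectory at kin_rate: flat stance, sinusoidal swing arc
  n_kin <- round(truth$trial_s * truth$kin_rate)
  t_kin <- (seq_len(n_kin) - 1) / truth$kin_rate
  ph_kin <- phase_of(t_kin)$phase
  sf <- truth$stance_fraction
  swing <- ph_kin >= sf
  hoof <- rep(0, n_kin)
  hoof[swing] <- 60 * sin(pi * (ph_kin[swing] - sf) / (1 - sf))
  hoof <- hoof + stats::rnorm(n_kin, sd = 0.3)
  # EMG channels at emg_rate: the activation envelope (bumps + smooth
  # per-cycle knot noise) amplitude-modulates a white carrier
  n_emg <- round(truth$trial_s * truth$emg_rate)
  t_emg <- (seq_len(n_emg) - 1) / truth$emg_rate
  pe <- phase_of(t_emg)
  knot_pos <- pe$phase * 40          # 41 knots, every 2.5 cycle-percent
  lo <- pmin(floor(knot_pos), 39)
  frac <- knot_pos - lo
  row <- pe$cycle + 1L
  channels <- lapply(truth$modes, function(md) {
    knots <- matrix(stats::rnorm(n_virtual * 41L, sd = truth$noise_sd),
                    n_virtual, 41L)
    act_noise <- knots[cbind(row, lo + 1L)] * (1 - frac) +
      knots[cbind(row, lo + 2L)] * frac
    env <- pmax(envelope_at(pe$phase, md) + act_noise, 0)
    x <- env * stats::rnorm(n_emg) + 0.02 * stats::rnorm(n_emg)
    emg_signal(x, truth$emg_rate)
  })
  truth$onsets_kin <- as.integer(round(onset_times * truth$kin_rate)) + 1L
  truth$onsets_kin <- truth$onsets_kin[truth$onsets_kin <= n_kin]
  truth$cycle_durations_s <- durations[seq_len(length(truth$onsets_kin) - 1L)]
  truth$n_cycles <- length(truth$onsets_kin) - 1L
  structure(list(channels = channels,
                 hoof_y = emg_signal(hoof, truth$kin_rate),
                 truth = truth),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d EMG channel(s) @ %g Hz, hoof_y @ %g Hz\n",
              length(x$channels),
              x$channels[[1L]]$rate, x$hoof_y$rate))
  invisible(x)
}

#' Generate a synthetic cohort with two planted subject groups
#'
#' Emulates a 14-subject, two-gait treadmill study with several trials per
#' subject and gait. Subjects are planted in two groups that differ in the
#' circular gap between their two activation bursts (`group_gaps`, frames);
#' within a group, per-subject center shifts of sd `between_subject_sd`
#' frames create realistic inter-subject variability. The planted partition
#' is the ground truth for clustering-recovery checks.
#'
#' @param n_subjects number of subjects (default 14).
#' @param gaits gaits to simulate (default both).
#' @param trials_per_gait trials per subject and gait (default 3).
#' @param group_gaps two-burst circular gaps (frames) of the planted groups
#'   (default `c(20, 45)`).
#' @param between_subject_sd sd of per-subject mode-center shifts in frames
#'   (default 1.5).
#' @param noise_sd activation noise level (default 0.25).
#' @param seed master seed; all per-trial seeds derive from it.
#' @param ... further arguments to [synthetic_truth()].
#' @return A `synthetic_cohort`: list with `trials` (list of
#'   `raw_recording`s, each carrying `subject`, `gait`, `trial` in its
#'   truth), `subjects` (ids), `group` (named planted group memberships).
#' @export
generate_cohort <- function(n_subjects = 14L, gaits = c("walk", "trot"),
                            trials_per_gait = 3L, group_gaps = c(20, 45),
                            between_subject_sd = 1.5, noise_sd = 0.25,
                            seed = 1L, ...) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  group <- rep(1:2, length.out = n_subjects)
  names(group) <- subjects
  trials <- list()
  for (i in seq_len(n_subjects)) {
    gap <- group_gaps[group[i]]
    shift <- stats::rnorm(1L, sd = between_subject_sd)
    first <- 25 + shift
    centers <- c(first, first + gap)
    centers <- ((centers - 1) %% 100) + 1
    modes <- default_sensor_modes(centers = centers)
    for (g in gaits) {
      for (tr in seq_len(trials_per_gait)) {
        trial_seed <- (seed * 10007L + i * 211L +
                         match(g, c("walk", "trot")) * 53L + tr) %% 2147483647L
        tru <- synthetic_truth(gait = g, modes = modes, noise_sd = noise_sd,
                               seed = trial_seed, ...)
        rec <- generate_trial(tru)
        rec$truth$subject <- subjects[i]
        rec$truth$trial <- tr
        rec$truth$group <- unname(group[i])
        trials[[length(trials) + 1L]] <- rec
      }
    }
  }
  structure(list(trials = trials, subjects = subjects, group = group,
                 gaits = gaits, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d trials (%s)\n",
              length(x$subjects), length(x$trials),
              paste(x$gaits, collapse = ", ")))
  invisible(x)
}
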