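#' Default pipeline configuration
#'
#' All tunable parameters of the processing chain in one validated document.
#' Keys: `emg` (target_rate_hz 120, cutoff_hz 20, order 4), `kin`
#' (cutoff_hz 10, order 4), `zero_phase`, `stance` (vel_threshold 0.1,
#' min_stance_s per gait: walk 0.2, trot 0.1), `peaks` (min_prominence 0.05,
#' min_separation 3), `em` (tol 1e-6, max_iter 500, covariance "full",
#' epsilon 1e-6), `kmeans` (n_restarts 10), `cluster` (n_clusters 4),
#' `seed`.
#'
#' @param ... overrides as nested lists, e.g. `emg = list(cutoff_hz = 25)`.
#' @return validated configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    emg = list(target_rate_hz = 120, cutoff_hz = 20, order = 4L),
    kin = list(cutoff_hz = 10, order = 4L),
    zero_phase = TRUE,
    stance = list(vel_threshold = 0.1,
                  min_stance_s = list(walk = 0.2, trot = 0.1)),
    peaks = list(min_prominence = 0.05, min_separation = 3L),
    em = list(tol = 1e-6, max_iter = 500L, covariance = "full",
              epsilon = 1e-6),
    kmeans = list(n_restarts = 10L),
    cluster = list(n_clusters = 4L),
    seed = 1L
  )
  overrides <- list(...)
  merge_cfg <- function(base, over, path = "") {
    for (nm in names(over)) {
      key <- if (nzchar(path)) paste0(path, ".", nm) else nm
      if (!nm %in% names(base))
        stop(sprintf("unknown configuration key: %s", key))
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]], key)
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  merge_cfg(cfg, overrides)
}

mad_about_mean <- function(x) mean(abs(x - mean(x)))

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt) %% 2147483647)
}

#' Run the whole analysis pipeline
#'
#' Preprocesses every trial, detects stance onsets from the hoof trajectory,
#' segments and normalizes gait cycles, pools cycles per subject, gait and
#' sensor, fits the peak-based, full-data and noise-baseline mixtures per
#' group, computes Cauchy-Schwarz model distances, intra- and inter-subject
#' variability, the two-peak distance histograms, and single-linkage subject
#' trees per muscle group; writes every artifact plus the report tables to
#' `out_dir`. Fully deterministic for a fixed config.
#'
#' @param input a `synthetic_cohort` from [generate_cohort()], a manifest
#'   path, or a [read_manifest()] data.frame.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); `NULL` skips writing.
#' @return A `pipeline_result`: list with `cycle_summary`, `cycles` (pooled
#'   normalized matrices by subject/gait/sensor), `fits`, `distances`,
#'   `variability_intra`, `variability_inter`, `histograms`, `trees`,
#'   `partitions`, `tables`, `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  trials <- pipeline_trials(input)
  # ---- stage: preprocessing and cycle detection, pooled per group --------
  cycles <- list()   # cycles[[gait]][[subject]][[sensor]] -> 100 x m matrix
  durations <- list()
  counts <- list()
  for (rec in trials) {
    meta <- rec$truth
    subject <- if (!is.null(meta$subject)) meta$subject else meta$subject_id
    gait <- meta$gait
    res <- tryCatch(
      process_trial(rec, gait, config),
      error = function(e) stop(sprintf("[segment %s/%s/trial %s] %s",
                                       subject, gait, meta$trial, conditionMessage(e)),
                               call. = FALSE))
    counts[[gait]][[subject]] <-
      c(counts[[gait]][[subject]], res$n_cycles)
    durations[[gait]][[subject]] <-
      c(durations[[gait]][[subject]], res$durations)
    for (sensor in names(res$normalized)) {
      cycles[[gait]][[subject]][[sensor]] <-
        cbind(cycles[[gait]][[subject]][[sensor]], res$normalized[[sensor]])
    }
  }
  cycle_summary <- cycle_bookkeeping(counts)
  # ---- stage: per-group model fitting and comparison ---------------------
  fits <- list()
  distances <- list()
  vari <- list()
  gi <- 0L
  for (gait in names(cycles)) {
    for (subject in names(cycles[[gait]])) {
      for (sensor in names(cycles[[gait]][[subject]])) {
        gi <- gi + 1L
        m <- cycles[[gait]][[subject]][[sensor]]
        gid <- paste(subject, gait, sensor, sep = "/")
        f <- tryCatch(
          fit_group(m, config, derive_seed(config$seed, gi)),
          error = function(e) stop(sprintf("[fit %s] %s", gid,
                                           conditionMessage(e)), call. = FALSE))
        fits[[gait]][[subject]][[sensor]] <- f
        distances[[length(distances) + 1L]] <- cbind(
          data.frame(subject = subject, gait = gait, sensor = sensor,
                     n_modes = f$k),
          f$agreement)
        vari[[length(vari) + 1L]] <- cbind(
          data.frame(subject = subject, gait = gait, sensor = sensor),
          variability_report(m))
      }
    }
  }
  distances <- do.call(rbind, distances)
  variability_intra <- do.call(rbind, vari)
  # ---- stage: inter-subject statistics and histograms --------------------
  variability_inter <- list()
  histograms <- list()
  inter_dev <- list()
  for (gait in names(cycles)) {
    subjects <- names(cycles[[gait]])
    for (sensor in ALL_SENSORS) {
      mean_curves <- vapply(subjects, function(s)
        fits[[gait]][[s]][[sensor]]$reference$mean_curve, numeric(100L))
      if (length(subjects) >= 2L) {
        variability_inter[[length(variability_inter) + 1L]] <- cbind(
          data.frame(gait = gait, sensor = sensor),
          inter_subject_stats(mean_curves))
      }
      global_mean <- rowMeans(mean_curves)
      for (s in subjects) {
        d <- deviation_stats(cycles[[gait]][[s]][[sensor]], global_mean)
        inter_dev[[length(inter_dev) + 1L]] <- data.frame(
          gait = gait, sensor = sensor, subject = s,
          mean_dev = d$mean_dev, mad = d$mad)
      }
      sets <- lapply(subjects, function(s) cycles[[gait]][[s]][[sensor]])
      names(sets) <- subjects
      histograms[[gait]][[sensor]] <- suppressWarnings(
        two_peak_distance_histogram(
          sets, min_prominence = config$peaks$min_prominence,
          min_separation = config$peaks$min_separation))
    }
  }
  variability_inter <- do.call(rbind, variability_inter)
  inter_dev <- do.call(rbind, inter_dev)
  # ---- stage: subject exploration per muscle group -----------------------
  trees <- list()
  partitions <- list()
  for (gait in names(cycles)) {
    subjects <- names(cycles[[gait]])
    if (length(subjects) < 2L) next
    for (mg in c("LD", "GM")) {
      rankings <- lapply(subjects, function(s) {
        out <- lapply(sensor_labels(mg), function(sen) {
          f <- fits[[gait]][[s]][[sen]]
          list(ranking = f$ranking, n_modes = f$k)
        })
        names(out) <- sensor_labels(mg)
        out
      })
      names(rankings) <- subjects
      feat <- build_features(rankings, muscle_group = mg)
      tree <- single_linkage(dissimilarity_matrix(feat))
      kcut <- min(config$cluster$n_clusters, length(subjects))
      trees[[gait]][[mg]] <- tree
      partitions[[gait]][[mg]] <- cut_tree(tree, kcut)
    }
  }
  tables <- report_tables(list(
    cycle_summary = cycle_summary, distances = distances,
    variability_intra = variability_intra,
    variability_inter = variability_inter, inter_dev = inter_dev,
    histograms = histograms, fits = fits))
  result <- structure(list(
    cycle_summary = cycle_summary, cycles = cycles, fits = fits,
    distances = distances, variability_intra = variability_intra,
    variability_inter = variability_inter, inter_dev = inter_dev,
    histograms = histograms, trees = trees, partitions = partitions,
    tables = tables, config = config), class = "pipeline_result")
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$cycle_summary)
  invisible(x)
}

pipeline_trials <- function(input) {
  if (inherits(input, "synthetic_cohort")) return(input$trials)
  if (is.character(input)) input <- read_manifest(input)
  if (is.data.frame(input))
    return(lapply(seq_len(nrow(input)), function(i) read_trial(input[i, ])))
  if (is.list(input)) return(input)
  stop("input must be a cohort, manifest path/data.frame, or trial list")
}

process_trial <- function(rec, gait, config) {
  kin <- preprocess_kinematics(rec$hoof_y, cutoff = config$kin$cutoff_hz,
                               order = config$kin$order,
                               zero_phase = config$zero_phase)
  min_stance <- config$stance$min_stance_s[[gait]]
  onsets <- detect_stance_onsets(kin, min_stance_s = min_stance,
                                 vel_threshold = config$stance$vel_threshold)
  normalized <- list()
  durations <- NULL
  for (sensor in names(rec$channels)) {
    emg <- preprocess_emg(rec$channels[[sensor]],
                          target_rate = config$emg$target_rate_hz,
                          cutoff = config$emg$cutoff_hz,
                          order = config$emg$order,
                          zero_phase = config$zero_phase)
    cs <- segment_cycles(emg, onsets, onset_rate = kin$rate)
    cs <- normalize_cycles(cs)
    normalized[[sensor]] <- cs$normalized
    durations <- cs$durations
  }
  list(normalized = normalized, durations = durations,
       n_cycles = length(durations))
}

fit_group <- function(m, config, seed) {
  pk <- fit_peak_model(m, seed = seed,
                       tol = config$em$tol, max_iter = config$em$max_iter,
                       covariance = config$em$covariance,
                       epsilon = config$em$epsilon)
  full <- fit_full_data_model(m, pk$init, tol = config$em$tol,
                              max_iter = config$em$max_iter,
                              covariance = config$em$covariance,
                              epsilon = config$em$epsilon)
  noise <- fit_noise_baseline(n_cycles = ncol(m), init = pk$init,
                              seed = seed + 1L, tol = config$em$tol,
                              max_iter = config$em$max_iter,
                              covariance = config$em$covariance,
                              epsilon = config$em$epsilon)
  list(k = pk$k, model = pk$model, full_model = full, noise_model = noise,
       init = pk$init, reference = pk$reference,
       ranking = rank_modes(pk$model, pk$reference),
       agreement = model_agreement_report(pk$model, full, noise))
}

cycle_bookkeeping <- function(counts) {
  rows <- lapply(names(counts), function(gait) {
    per_subject <- vapply(counts[[gait]], sum, numeric(1L))
    trials_per_subject <- vapply(counts[[gait]], length, numeric(1L))
    data.frame(gait = gait,
               n_trials = sum(trials_per_subject),
               trials_per_subject_mean = mean(trials_per_subject),
               trials_per_subject_mad = mad_about_mean(trials_per_subject),
               total_cycles = sum(per_subject),
               cycles_per_subject_mean = mean(per_subject),
               cycles_per_subject_mad = mad_about_mean(per_subject))
  })
  do.call(rbind, rows)
}

#' Assemble the report tables
#'
#' Builds the standard result tables from pipeline artifacts: per-gait
#' intra-subject deviations (sensors x subjects), the variability summary
#' (medians over subjects of VR, CV, meanCV, CQV per sensor), per-gait
#' deviations of each subject's cycles from the global mean curve, the
#' Cauchy-Schwarz distance table with per-row/column medians and MADs,
#' per-subject mode-count ranges, and the two-peak distance histograms.
#'
#' @param artifacts list with `cycle_summary`, `distances`,
#'   `variability_intra`, `variability_inter`, `inter_dev`, `histograms`,
#'   `fits` (as produced inside [run_pipeline()]).
#' @return named list of data.frames.
#' @export
report_tables <- function(artifacts) {
  need <- c("cycle_summary", "distances", "variability_intra",
            "variability_inter", "inter_dev", "histograms", "fits")
  miss <- setdiff(need, names(artifacts))
  if (length(miss))
    stop(sprintf("missing artifact(s) %s: report tables blocked",
                 paste(miss, collapse = ", ")))
  vi <- artifacts$variability_intra
  tables <- list(cycle_summary = artifacts$cycle_summary)
  for (gait in unique(vi$gait)) {
    sub <- vi[vi$gait == gait, ]
    tables[[paste0("intra_deviation_", gait)]] <-
      wide_table(sub, "mean_dev", "mad")
    agg <- stats::aggregate(sub[c("vr", "cv", "mean_cv", "cqv")],
                            by = list(sensor = sub$sensor), stats::median)
    names(agg) <- c("sensor", "VR_median", "CV_median", "meanCV_median",
                    "CQV_median")
    tables[[paste0("variability_summary_", gait)]] <-
      agg[match(intersect(ALL_SENSORS, agg$sensor), agg$sensor), ]
    idv <- artifacts$inter_dev[artifacts$inter_dev$gait == gait, ]
    tables[[paste0("inter_deviation_", gait)]] <-
      wide_table(idv, "mean_dev", "mad")
    dd <- artifacts$distances[artifacts$distances$gait == gait, ]
    tables[[paste0("cs_distance_", gait)]] <- cs_table(dd)
    fits_g <- artifacts$fits[[gait]]
    tables[[paste0("mode_counts_", gait)]] <- data.frame(
      subject = names(fits_g),
      max_modes = vapply(fits_g, function(f)
        max(vapply(f, `[[`, numeric(1L), "k")), numeric(1L)),
      min_modes = vapply(fits_g, function(f)
        min(vapply(f, `[[`, numeric(1L), "k")), numeric(1L)),
      row.names = NULL)
    h <- artifacts$histograms[[gait]]
    tables[[paste0("two_peak_histogram_", gait)]] <- data.frame(
      sensor = names(h),
      do.call(rbind, lapply(h, function(x) as.data.frame(t(x$counts)))),
      row.names = NULL, check.names = FALSE)
  }
  tables
}

# sensors x subjects wide table with interleaved statistic rows
wide_table <- function(df, ..., sensor_col = "sensor",
                       subject_col = "subject") {
  stats_cols <- c(...)
  subjects <- sort(unique(df[[subject_col]]))
  sensors <- intersect(ALL_SENSORS, unique(df[[sensor_col]]))
  rows <- list()
  for (sen in sensors) for (st in stats_cols) {
    vals <- vapply(subjects, function(su) {
      v <- df[df[[sensor_col]] == sen & df[[subject_col]] == su, st]
      if (length(v)) v[1L] else NA_real_
    }, numeric(1L))
    rows[[length(rows) + 1L]] <-
      data.frame(sensor = sen, statistic = st, t(vals), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out) <- c("sensor", "statistic", subjects)
  out
}

cs_table <- function(dd) {
  subjects <- sort(unique(dd$subject))
  sensors <- intersect(ALL_SENSORS, unique(dd$sensor))
  m <- matrix(NA_real_, length(sensors), length(subjects),
              dimnames = list(sensors, subjects))
  for (i in seq_len(nrow(dd)))
    m[dd$sensor[i], dd$subject[i]] <- dd$dist_full[i]
  out <- data.frame(sensor = sensors, m, check.names = FALSE)
  out$Median <- apply(m, 1L, stats::median, na.rm = TRUE)
  out$MAD <- apply(m, 1L, function(r) mad_about_mean(r[!is.na(r)]))
  bottom <- data.frame(
    sensor = c("Median", "MAD"),
    rbind(apply(m, 2L, stats::median, na.rm = TRUE),
          apply(m, 2L, function(c) mad_about_mean(c[!is.na(c)]))),
    Median = NA_real_, MAD = NA_real_, check.names = FALSE)
  rbind(out, bottom)
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cycles(result$cycles, file.path(out_dir, "cycles.csv"))
  # peak clouds
  peaks <- list()
  models_dir <- file.path(out_dir, "models")
  dir.create(models_dir, showWarnings = FALSE)
  for (gait in names(result$fits))
    for (subject in names(result$fits[[gait]]))
      for (sensor in names(result$fits[[gait]][[subject]])) {
        f <- result$fits[[gait]][[subject]][[sensor]]
        cloud <- extract_peak_cloud(result$cycles[[gait]][[subject]][[sensor]])
        peaks[[length(peaks) + 1L]] <- data.frame(
          subject = subject, gait = gait, sensor = sensor,
          cycle_index = cloud$cycle, t = cloud$X[, "t"], a = cloud$X[, "a"])
        stem <- paste(subject, gait, sensor, sep = "_")
        write_gmm(f$model, file.path(models_dir, paste0(stem, "_peak.json")))
        write_gmm(f$full_model,
                  file.path(models_dir, paste0(stem, "_full.json")))
        write_gmm(f$noise_model,
                  file.path(models_dir, paste0(stem, "_noise.json")))
      }
  write_full_precision_csv(do.call(rbind, peaks),
                           file.path(out_dir, "peaks.csv"))
  write_full_precision_csv(result$distances,
                           file.path(out_dir, "cs_distances.csv"))
  write_full_precision_csv(result$variability_intra,
                           file.path(out_dir, "variability_intra.csv"))
  write_full_precision_csv(result$variability_inter,
                           file.path(out_dir, "variability_inter.csv"))
  for (gait in names(result$trees))
    for (mg in names(result$trees[[gait]])) {
      stem <- file.path(out_dir, paste0("tree_", gait, "_", mg))
      write_linkage(result$trees[[gait]][[mg]],
                    paste0(stem, "_linkage.csv"), paste0(stem, ".newick"))
      part <- result$partitions[[gait]][[mg]]
      write_full_precision_csv(
        data.frame(subject = names(part), cluster = as.integer(part)),
        paste0(stem, "_partition.csv"))
    }
  tables_dir <- file.path(out_dir, "tables")
  dir.create(tables_dir, showWarnings = FALSE)
  for (nm in names(result$tables))
    write_full_precision_csv(result$tables[[nm]],
                             file.path(tables_dir, paste0(nm, ".csv")))
  log <- c("# pipeline run log", "", "## resolved configuration",
           yaml::as.yaml(result$config), "## cycle summary",
           utils::capture.output(print(result$cycle_summary)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
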