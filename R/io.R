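#' Read a trial manifest
#'
#' A manifest lists the trials of a study: one record per trial with
#' `subject_id`, `gait` (`walk`/`trot`), `trial_index`, `emg_path`,
#' `kin_path`, and optional `emg_rate` (default 4000) and `kin_rate`
#' (default 120). YAML (`.yaml`/`.yml`) or JSON (`.json`) by extension.
#'
#' @param path manifest file path. Relative data paths are resolved against
#'   the manifest's directory.
#' @return data.frame with one validated row per trial.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("manifest must be .yaml/.yml or .json"))
  if (!is.null(raw$trials)) raw <- raw$trials
  rows <- lapply(raw, function(tr) {
    tr <- as.list(tr)
    if (is.null(tr$emg_rate)) tr$emg_rate <- 4000
    if (is.null(tr$kin_rate)) tr$kin_rate <- 120
    need <- c("subject_id", "gait", "trial_index", "emg_path", "kin_path")
    miss <- setdiff(need, names(tr))
    if (length(miss))
      stop(sprintf("manifest record missing field(s): %s",
                   paste(miss, collapse = ", ")))
    if (!tr$gait %in% c("walk", "trot"))
      stop(sprintf("gait must be 'walk' or 'trot', got '%s'", tr$gait))
    if (tr$emg_rate <= 0 || tr$kin_rate <= 0) stop("rates must be positive")
    if (identical(tr$emg_path, tr$kin_path))
      stop("emg_path and kin_path must differ")
    as.data.frame(tr[c(need, "emg_rate", "kin_rate")],
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  base <- dirname(normalizePath(path))
  for (col in c("emg_path", "kin_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", out[[col]])
    out[[col]][rel] <- file.path(base, out[[col]][rel])
  }
  out
}

# Numeric CSV reader shared by the trial readers. Empty cells become NA when
# allow_gaps; non-numeric cells error with the offending data row index.
read_numeric_csv <- function(path, allow_gaps, dec = ".") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, dec = dec,
                        colClasses = "character", strip.white = TRUE,
                        blank.lines.skip = FALSE)
  if (anyDuplicated(names(df)))
    stop(sprintf("duplicate channel label in %s", path))
  out <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    cell <- df[[j]]
    if (dec != ".") cell <- gsub(dec, ".", cell, fixed = TRUE)
    blank <- cell == "" | is.na(cell)
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!blank & is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s, column '%s', data row %d",
                   path, names(df)[j], bad[1L]))
    if (any(blank) && !allow_gaps)
      stop(sprintf("gap (empty cell) in %s, column '%s', data row %d: EMG must be gap-free",
                   path, names(df)[j], which(blank)[1L]))
    out[, j] <- val
  }
  out
}

#' Read one trial's EMG and kinematics files
#'
#' Both files are delimited text with a header row and one sample per row.
#' The EMG file's columns must be a subset of the 8 canonical sensor labels
#' (LDL, GML1-GML3, LDR, GMR1-GMR3) and must be gap-free; the kinematics
#' file needs a `hoof_y` column (vertical coordinate of the left-fore hoof
#' marker) in which empty cells are kept as gaps.
#'
#' @param manifest_row one row of a [read_manifest()] data.frame (or an
#'   equivalent list).
#' @param dec decimal separator in the data files (`"."` default; `","`
#'   accepted for comma-decimal exports).
#' @return A `raw_recording` (see [generate_trial()]) with a `truth` slot
#'   holding the manifest metadata.
#' @export
read_trial <- function(manifest_row, dec = ".") {
  mr <- as.list(manifest_row)
  emg <- read_numeric_csv(mr$emg_path, allow_gaps = FALSE, dec = dec)
  unknown <- setdiff(colnames(emg), ALL_SENSORS)
  if (length(unknown))
    stop(sprintf("unknown channel label(s): %s",
                 paste(unknown, collapse = ", ")))
  kin <- read_numeric_csv(mr$kin_path, allow_gaps = TRUE, dec = dec)
  if (!"hoof_y" %in% colnames(kin))
    stop("kinematics file must contain a 'hoof_y' column")
  channels <- lapply(seq_len(ncol(emg)), function(j)
    emg_signal(emg[, j], mr$emg_rate))
  names(channels) <- colnames(emg)
  structure(list(channels = channels,
                 hoof_y = emg_signal(kin[, "hoof_y"], mr$kin_rate),
                 truth = mr),
            class = "raw_recording")
}

#' Write one trial to CSV files
#'
#' Inverse of [read_trial()]: the EMG channels to `emg_path` and the hoof
#' trajectory to `kin_path`, full precision, gaps as empty cells.
#'
#' @param recording a `raw_recording`.
#' @param emg_path,kin_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_trial <- function(recording, emg_path, kin_path) {
  emg <- vapply(recording$channels, function(s) s$values,
                numeric(recording$channels[[1L]]$n))
  write_full_precision_csv(as.data.frame(emg), emg_path)
  write_full_precision_csv(data.frame(hoof_y = recording$hoof_y$values),
                           kin_path)
  invisible(c(emg_path, kin_path))
}

write_full_precision_csv <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "",
                        formatC(df[[j]], format = "g", digits = 17))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write %s", path))
  invisible(path)
}

#' Write normalized cycles of several groups to one CSV
#'
#' @param cyclesets nested named list `cyclesets[[subject]][[gait]][[sensor]]`
#'   of normalized `cycle_set`s (inner levels may be flattened; any list
#'   whose leaves are `cycle_set`s works, names are joined with `/` into the
#'   `group` column).
#' @param path output CSV. Columns: group, cycle_index, frame, value.
#' @return invisibly, `path`.
#' @export
write_cycles <- function(cyclesets, path) {
  rows <- list()
  walk <- function(x, prefix) {
    if (inherits(x, "cycle_set")) {
      m <- normalized_matrix(x)
      rows[[length(rows) + 1L]] <<- data.frame(
        group = prefix,
        cycle_index = rep(seq_len(ncol(m)), each = 100L),
        frame = rep(seq_len(100L), ncol(m)),
        value = as.numeric(m))
    } else if (is.list(x)) {
      for (nm in names(x))
        walk(x[[nm]], if (nzchar(prefix)) paste(prefix, nm, sep = "/") else nm)
    }
  }
  walk(cyclesets, "")
  write_full_precision_csv(do.call(rbind, rows), path)
}

#' Serialize a fitted mixture model to JSON
#'
#' Weights, means, covariance entries, the log-likelihood trace and fit
#' diagnostics, at full precision; [read_gmm()] restores the model exactly.
#'
#' @param model a `gmm_model`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_gmm <- function(model, path) {
  stopifnot(inherits(model, "gmm_model"))
  doc <- list(k = model$k, weights = model$weights,
              means = lapply(seq_len(model$k), function(j)
                unname(model$means[j, ])),
              covariances = lapply(model$covariances, function(S)
                unname(as.numeric(S))),
              loglik_trace = model$loglik_trace,
              converged = model$converged, n_iter = model$n_iter,
              n_points = model$n_points,
              covariance_type = model$covariance_type)
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write %s", path))
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
  k <- doc$k
  means <- do.call(rbind, doc$means)
  colnames(means) <- c("t", "a")
  structure(list(k = k, weights = as.numeric(doc$weights), means = means,
                 covariances = lapply(doc$covariances, function(v)
                   matrix(as.numeric(v), 2L, 2L)),
                 loglik = doc$loglik_trace[length(doc$loglik_trace)],
                 loglik_trace = as.numeric(doc$loglik_trace),
                 converged = doc$converged, n_iter = doc$n_iter,
                 n_points = doc$n_points,
                 covariance_type = doc$covariance_type),
            class = "gmm_model")
}

#' Export a cluster tree as a merge table and a Newick string
#'
#' @param tree a `cluster_tree` from [single_linkage()].
#' @param merge_path CSV path for the merge table (step, a, b, height).
#' @param newick_path path for the Newick tree; subject ids are leaf labels
#'   and merge heights become branch lengths.
#' @return invisibly, the Newick string.
#' @export
write_linkage <- function(tree, merge_path, newick_path) {
  stopifnot(inherits(tree, "cluster_tree"))
  write_full_precision_csv(tree$merges, merge_path)
  phy <- ape::as.phylo(tree$hclust)
  ok <- tryCatch({
    ape::write.tree(phy, file = newick_path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write %s", newick_path))
  invisible(ape::write.tree(phy))
}
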