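#' Sensor groups of the 8-electrode montage
#'
#' Fixed sensor orderings for the two muscle groups: the long back muscle
#' (longissimus dorsi, one sensor per side) and the gluteus medius (three
#' sensors per side).
#'
#' @param muscle_group `"LD"` or `"GM"`.
#' @return character vector of sensor labels in canonical order.
#' @export
sensor_labels <- function(muscle_group = c("LD", "GM")) {
  switch(match.arg(muscle_group),
         LD = c("LDL", "LDR"),
         GM = c("GML1", "GML2", "GML3", "GMR1", "GMR2", "GMR3"))
}

ALL_SENSORS <- c("LDL", "GML1", "GML2", "GML3", "LDR", "GMR1", "GMR2", "GMR3")

#' Mixture-derived feature vectors for subject exploration
#'
#' Per sensor, each subject contributes 11 numbers: the frames of the 5
#' highest reference-curve peaks, the heights of those peaks, and the total
#' mode count of the sensor's mixture. Sensors are concatenated in canonical
#' order (LD: 22 features; GM: 66). Missing ranks (fewer than 5 peaks) are
#' padded with 0 and masked out of the standardization statistics. Features
#' are z-scored across subjects before distance computation, so frames
#' (1-100) and amplitudes (0-1) contribute comparably.
#'
#' @param rankings nested named list: `rankings[[subject]][[sensor]]` is a
#'   [rank_modes()] table, and `rankings[[subject]][[sensor]]$n_modes` may
#'   supply the mode count; alternatively pass `mode_counts`.
#' @param mode_counts optional named list `mode_counts[[subject]][[sensor]]`
#'   of integer mode counts.
#' @param muscle_group `"LD"` or `"GM"`.
#' @param standardize z-score across subjects (default `TRUE`).
#' @return matrix with one row per subject (rownames = subject ids), 11 x
#'   n_sensors columns.
#' @export
build_features <- function(rankings, mode_counts = NULL,
                           muscle_group = c("LD", "GM"), standardize = TRUE) {
  muscle_group <- match.arg(muscle_group)
  sensors <- sensor_labels(muscle_group)
  subjects <- names(rankings)
  if (is.null(subjects) || length(subjects) < 2L)
    stop("need a named list of at least 2 subjects")
  feat <- matrix(NA_real_, length(subjects), 11L * length(sensors),
                 dimnames = list(subjects, NULL))
  cn <- character(0)
  for (s in sensors)
    cn <- c(cn, paste0(s, "_peak_t", 1:5), paste0(s, "_peak_a", 1:5),
            paste0(s, "_n_modes"))
  colnames(feat) <- cn
  for (subj in subjects) {
    row <- numeric(0)
    for (s in sensors) {
      rk <- rankings[[subj]][[s]]
      if (is.null(rk)) stop(sprintf("subject %s is missing sensor %s", subj, s))
      tab <- if (is.data.frame(rk)) rk else rk$ranking
      nm <- if (!is.null(mode_counts)) mode_counts[[subj]][[s]]
            else if (!is.data.frame(rk) && !is.null(rk$n_modes)) rk$n_modes
            else sum(!is.na(tab$WhMC))
      row <- c(row, tab$HhMC[1:5], tab$HhValue[1:5], nm)
    }
    feat[subj, ] <- row
  }
  if (standardize) {
    for (j in seq_len(ncol(feat))) {
      col <- feat[, j]
      obs <- !is.na(col)
      mu <- mean(col[obs])
      sd <- stats::sd(col[obs])
      feat[, j] <- if (!is.na(sd) && sd > 0) (col - mu) / sd else 0
    }
  }
  feat[is.na(feat)] <- 0
  feat
}

#' Pairwise Euclidean dissimilarities between feature vectors
#'
#' @param features subjects x features matrix (rownames = subject ids).
#' @return symmetric matrix of Euclidean distances with zero diagonal.
#' @export
dissimilarity_matrix <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 subjects")
  d <- as.matrix(stats::dist(features, method = "euclidean"))
  dimnames(d) <- list(rownames(features), rownames(features))
  d
}

#' Agglomerative single-linkage clustering of subjects
#'
#' Iteratively merges the two clusters at the smallest single-link distance
#' (the minimum pairwise distance between their members). Subjects are
#' internally reordered by label before clustering so the merge sequence,
#' including tie-breaks, does not depend on input order.
#'
#' @param dissimilarity symmetric dissimilarity matrix with labels as
#'   dimnames.
#' @return A `cluster_tree`: list with `hclust` (the underlying
#'   [stats::hclust] object), `merges` (data.frame of member labels and
#'   heights, n-1 rows), `labels`.
#' @export
single_linkage <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("dissimilarity must be symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(d)))
  ord <- order(labs)
  d <- d[ord, ord, drop = FALSE]
  labs <- labs[ord]
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  hc$labels <- labs
  merges <- data.frame(
    step = seq_len(nrow(hc$merge)),
    a = merge_member(hc, hc$merge[, 1L]),
    b = merge_member(hc, hc$merge[, 2L]),
    height = hc$height
  )
  structure(list(hclust = hc, merges = merges, labels = labs),
            class = "cluster_tree")
}

# Human-readable handle for one side of an hclust merge row.
merge_member <- function(hc, idx) {
  vapply(idx, function(i)
    if (i < 0) hc$labels[-i] else paste0("cluster", i), character(1L))
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d subjects, %d merges (heights %.3g .. %.3g)\n",
              length(x$labels), nrow(x$merges),
              min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

#' Cut a cluster tree into a flat partition
#'
#' @param tree a `cluster_tree`.
#' @param n_clusters number of clusters, between 1 and the subject count.
#' @return named integer vector of cluster memberships.
#' @export
cut_tree <- function(tree, n_clusters) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- length(tree$labels)
  if (n_clusters < 1L || n_clusters > n)
    stop(sprintf("n_clusters must lie in [1, %d]", n))
  stats::cutree(tree$hclust, k = n_clusters)
}
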