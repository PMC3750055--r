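#' Leader-follower streaming clustering
#'
#' A single deterministic pass over the voxels in [iterate_voxels()]
#' order. Each voxel is compared with every existing cluster centroid
#' using Pearson correlation similarity; if the best similarity reaches
#' `threshold` the voxel joins that cluster (running-mean centroid
#' update), otherwise it founds a new cluster — unless `max_clusters`
#' has been reached, in which case it joins the best cluster anyway and
#' the overflow is noted in `extra_info`. Clusters are returned sorted by
#' size, descending. The technique has no random component: rerunning on
#' the same image reproduces the result exactly.
#'
#' @param image a [dynamic_image()].
#' @param threshold correlation similarity threshold in \[-1, 1\]. The
#'   default 0.3 is a conservative starting point for bolus-shaped
#'   kinetics; `-1` accepts everything (one cluster).
#' @param max_clusters cap on the number of clusters (default unlimited).
#' @return a [cluster_result()].
#' @export
leader_follower <- function(image, threshold = 0.3, max_clusters = Inf) {
  stopifnot(inherits(image, "dynamic_image"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < -1 || threshold > 1)
    stop("threshold must be a correlation value in [-1, 1]", call. = FALSE)
  if (max_clusters < 1L)
    stop("max_clusters must be >= 1", call. = FALSE)

  # correlation of a TAC with each centroid; flat curves correlate with
  # nothing and get similarity -1 (they will found or join the overflow
  # cluster rather than a kinetic one)
  sim_to <- function(tac, centroids) {
    s <- vapply(centroids, function(ce) {
      if (stats::sd(tac) == 0 || stats::sd(ce) == 0) -1
      else stats::cor(tac, ce)
    }, numeric(1))
    s
  }

  clusters <- list()
  overflow <- 0L
  for (v in iterate_voxels(image)) {
    if (length(clusters) == 0L) {
      clusters[[1L]] <- cluster_add(new_cluster(v$tac, "RUNNING_MEAN"), v)
      next
    }
    s <- sim_to(v$tac, lapply(clusters, `[[`, "centroid"))
    best <- which.max(s)
    if (s[best] >= threshold) {
      clusters[[best]] <- cluster_add(clusters[[best]], v)
    } else if (length(clusters) < max_clusters) {
      clusters[[length(clusters) + 1L]] <-
        cluster_add(new_cluster(v$tac, "RUNNING_MEAN"), v)
    } else {
      clusters[[best]] <- cluster_add(clusters[[best]], v)
      overflow <- overflow + 1L
    }
  }

  sizes <- vapply(clusters, function(cl) cl$size, integer(1))
  clusters <- clusters[order(sizes, decreasing = TRUE)]
  info <- c(sprintf("technique: leader-follower (threshold=%g)", threshold),
            sprintf("clusters formed: %d", length(clusters)))
  if (overflow > 0L)
    info <- c(info, sprintf(
      "max_clusters=%g reached: %d voxels forced into their best cluster",
      max_clusters, overflow))
  cluster_result(clusters, dims = c(image$n_x, image$n_y, image$n_z),
                 extra_info = info)
}
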