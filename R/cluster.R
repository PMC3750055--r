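#' Voxel cluster with a fixed-reference or running-mean centroid
#'
#' A cluster groups voxels sharing similar kinetics. Its centroid — the
#' representative TAC distances are measured against — follows one of two
#' update modes:
#' \describe{
#'   \item{`"RUNNING_MEAN"`}{the centroid is the arithmetic mean of the
#'     member TACs and is updated with every addition (the streaming mode
#'     leader-follower uses).}
#'   \item{`"FIXED_REFERENCE"`}{the centroid is an immutable reference
#'     vector set at construction; the mean member TAC is still tracked
#'     (the mode a k-means sweep uses, rebuilding clusters around the
#'     current centroids).}
#' }
#'
#' @param centroid numeric reference TAC. For `RUNNING_MEAN` clusters it is
#'   only an initial value, replaced by the member mean on the first
#'   [cluster_add()].
#' @param mode `"RUNNING_MEAN"` or `"FIXED_REFERENCE"`.
#' @return object of class `tac_cluster` with fields `mode`, `centroid`,
#'   `mean_tac`, `sum_tac`, `members` (3-column coordinate matrix), `size`.
#' @export
new_cluster <- function(centroid, mode = c("RUNNING_MEAN", "FIXED_REFERENCE")) {
  mode <- match.arg(mode)
  centroid <- as.numeric(centroid)
  structure(
    list(mode = mode, centroid = centroid,
         mean_tac = rep(NA_real_, length(centroid)),
         sum_tac = numeric(length(centroid)),
         members = matrix(integer(0), ncol = 3,
                          dimnames = list(NULL, c("x", "y", "slice"))),
         size = 0L),
    class = "tac_cluster"
  )
}

#' Add a voxel to a cluster
#'
#' Appends the voxel's coordinates, increments the size and updates the
#' running mean TAC. In `RUNNING_MEAN` mode the centroid follows the mean;
#' in `FIXED_REFERENCE` mode the centroid never changes.
#'
#' @param cluster a [new_cluster()] object.
#' @param voxel a `voxel` object ([iterate_voxels()]), or any list with
#'   fields `x`, `y`, `slice`, `tac`.
#' @return the updated cluster.
#' @export
cluster_add <- function(cluster, voxel) {
  stopifnot(inherits(cluster, "tac_cluster"))
  tac <- as.numeric(voxel$tac)
  if (length(tac) != length(cluster$centroid))
    stop(sprintf("TAC length %d does not match centroid length %d",
                 length(tac), length(cluster$centroid)), call. = FALSE)
  cluster$members <- rbind(cluster$members,
                           c(x = voxel$x, y = voxel$y, slice = voxel$slice))
  cluster$size <- cluster$size + 1L
  cluster$sum_tac <- cluster$sum_tac + tac
  cluster$mean_tac <- cluster$sum_tac / cluster$size
  if (cluster$mode == "RUNNING_MEAN") cluster$centroid <- cluster$mean_tac
  cluster
}

#' @export
print.tac_cluster <- function(x, ...) {
  cat(sprintf("<tac_cluster> mode=%s, size=%d, %d frames\n",
              x$mode, x$size, length(x$centroid)))
  invisible(x)
}

#' Result of a clustering technique
#'
#' Bundles the ordered cluster list (1-based cluster numbers follow list
#' order), the composite integer label volume (0 = unassigned), and the
#' optional extra images (e.g. PCA score maps) and free-text info lines a
#' technique may emit. The partition is hard: each voxel belongs to at
#' most one cluster.
#'
#' @param clusters list of `tac_cluster` objects.
#' @param dims spatial dimensions `(n_x, n_y, n_z)` used to build the
#'   label volume from the members lists.
#' @param extra_images optional named list of 3D/4D arrays.
#' @param extra_info optional character vector of information lines.
#' @return object of class `cluster_result` with fields `clusters`,
#'   `label_volume`, `extra_images`, `extra_info`, `n_clusters`.
#' @export
cluster_result <- function(clusters, dims, extra_images = NULL,
                           extra_info = NULL) {
  stopifnot(length(dims) == 3L, length(clusters) >= 1L)
  lab <- array(0L, dim = dims)
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    if (cl$size == 0L) next
    idx <- cbind(cl$members[, "x"] + 1L, cl$members[, "y"] + 1L,
                 cl$members[, "slice"])
    if (any(lab[idx] != 0L))
      stop("hard-partition violation: a voxel appears in more than one cluster",
           call. = FALSE)
    lab[idx] <- k
  }
  structure(
    list(clusters = clusters, label_volume = lab,
         extra_images = extra_images, extra_info = extra_info,
         n_clusters = length(clusters)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) cl$size, integer(1))
  cat(sprintf("<cluster_result> %d clusters over %s volume\n",
              x$n_clusters, paste(dim(x$label_volume), collapse = "x")))
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  if (!is.null(x$extra_images))
    cat("  extra images:", paste(names(x$extra_images), collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster mean TACs as a matrix
#'
#' @param result a [cluster_result()].
#' @return numeric matrix, one column per cluster (named `cluster1`, ...),
#'   one row per frame. Empty clusters yield NA columns.
#' @export
cluster_mean_tacs <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  m <- vapply(result$clusters, function(cl) cl$mean_tac,
              numeric(length(result$clusters[[1]]$centroid)))
  m <- matrix(m, ncol = length(result$clusters))
  colnames(m) <- paste0("cluster", seq_len(ncol(m)))
  m
}
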