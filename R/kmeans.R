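#' k-means++ seeding
#'
#' Chooses `k` initial centroids from the rows of `tacs` following the
#' D-squared weighting of Arthur & Vassilvitskii: the first centroid is
#' drawn uniformly at random; each subsequent one is drawn with
#' probability proportional to the squared metric distance to its nearest
#' already-chosen centroid. Reproducible given `seed`.
#'
#' @param tacs numeric matrix, one candidate TAC per row.
#' @param k number of centroids; must not exceed the number of distinct
#'   rows.
#' @param metric an initialized [tac_metric()]; defaults to Euclidean.
#' @param seed integer RNG seed.
#' @return list with `centroids` (k x n_frames matrix) and `index` (row
#'   indices of the chosen TACs).
#' @export
kmeanspp_seed <- function(tacs, k, metric = tac_metric("pnorm", p = 2),
                          seed = 1L) {
  tacs <- as.matrix(tacs)
  n_distinct <- nrow(unique(tacs))
  if (k > n_distinct)
    stop(sprintf("k = %d exceeds the %d distinct TACs available", k, n_distinct),
         call. = FALSE)
  chosen <- integer(k)
  old <- .seed_rng(seed)
  on.exit(.restore_rng(old), add = TRUE)
  chosen[1L] <- sample.int(nrow(tacs), 1L)
  d_near <- metric_pairwise(metric, tacs, tacs[chosen[1L], , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    w <- d_near^2
    if (sum(w) <= 0) {
      # all remaining mass sits on already-chosen points; pick an unchosen
      # distinct row uniformly (only reachable with duplicated rows)
      cand <- setdiff(seq_len(nrow(tacs)), chosen[seq_len(j - 1L)])
      chosen[j] <- cand[sample.int(length(cand), 1L)]
    } else {
      chosen[j] <- sample.int(nrow(tacs), 1L, prob = w)
    }
    d_new <- metric_pairwise(metric, tacs, tacs[chosen[j], , drop = FALSE])[, 1L]
    d_near <- pmin(d_near, d_new)
  }
  list(centroids = tacs[chosen, , drop = FALSE], index = chosen)
}

# Scoped RNG: save and restore the caller's state around seeded draws.
# `seed` is forced before the snapshot so a lazily evaluated expression
# that itself draws from the RNG is not rewound by the restore.
.seed_rng <- function(seed) {
  force(seed)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' k-means clustering of voxel TACs
#'
#' Lloyd-style alternation under an arbitrary TAC metric: each voxel is
#' assigned to the nearest centroid, then each centroid is recomputed as
#' the arithmetic mean of its members (whatever the assignment metric —
#' the centroid update is not redefined per metric). Iteration stops when
#' no assignment changes or after `max_iter` sweeps. A cluster left empty
#' by a sweep is reseeded with the voxel currently farthest from its own
#' centroid, so the result always has exactly `k` clusters. Deterministic
#' given `seed`.
#'
#' @param image a [dynamic_image()].
#' @param k number of clusters, `1 <= k <=` number of voxels (`k = 1`
#'   degenerates to the global mean TAC).
#' @param metric a [tac_metric()]; initialized here if it was not already.
#' @param max_iter maximum number of Lloyd sweeps.
#' @param seed integer RNG seed for the initialization draw.
#' @param init `"plusplus"` (k-means++ D-squared seeding, the default) or
#'   `"random"` (k distinct TACs drawn uniformly).
#' @return a [cluster_result()]; `extra_info` records the per-sweep
#'   objective (sum of member-to-centroid metric distances).
#' @export
tac_kmeans <- function(image, k, metric = tac_metric("pnorm", p = 2),
                       max_iter = 100L, seed = 1L,
                       init = c("plusplus", "random")) {
  stopifnot(inherits(image, "dynamic_image"))
  init <- match.arg(init)
  X <- tac_matrix(image)
  n <- nrow(X)
  if (k < 1L || k > n)
    stop(sprintf("k must be between 1 and the voxel count (%d)", n),
         call. = FALSE)
  if (!metric$initialized) metric <- metric_init(metric, image)

  if (init == "plusplus") {
    centroids <- kmeanspp_seed(X, k, metric, seed)$centroids
  } else {
    n_distinct <- nrow(unique(X))
    if (k > n_distinct)
      stop(sprintf("k = %d exceeds the %d distinct TACs available", k, n_distinct),
           call. = FALSE)
    old <- .seed_rng(seed)
    idx <- sample.int(n)
    .restore_rng(old)
    idx <- idx[!duplicated(X[idx, , drop = FALSE])][seq_len(k)]
    centroids <- X[idx, , drop = FALSE]
  }

  assign_prev <- rep(0L, n)
  objective <- numeric(0)
  for (iter in seq_len(max_iter)) {
    D <- metric_pairwise(metric, X, centroids)
    assign_cur <- max.col(-D, ties.method = "first")

    # reseed empty clusters with the voxel farthest from its centroid
    for (kk in which(tabulate(assign_cur, nbins = k) == 0L)) {
      far <- which.max(D[cbind(seq_len(n), assign_cur)])
      assign_cur[far] <- kk
      centroids[kk, ] <- X[far, ]
      D[, kk] <- metric_pairwise(metric, X, centroids[kk, , drop = FALSE])[, 1L]
    }

    objective <- c(objective, sum(D[cbind(seq_len(n), assign_cur)]))
    if (all(assign_cur == assign_prev)) break
    assign_prev <- assign_cur
    for (kk in seq_len(k))
      centroids[kk, ] <- colMeans(X[assign_cur == kk, , drop = FALSE])
  }

  grid <- voxel_grid(image)
  clusters <- lapply(seq_len(k), function(kk) {
    cl <- new_cluster(centroids[kk, ], mode = "FIXED_REFERENCE")
    for (i in which(assign_prev == kk))
      cl <- cluster_add(cl, list(x = grid[i, 1L], y = grid[i, 2L],
                                 slice = grid[i, 3L], tac = X[i, ]))
    cl
  })
  res <- cluster_result(
    clusters, dims = c(image$n_x, image$n_y, image$n_z),
    extra_info = c(
      sprintf("technique: kmeans (init=%s, k=%d, metric=%s, seed=%d)",
              init, k, metric$name, seed),
      sprintf("iterations: %d", length(objective)),
      sprintf("objective per sweep: %s",
              paste(formatC(objective, digits = 10, format = "g"),
                    collapse = " "))
    )
  )
  res$objective <- objective
  res
}
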