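# Shared fixtures: all test inputs are built in code.

# image whose voxel values are a known function of (x, y, z, t), for
# indexing oracles
indexed_image <- function(nx, ny, nz, nt) {
  arr <- array(seq_len(nx * ny * nz * nt) - 1, dim = c(nx, ny, nz, nt))
  dynamic_image(arr)
}

# two hand-built, near-orthogonal kinetic shapes: an early bolus and a
# late accumulation; their correlation is strongly negative
two_shape_image <- function(nx = 4, ny = 4, nz = 2) {
  tac_a <- gamma_variate_tac(0:7, A = 5, t0 = 0, alpha = 1.5, beta = 1)
  tac_b <- c(0, 0.1, 0.3, 0.8, 1.6, 2.6, 3.8, 5.2)
  n_vox <- nx * ny * nz
  labels <- rep(1:2, each = n_vox / 2)
  X <- rbind(tac_a, tac_b)[labels, ]
  list(image = dynamic_image(array(as.vector(X), c(nx, ny, nz, 8))),
       labels = array(labels, c(nx, ny, nz)),
       tacs = rbind(tac_a, tac_b))
}

ari <- function(a, b) mclust::adjustedRandIndex(as.vector(a), as.vector(b))

# exhaustive k=2 optimum of the k-means objective (sum of member-to-mean
# Euclidean distances) over all 2-partitions of the rows of X
brute_force_optimum <- function(X, k = 2) {
  stopifnot(k == 2, nrow(X) <= 12)
  n <- nrow(X)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    a <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(a)) < k) next
    obj <- 0
    for (kk in 1:k) {
      M <- X[a == kk, , drop = FALSE]
      ce <- colMeans(M)
      obj <- obj + sum(sqrt(rowSums((M - rep(ce, each = nrow(M)))^2)))
    }
    if (obj < best) best <- obj
  }
  best
}

# label volume re-derived from the members lists, for partition checks
labels_from_members <- function(result) {
  lab <- array(0L, dim = dim(result$label_volume))
  for (k in seq_along(result$clusters)) {
    m <- result$clusters[[k]]$members
    if (nrow(m) == 0) next
    lab[cbind(m[, "x"] + 1L, m[, "y"] + 1L, m[, "slice"])] <- k
  }
  lab
}
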