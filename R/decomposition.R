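# Shared tail for PCA/SVD/ICA: voxel scores -> argmax-|score| hard labels,
# per-component 3D score maps, and the assembled cluster_result. The hard
# assignment is this package's documented convention: component images are
# the primary output, the labeling is a convenience view of them.
.scores_to_result <- function(image, scores, prefix, info) {
  grid <- voxel_grid(image)
  X <- tac_matrix(image)
  lab <- max.col(abs(scores), ties.method = "first")
  n_comp <- ncol(scores)
  clusters <- lapply(seq_len(n_comp), function(kk) {
    members <- which(lab == kk)
    seed <- if (length(members)) colMeans(X[members, , drop = FALSE])
            else numeric(ncol(X))
    cl <- new_cluster(seed, mode = "FIXED_REFERENCE")
    for (i in members)
      cl <- cluster_add(cl, list(x = grid[i, 1L], y = grid[i, 2L],
                                 slice = grid[i, 3L], tac = X[i, ]))
    cl
  })
  extra <- lapply(seq_len(n_comp), function(j)
    array(scores[, j], dim = c(image$n_x, image$n_y, image$n_z)))
  names(extra) <- paste0(prefix, seq_len(n_comp))
  cluster_result(clusters, dims = c(image$n_x, image$n_y, image$n_z),
                 extra_images = extra, extra_info = info)
}

#' Voxelwise principal component analysis
#'
#' Builds the voxels-by-frames TAC matrix, centers each frame (column) and
#' computes all `n_frames` principal components of the TAC covariance.
#' `extra_images` carries one 3D score map per component (`PC1`, `PC2`,
#' ...); a hard labeling is derived by assigning each voxel to the
#' component on which its absolute score is largest.
#'
#' @param image a [dynamic_image()].
#' @return a [cluster_result()] with `n_frames` clusters and score maps;
#'   `extra_info` lists the proportion of variance per component.
#' @export
pca_technique <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  X <- tac_matrix(image)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x
  # prcomp drops zero-variance trailing components only via rank arguments;
  # pad to n_frames so the component count always equals the frame count
  if (ncol(scores) < image$n_frames) {
    pad <- matrix(0, nrow(scores), image$n_frames - ncol(scores))
    scores <- cbind(scores, pad)
  }
  varprop <- pc$sdev^2 / sum(pc$sdev^2)
  info <- c(sprintf("technique: pca (%d components)", image$n_frames),
            sprintf("variance explained: %s",
                    paste(formatC(varprop, digits = 6, format = "g"),
                          collapse = " ")))
  .scores_to_result(image, scores, "PC", info)
}

#' Voxelwise singular value decomposition
#'
#' SVD of the uncentered voxels-by-frames TAC matrix `X = U D V'`. The
#' right singular vectors are temporal factors; voxel scores are the
#' projections `X V = U D`, emitted as one 3D map per factor (`SV1`,
#' ...). Hard labels by argmax absolute score, as for PCA.
#'
#' @param image a [dynamic_image()].
#' @return a [cluster_result()] with `n_frames` clusters and score maps;
#'   `extra_info` lists the singular values.
#' @export
svd_technique <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  X <- tac_matrix(image)
  sv <- svd(X, nu = 0, nv = image$n_frames)
  scores <- X %*% sv$v
  info <- c(sprintf("technique: svd (%d components)", image$n_frames),
            sprintf("singular values: %s",
                    paste(formatC(sv$d, digits = 10, format = "g"),
                          collapse = " ")))
  .scores_to_result(image, scores, "SV", info)
}

#' Voxelwise independent component analysis (FastICA)
#'
#' Whitens the centered voxels-by-frames TAC matrix and runs the
#' symmetric fixed-point FastICA iteration with the logcosh contrast until
#' the unmixing directions change by less than `tol` (measured as
#' `max |1 - |diag(W_new W_old')||`) or `max_iter` is reached. Each
#' independent component yields a 3D score map (`IC1`, ...); hard labels
#' by argmax absolute score. Deterministic given `seed`. Non-convergence
#' is reported with a warning and flagged in `extra_info`; the current
#' estimate is still returned.
#'
#' @param image a [dynamic_image()].
#' @param n_components number of components, between 2 and `n_frames`.
#' @param seed integer RNG seed for the random orthogonal start.
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on the component directions.
#' @return a [cluster_result()] with `n_components` clusters and score
#'   maps; `extra_info` records the iteration count and the estimated
#'   temporal mixing directions.
#' @export
ica_technique <- function(image, n_components = 2L, seed = 1L,
                          max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(image, "dynamic_image"))
  if (n_components < 2L || n_components > image$n_frames)
    stop("n_components must be between 2 and n_frames", call. = FALSE)
  X <- tac_matrix(image)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(Xc)

  # whiten: Z = Xc E D^{-1/2}, keeping the n_components leading directions
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  keep <- seq_len(n_components)
  dvals <- pmax(eg$values[keep], .Machine$double.eps)
  K <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(dvals), n_components)
  Z <- Xc %*% K

  # symmetric orthogonalization: W <- (W W')^{-1/2} W
  sym_orth <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps))) %*%
      t(e$vectors) %*% W
  }

  old <- .seed_rng(seed)
  W <- matrix(stats::rnorm(n_components^2), n_components)
  .restore_rng(old)
  W <- sym_orth(W)

  converged <- FALSE
  iters <- max_iter
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)                 # n x c component activations
    G <- tanh(WX)                    # logcosh contrast: g = tanh
    gprime <- 1 - G^2
    W_new <- t(G) %*% Z / n - diag(colMeans(gprime), n_components) %*% W
    W_new <- sym_orth(W_new)
    delta <- max(abs(1 - abs(diag(W_new %*% t(W)))))
    W <- W_new
    if (delta < tol) { converged <- TRUE; iters <- it; break }
  }
  if (!converged)
    warning(sprintf("FastICA did not converge in %d iterations (tol %g); returning current estimate",
                    max_iter, tol))

  scores <- Z %*% t(W)
  mixing <- t(W %*% t(K))  # n_frames x c temporal mixing estimate
  info <- c(sprintf("technique: ica (%d components, seed=%d)", n_components, seed),
            sprintf("fastica iterations: %d%s", iters,
                    if (converged) "" else " (NOT CONVERGED)"))
  res <- .scores_to_result(image, scores, "IC", info)
  res$mixing <- mixing
  res$unmixing <- W        # orthonormal in whitened space
  res$converged <- converged
  res
}
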