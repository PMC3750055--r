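test_that("k-means separates two well-separated point clouds exactly", {
  set.seed(31)
  truth <- rep(1:2, c(30, 30))
  X <- matrix(rep(c(0, 10), c(30, 30) * 3), 60, 3) +
    matrix(rnorm(180, sd = 0.1), 60, 3)
  img <- dynamic_image(array(as.vector(X), c(6, 10, 1, 3)))
  res <- tac_kmeans(img, 2, seed = 1, init = "plusplus")
  expect_equal(ari(res$label_volume, array(truth, c(6, 10, 1))), 1.0)
})

test_that("k = 1 degenerates to the global mean TAC", {
  img <- dynamic_image(array(rnorm(4 * 4 * 2 * 5), c(4, 4, 2, 5)))
  res <- tac_kmeans(img, 1, seed = 1)
  expect_equal(res$n_clusters, 1L)
  expect_equal(res$clusters[[1]]$size, 32L)
  expect_equal(res$clusters[[1]]$mean_tac, colMeans(tac_matrix(img)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("k-means on a tiny instance attains the brute-force optimum", {
  ph <- generate_phantom(c(2, 2, 2, 5), n_classes = 2, noise_sigma = 0.6,
                         seed = 7, min_separation = 2)
  opt <- brute_force_optimum(tac_matrix(ph$image))
  res <- tac_kmeans(ph$image, 2, seed = 1, init = "plusplus")
  expect_equal(tail(res$objective, 1), opt, tolerance = 1e-8)
})

test_that("the k-means objective is non-increasing across sweeps", {
  ph <- generate_phantom(c(8, 8, 2, 6), n_classes = 3, noise_sigma = 0.3,
                         seed = 3, min_separation = 1)
  res <- tac_kmeans(ph$image, 3, seed = 2, init = "random")
  expect_true(all(diff(res$objective) <= 1e-8))
})

test_that("k-means is deterministic given the seed and validates k", {
  ph <- generate_phantom(c(4, 4, 2, 5), n_classes = 2, noise_sigma = 0.2,
                         seed = 5)
  r1 <- tac_kmeans(ph$image, 3, seed = 9)
  r2 <- tac_kmeans(ph$image, 3, seed = 9)
  expect_identical(r1$label_volume, r2$label_volume)
  expect_error(tac_kmeans(ph$image, 33, seed = 1), "voxel count")
  expect_error(tac_kmeans(ph$image, 0, seed = 1), "between 1")
})

test_that("k-means++ seeding selects distinct TACs with D-squared weighting", {
  # n = k distinct points: every point is selected whatever the seed
  pts <- matrix(c(0, 3, 11, 0, 1, 2), 3, 2)
  m <- tac_metric("pnorm", p = 2)
  for (s in c(1, 2, 99))
    expect_setequal(kmeanspp_seed(pts, 3, m, seed = s)$index, 1:3)

  # same seed -> identical centroid sets
  set.seed(32)
  X <- matrix(rnorm(40), 20, 2)
  expect_identical(kmeanspp_seed(X, 5, m, seed = 4),
                   kmeanspp_seed(X, 5, m, seed = 4))

  # more centroids than distinct TACs is an error
  expect_error(kmeanspp_seed(matrix(1, 4, 2), 2, m, seed = 1), "distinct")
})

test_that("k-means++ second pick follows the squared-distance law", {
  # points {0, 1, 100}: given the first pick is 0, the second should be
  # 100 with probability 100^2 / (1 + 100^2) = 0.99990
  pts <- matrix(c(0, 1, 100), 3, 1)
  m <- tac_metric("pnorm", p = 2)
  first0 <- 0L; second100 <- 0L
  for (s in 1:10000) {
    sel <- kmeanspp_seed(pts, 2, m, seed = s)$index
    if (sel[1] == 1L) {
      first0 <- first0 + 1L
      if (sel[2] == 3L) second100 <- second100 + 1L
    }
  }
  expect_gt(first0, 2000)  # uniform first pick visits each point often
  expect_equal(second100 / first0, 100^2 / (1 + 100^2), tolerance = 0.005)
})

test_that("leader-follower accepts everything at threshold -1", {
  ph <- generate_phantom(c(4, 4, 2, 6), n_classes = 3, noise_sigma = 0.2,
                         seed = 6)
  res <- leader_follower(ph$image, threshold = -1)
  expect_equal(res$n_clusters, 1L)
  expect_equal(res$clusters[[1]]$size, 32L)
})

test_that("leader-follower recovers decorrelated classes without noise", {
  fix <- two_shape_image()
  expect_lt(cor(fix$tacs[1, ], fix$tacs[2, ]), 0.2)
  res <- leader_follower(fix$image, threshold = 0.9)
  expect_equal(res$n_clusters, 2L)
  expect_equal(ari(res$label_volume, fix$labels), 1.0)
})

test_that("leader-follower is deterministic and validates its inputs", {
  ph <- generate_phantom(c(4, 4, 2, 6), n_classes = 3, noise_sigma = 0.3,
                         seed = 8)
  expect_identical(leader_follower(ph$image, 0.7),
                   leader_follower(ph$image, 0.7))
  expect_error(leader_follower(ph$image, threshold = 1.5), "\\[-1, 1\\]")
  expect_error(leader_follower(ph$image, threshold = 0.5, max_clusters = 0),
               "max_clusters")
})

test_that("leader-follower caps the cluster count and logs the overflow", {
  # three decorrelated classes but only two cluster slots: the third
  # class must be absorbed and the event logged
  ph <- generate_phantom(c(6, 6, 2, 8), n_classes = 3, noise_sigma = 0.05,
                         seed = 2, max_class_correlation = 0.8)
  res <- leader_follower(ph$image, threshold = 0.9, max_clusters = 2)
  expect_equal(res$n_clusters, 2L)
  expect_true(any(grepl("max_clusters", res$extra_info)))
  # clusters sorted by size, descending
  sizes <- vapply(res$clusters, function(cl) cl$size, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("PCA emits one component and score map per frame", {
  ph <- generate_phantom(c(6, 6, 2, 25), n_classes = 3, noise_sigma = 0.2,
                         seed = 9)
  res <- pca_technique(ph$image)
  expect_length(res$extra_images, 25L)
  expect_equal(res$n_clusters, 25L)
  expect_equal(dim(res$extra_images[[1]]), c(6, 6, 2))
})

test_that("PCA on rank-1 data concentrates all variance on component 1", {
  set.seed(33)
  w <- runif(24, 0.5, 2)                    # spatial weights
  f <- c(1, 3, 7, 4, 2)                     # temporal shape
  X <- outer(w, f)
  img <- dynamic_image(array(as.vector(X), c(4, 3, 2, 5)))
  res <- pca_technique(img)
  scores <- vapply(res$extra_images, as.vector, numeric(24))
  expect_lt(max(abs(scores[, 2:5])), 1e-8)
  expect_gt(max(abs(scores[, 1])), 0)
})

test_that("PCA scores agree with an independent eigendecomposition", {
  ph <- generate_phantom(c(4, 4, 2, 6), n_classes = 2, noise_sigma = 0.5,
                         seed = 10)
  X <- tac_matrix(ph$image)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(cov(Xc), symmetric = TRUE)
  want <- Xc %*% eg$vectors
  res <- pca_technique(ph$image)
  got <- vapply(res$extra_images, as.vector, numeric(32))
  for (j in 1:6)
    expect_equal(abs(got[, j]), abs(want[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("SVD reconstructs rank-1 data and matches eigenvalue magnitudes", {
  set.seed(34)
  w <- runif(24, 0.5, 2); f <- c(2, 5, 9, 6, 3)
  X <- outer(w, f)
  img <- dynamic_image(array(as.vector(X), c(4, 3, 2, 5)))
  res <- svd_technique(img)
  scores <- vapply(res$extra_images, as.vector, numeric(24))

  # rank-1 exactness: component 1 alone reconstructs X
  sv <- svd(X)
  recon <- scores[, 1] %*% t(sv$v[, 1])
  expect_equal(recon, X, tolerance = 1e-8 * max(abs(X)), ignore_attr = TRUE)
  expect_lt(max(abs(scores[, 2:5])), 1e-8)

  # full-rank data: singular values via an independent route (sqrt of the
  # eigenvalues of X'X) and orthogonality of the left factors
  X2 <- matrix(rnorm(24 * 5), 24, 5)
  img2 <- dynamic_image(array(as.vector(X2), c(4, 3, 2, 5)))
  scores2 <- vapply(svd_technique(img2)$extra_images, as.vector, numeric(24))
  d_got <- sort(sqrt(colSums(scores2^2)), decreasing = TRUE)
  d_oracle <- sqrt(pmax(eigen(crossprod(X2), symmetric = TRUE)$values, 0))
  expect_equal(d_got, d_oracle, tolerance = 1e-9, ignore_attr = TRUE)
  U <- sweep(scores2, 2, sqrt(colSums(scores2^2)), "/")
  expect_equal(crossprod(U), diag(5), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("FastICA recovers independent non-Gaussian sources", {
  set.seed(35)
  n <- 2000
  S <- cbind(runif(n, -1, 1), rexp(n) * sample(c(-1, 1), n, TRUE))
  A <- matrix(c(1, 0.5, -0.3, 0.8, 0.2,
                0.4, -1, 0.6, 0.3, -0.7), 5, 2)
  img <- dynamic_image(array(as.vector(S %*% t(A)), c(20, 10, 10, 5)))
  res <- ica_technique(img, n_components = 2, seed = 1)
  expect_length(res$extra_images, 2L)
  scores <- vapply(res$extra_images, as.vector, numeric(n))
  cc <- abs(cor(scores, S))
  # each true source matched by some component up to sign/permutation
  expect_gt(min(apply(cc, 2, max)), 0.95)

  # same seed -> identical component maps
  res2 <- ica_technique(img, n_components = 2, seed = 1)
  expect_identical(res$extra_images, res2$extra_images)
})

test_that("FastICA keeps the unmixing matrix orthogonal in whitened space", {
  set.seed(36)
  img <- dynamic_image(array(rnorm(1000 * 4), c(10, 10, 10, 4)))
  # white data carries no non-Gaussian structure, so the fixed point need
  # not settle; the estimate must still be flagged and stay orthogonal
  res <- suppressWarnings(ica_technique(img, n_components = 4, seed = 2,
                                        max_iter = 50))
  W <- res$unmixing
  expect_equal(W %*% t(W), diag(4), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(ica_technique(img, n_components = 1, seed = 1), "between 2")
})

test_that("every technique produces a consistent hard partition", {
  ph <- generate_phantom(c(6, 6, 2, 8), n_classes = 3, noise_sigma = 0.2,
                         seed = 13, min_separation = 1)
  results <- list(
    kmeans = tac_kmeans(ph$image, 3, seed = 1),
    lf = leader_follower(ph$image, threshold = 0.7),
    pca = pca_technique(ph$image),
    svd = svd_technique(ph$image),
    ica = suppressWarnings(ica_technique(ph$image, 3, seed = 1))
  )
  for (nm in names(results)) {
    res <- results[[nm]]
    expect_identical(labels_from_members(res), res$label_volume)
    sizes <- vapply(res$clusters, function(cl) cl$size, integer(1))
    expect_equal(sum(sizes), 72L)
  }
})
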