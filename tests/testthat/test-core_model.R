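test_that("hyperstack indexing is the frame-major bijection", {
  expect_identical(hyperstack_index(20, 20, 20), 400)
  expect_identical(hyperstack_index(1, 1, 47), 1)

  # exhaustive enumeration: 3 slices x 4 frames covers 1..12 exactly once
  grid <- expand.grid(slice = 1:3, frame = 1:4)
  idx <- hyperstack_index(grid$frame, grid$slice, 3)
  expect_setequal(idx, 1:12)
  expect_false(anyDuplicated(idx) > 0)

  expect_error(hyperstack_index(1, 4, 3), "out of range")
  expect_error(hyperstack_index(0, 1, 3), ">= 1")
})

test_that("hyperstack index round-trips over a 50x50 grid", {
  grid <- expand.grid(slice = 1:50, frame = 1:50)
  idx <- hyperstack_index(grid$frame, grid$slice, 50)
  back <- hyperstack_coords(idx, 50)
  expect_identical(back$frame, grid$frame)
  expect_identical(back$slice, grid$slice)
})

test_that("a static image is rejected on construction", {
  expect_error(dynamic_image(array(0, c(4, 4, 3, 1))), "static image")
  expect_silent(dynamic_image(array(0, c(4, 4, 3, 2))))
})

test_that("get_tac returns the (x, y, slice) time series as a copy", {
  # constant-in-space image: TAC is the frame index everywhere
  arr <- array(0, c(3, 3, 2, 5))
  for (t in 1:5) arr[, , , t] <- t - 1
  img <- dynamic_image(arr)
  expect_equal(get_tac(img, 0, 0, 1), 0:4)
  expect_equal(get_tac(img, 2, 1, 2), 0:4)

  # distinct integers: TAC matches direct 4D indexing at every coordinate
  img2 <- indexed_image(2, 1, 2, 3)
  for (x in 0:1) for (s in 1:2) {
    expect_equal(get_tac(img2, x, 0, s), as.vector(img2$data[x + 1, 1, s, ]))
  }

  expect_error(get_tac(img2, 0, 0, 3), "out of bounds")
  expect_error(get_tac(img2, 2, 0, 1), "out of bounds")
  expect_error(get_tac(img2, 0, -1, 1), "out of bounds")

  # mutating the returned vector must not alter the image
  tac <- get_tac(img2, 0, 0, 1)
  tac[1] <- 999
  expect_equal(get_tac(img2, 0, 0, 1)[1], img2$data[1, 1, 1, 1])
})

test_that("voxel iteration yields each coordinate once, in a fixed order", {
  img <- dynamic_image(array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3)))
  vox <- iterate_voxels(img)
  expect_length(vox, 8)

  # deterministic: two iterations give identical sequences
  vox2 <- iterate_voxels(img)
  expect_identical(vox, vox2)

  # set equality with the full Cartesian grid for a 3x4x2 volume
  img2 <- dynamic_image(array(rnorm(3 * 4 * 2 * 2), c(3, 4, 2, 2)))
  coords <- t(vapply(iterate_voxels(img2),
                     function(v) c(v$x, v$y, v$slice), numeric(3)))
  want <- as.matrix(expand.grid(x = 0:2, y = 0:3, slice = 1:2))
  expect_equal(coords[order(coords[, 3], coords[, 2], coords[, 1]), ],
               want[order(want[, 3], want[, 2], want[, 1]), ],
               ignore_attr = TRUE)

  # documented order: x fastest, then y, then slice
  expect_equal(coords[1:4, 1], c(0, 1, 2, 0))
  expect_equal(coords[1:4, 2], c(0, 0, 0, 1))
})

test_that("concatenating get_tac over the iterator touches every value once", {
  img <- dynamic_image(array(rnorm(3 * 2 * 2 * 4), c(3, 2, 2, 4)))
  total <- sum(vapply(iterate_voxels(img), function(v) sum(v$tac), numeric(1)))
  expect_equal(total, sum(img$data))
  expect_equal(tac_matrix(img)[5, ], iterate_voxels(img)[[5]]$tac,
               ignore_attr = TRUE)
})

test_that("running-mean clusters track the member mean in the centroid", {
  cl <- new_cluster(c(0, 0), "RUNNING_MEAN")
  cl <- cluster_add(cl, list(x = 0, y = 0, slice = 1, tac = c(0, 0)))
  cl <- cluster_add(cl, list(x = 1, y = 0, slice = 1, tac = c(2, 2)))
  expect_equal(cl$centroid, c(1, 1))
  expect_equal(cl$mean_tac, c(1, 1))
  expect_equal(cl$size, 2L)
})

test_that("fixed-reference clusters keep the centroid immutable", {
  cl <- new_cluster(c(5, 5), "FIXED_REFERENCE")
  cl <- cluster_add(cl, list(x = 0, y = 0, slice = 1, tac = c(2, 2)))
  cl <- cluster_add(cl, list(x = 1, y = 0, slice = 1, tac = c(4, 4)))
  expect_equal(cl$centroid, c(5, 5))
  expect_equal(cl$mean_tac, c(3, 3))
})

test_that("cluster mean matches an independent accumulation over 100 TACs", {
  set.seed(11)
  tacs <- matrix(rnorm(100 * 6), 100, 6)
  cl <- new_cluster(numeric(6), "RUNNING_MEAN")
  for (i in 1:100)
    cl <- cluster_add(cl, list(x = i, y = 0, slice = 1, tac = tacs[i, ]))
  expect_equal(cl$mean_tac, colMeans(tacs), tolerance = 1e-10)
  expect_equal(cl$size, 100L)
  expect_equal(nrow(cl$members), 100L)
})

test_that("cluster mean is invariant to the order voxels are added", {
  set.seed(12)
  tacs <- matrix(rnorm(40 * 5), 40, 5)
  add_all <- function(ord) {
    cl <- new_cluster(numeric(5), "RUNNING_MEAN")
    for (i in ord)
      cl <- cluster_add(cl, list(x = i, y = 0, slice = 1, tac = tacs[i, ]))
    cl$mean_tac
  }
  expect_equal(add_all(1:40), add_all(sample(40)), tolerance = 1e-9)
})

test_that("cluster_add rejects TACs of the wrong length", {
  cl <- new_cluster(c(1, 2, 3), "RUNNING_MEAN")
  expect_error(cluster_add(cl, list(x = 0, y = 0, slice = 1, tac = c(1, 2))),
               "length")
})

test_that("cluster_result enforces the hard partition and builds labels", {
  cl1 <- cluster_add(new_cluster(c(0, 0), "RUNNING_MEAN"),
                     list(x = 0, y = 0, slice = 1, tac = c(0, 0)))
  cl2 <- cluster_add(new_cluster(c(1, 1), "RUNNING_MEAN"),
                     list(x = 1, y = 0, slice = 1, tac = c(1, 1)))
  res <- cluster_result(list(cl1, cl2), dims = c(2, 1, 1))
  expect_equal(as.vector(res$label_volume), c(1L, 2L))

  # the same voxel in two clusters is a contract violation
  cl_dup <- cluster_add(new_cluster(c(9, 9), "RUNNING_MEAN"),
                        list(x = 0, y = 0, slice = 1, tac = c(9, 9)))
  expect_error(cluster_result(list(cl1, cl_dup), dims = c(2, 1, 1)),
               "hard-partition")
})
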