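#' Dynamic (4D) image container
#'
#' Wraps a 4D numeric array indexed `(x, y, z, t)` holding a temporal
#' sequence of 3D volumes, the object every clustering technique consumes.
#' Each voxel's vector of intensities across frames is its time-activity
#' curve (TAC). A static image (fewer than two frames) is rejected, since
#' there is no kinetic information to cluster.
#'
#' @param data numeric 4D array, dimensions `(n_x, n_y, n_z, n_frames)`.
#'   A 3D array is interpreted as a single-slice 2D+time acquisition and
#'   promoted to `(n_x, n_y, 1, n_frames)`.
#' @return an object of class `dynamic_image` with elements `data`, `n_x`,
#'   `n_y`, `n_z`, `n_frames`.
#' @examples
#' img <- dynamic_image(array(rnorm(4 * 4 * 2 * 5), c(4, 4, 2, 5)))
#' img$n_frames
#' @export
dynamic_image <- function(data) {
  if (!is.array(data) || !is.numeric(data))
    stop("`data` must be a numeric array", call. = FALSE)
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D (x, y, z, t) array", call. = FALSE)
  d <- dim(data)
  if (d[4] < 2L)
    stop("static image: the input has fewer than 2 frames and cannot be clustered",
         call. = FALSE)
  structure(
    list(data = data, n_x = d[1], n_y = d[2], n_z = d[3], n_frames = d[4]),
    class = "dynamic_image"
  )
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat(sprintf("<dynamic_image> %d x %d x %d voxels, %d frames\n",
              x$n_x, x$n_y, x$n_z, x$n_frames))
  invisible(x)
}

#' @export
dim.dynamic_image <- function(x) dim(x$data)

#' Hyperstack linear slice index
#'
#' ImageJ-style hyperstacks store a 4D image as a flat stack of 2D slices
#' ordered frame-major: a volume with `n_slices` slices and `F` frames is a
#' stack of `n_slices * F` planes, and plane `(frame, slice)` sits at linear
#' position `(frame - 1) * n_slices + slice` (all 1-based). The mapping is a
#' bijection between the `(frame, slice)` grid and `1..n_slices*F`.
#'
#' @param frame 1-based frame number (vectorised).
#' @param slice 1-based slice number (vectorised).
#' @param n_slices number of slices per frame.
#' @return 1-based linear stack index.
#' @examples
#' hyperstack_index(20, 20, 20)  # 400
#' @export
hyperstack_index <- function(frame, slice, n_slices) {
  if (any(frame < 1L)) stop("frame must be >= 1", call. = FALSE)
  if (any(slice < 1L) || any(slice > n_slices))
    stop("slice out of range 1..n_slices", call. = FALSE)
  (frame - 1L) * n_slices + slice
}

#' Invert a hyperstack linear index
#'
#' Recovers `(frame, slice)` from the linear stack position produced by
#' [hyperstack_index()].
#'
#' @param index 1-based linear stack index.
#' @param n_slices number of slices per frame.
#' @return list with integer vectors `frame` and `slice`.
#' @export
hyperstack_coords <- function(index, n_slices) {
  if (any(index < 1L)) stop("index must be >= 1", call. = FALSE)
  idx0 <- index - 1L
  list(frame = as.integer(idx0 %/% n_slices + 1L),
       slice = as.integer(idx0 %% n_slices + 1L))
}

#' Extract one voxel's time-activity curve
#'
#' Returns a copy of the TAC at the given coordinates. Following the
#' hyperstack convention, the in-plane coordinates `x`, `y` are 0-based
#' while `slice` is 1-based (`slice = z + 1`). Mutating the returned
#' vector does not alter the image.
#'
#' @param image a [dynamic_image()].
#' @param x,y 0-based in-plane coordinates.
#' @param slice 1-based axial coordinate.
#' @return numeric vector of length `n_frames`.
#' @export
get_tac <- function(image, x, y, slice) {
  stopifnot(inherits(image, "dynamic_image"))
  if (length(x) != 1L || length(y) != 1L || length(slice) != 1L)
    stop("x, y, slice must be scalars", call. = FALSE)
  if (x < 0L || x >= image$n_x || y < 0L || y >= image$n_y ||
      slice < 1L || slice > image$n_z)
    stop(sprintf("voxel (x=%d, y=%d, slice=%d) out of bounds for %dx%dx%d image",
                 x, y, slice, image$n_x, image$n_y, image$n_z), call. = FALSE)
  as.vector(image$data[x + 1L, y + 1L, slice, ])
}

#' Voxel coordinate grid in iteration order
#'
#' The canonical voxel order used throughout the package: `x` varies
#' fastest, then `y`, then `slice`. Every technique, the TAC matrix and
#' the streaming iterator all share this order, so row `i` of
#' [tac_matrix()] is the TAC of voxel `i` here.
#'
#' @param image a [dynamic_image()].
#' @return integer matrix with columns `x` (0-based), `y` (0-based),
#'   `slice` (1-based), one row per voxel.
#' @export
voxel_grid <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  g <- expand.grid(x = seq_len(image$n_x) - 1L,
                   y = seq_len(image$n_y) - 1L,
                   slice = seq_len(image$n_z),
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' All voxel TACs as a matrix
#'
#' @param image a [dynamic_image()].
#' @return numeric matrix, one row per voxel in [voxel_grid()] order, one
#'   column per frame.
#' @export
tac_matrix <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  m <- matrix(as.vector(image$data),
              nrow = image$n_x * image$n_y * image$n_z,
              ncol = image$n_frames)
  colnames(m) <- paste0("frame", seq_len(image$n_frames))
  m
}

#' Stream the image voxel by voxel
#'
#' Yields every voxel exactly once as a list of `voxel` objects (fields
#' `x`, `y`, `slice`, `tac`), in the fixed [voxel_grid()] order — the same
#' sequence on every call, which is what a deterministic streaming
#' technique such as leader-follower requires.
#'
#' @param image a [dynamic_image()].
#' @return list of `voxel` objects, length `n_x * n_y * n_z`.
#' @export
iterate_voxels <- function(image) {
  grid <- voxel_grid(image)
  tacs <- tac_matrix(image)
  lapply(seq_len(nrow(grid)), function(i) {
    structure(list(x = grid[i, 1L], y = grid[i, 2L], slice = grid[i, 3L],
                   tac = tacs[i, ]),
              class = "voxel")
  })
}
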