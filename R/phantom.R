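#' Parametric kinetic models for phantom TACs
#'
#' The two noise-free curve shapes the phantom generator draws from.
#' `gamma_variate_tac` is the classic bolus-passage model
#' `A * (t - t0)^alpha * exp(-(t - t0)/beta)` (0 for `t <= t0`);
#' `biexponential_tac` is the washout model
#' `A1 * exp(-l1 t) + A2 * exp(-l2 t)`.
#'
#' @param t numeric vector of frame times.
#' @param A,t0,alpha,beta gamma-variate amplitude, delay, shape and
#'   decay parameters.
#' @return numeric vector of activities (nonnegative for nonnegative
#'   parameters).
#' @export
gamma_variate_tac <- function(t, A, t0, alpha, beta) {
  tt <- pmax(t - t0, 0)
  A * tt^alpha * exp(-tt / beta)
}

#' @rdname gamma_variate_tac
#' @param A1,A2,l1,l2 biexponential amplitudes and rate constants.
#' @export
biexponential_tac <- function(t, A1, A2, l1, l2) {
  A1 * exp(-l1 * t) + A2 * exp(-l2 * t)
}

#' Noise-free class kinetics for the synthetic phantom
#'
#' Draws one TAC per kinetic class from a parametric tracer model,
#' evaluated at frame times `t = 0, 1, ..., n_frames - 1`:
#' \describe{
#'   \item{`gamma_variate`}{`A * (t - t0)^alpha * exp(-(t - t0)/beta)` for
#'     `t > t0`, 0 before — the classic bolus-passage shape (ventricles,
#'     myocardium). Per-class draws: `A` in \[2, 10\], `t0` in \[0, 2\],
#'     `alpha` in \[0.5, 3\], `beta` in \[1, 5\].}
#'   \item{`biexponential`}{`A1 * exp(-l1 t) + A2 * exp(-l2 t)` — washout
#'     kinetics. Draws: `A1, A2` in \[1, 6\], `l1` in \[0.2, 1\], `l2` in
#'     \[0.01, 0.2\].}
#' }
#' All curves are nonnegative; output is deterministic per seed.
#'
#' @param n_classes number of kinetic classes (>= 1).
#' @param n_frames number of frames (>= 2).
#' @param model `"gamma_variate"` (default) or `"biexponential"`.
#' @param seed integer RNG seed.
#' @return `n_classes x n_frames` matrix, one class TAC per row.
#' @export
make_class_tacs <- function(n_classes, n_frames,
                            model = c("gamma_variate", "biexponential"),
                            seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_classes >= 1L, n_frames >= 2L)
  t <- seq_len(n_frames) - 1
  old <- .seed_rng(seed)
  on.exit(.restore_rng(old), add = TRUE)
  tacs <- matrix(0, n_classes, n_frames)
  for (cl in seq_len(n_classes)) {
    if (model == "gamma_variate") {
      tacs[cl, ] <- gamma_variate_tac(t, A = stats::runif(1, 2, 10),
                                      t0 = stats::runif(1, 0, 2),
                                      alpha = stats::runif(1, 0.5, 3),
                                      beta = stats::runif(1, 1, 5))
    } else {
      tacs[cl, ] <- biexponential_tac(t, A1 = stats::runif(1, 1, 6),
                                      A2 = stats::runif(1, 1, 6),
                                      l1 = stats::runif(1, 0.2, 1),
                                      l2 = stats::runif(1, 0.01, 0.2))
    }
  }
  tacs
}

#' Synthetic 4D kinetic phantom with ground-truth labels
#'
#' Builds a block-structured phantom: the voxel grid is split (in the
#' canonical x-fastest order) into `n_classes` contiguous, near-equal
#' slabs, each carrying one class TAC, plus i.i.d. voxelwise noise. It
#' emulates the piecewise-homogeneous kinetics of a dynamic PET or DCE-MRI
#' study with known ground truth; it does not simulate scanner physics
#' (PSF, attenuation, reconstruction correlations).
#'
#' When `min_separation > 0` (or `max_class_correlation < 1`), the class
#' TACs are redrawn (advancing a deterministic attempt counter from
#' `seed`) until the minimum pairwise Euclidean distance — and, when
#' capped, the maximum pairwise Pearson correlation — between class TACs
#' meets the condition, so tests can state their class-separation
#' conditions as generator inputs. Amplitude separation governs
#' Euclidean-distance clustering; shape decorrelation governs
#' correlation-based clustering (Pearson k-means, leader-follower).
#'
#' @param dims integer vector `(n_x, n_y, n_z, n_frames)`.
#' @param n_classes number of kinetic classes.
#' @param noise_sigma SD of the additive Gaussian noise (`"gaussian"`
#'   mode).
#' @param seed integer RNG seed; the phantom is fully reproducible from
#'   `(dims, n_classes, ..., seed)`.
#' @param model kinetic model passed to [make_class_tacs()].
#' @param min_separation required minimum pairwise Euclidean distance
#'   between class TACs (0 = accept the first draw).
#' @param max_class_correlation required maximum pairwise Pearson
#'   correlation between class TACs (1 = no constraint).
#' @param noise `"gaussian"` (default) or `"poisson"` — the Poisson mode
#'   draws frame counts `~ Pois(TAC * duration)` scaled back to rate
#'   units, for count-statistics realism; it needs `timing`.
#' @param timing optional [frame_timing()] used for Poisson frame
#'   durations.
#' @return list with `image` (a [dynamic_image()]), `labels` (integer 3D
#'   ground-truth volume), `class_tacs`, `separations` (pairwise
#'   Euclidean distance matrix between class TACs), `noise_sigma`, `seed`.
#' @export
generate_phantom <- function(dims = c(16L, 16L, 4L, 10L), n_classes = 4L,
                             noise_sigma = 0.1, seed = 1L,
                             model = "gamma_variate", min_separation = 0,
                             max_class_correlation = 1,
                             noise = c("gaussian", "poisson"),
                             timing = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(dims) == 4L, n_classes >= 1L, noise_sigma >= 0)
  n_vox <- prod(dims[1:3])
  if (n_classes > n_vox)
    stop("more classes than voxels", call. = FALSE)

  tacs <- make_class_tacs(n_classes, dims[4], model = model, seed = seed)
  attempt <- 0L
  sep <- function(m) as.matrix(stats::dist(m))
  ut <- upper.tri(diag(n_classes))
  conditions_met <- function(m) {
    (min_separation <= 0 || min(sep(m)[ut]) >= min_separation) &&
      (max_class_correlation >= 1 || max(stats::cor(t(m))[ut]) <= max_class_correlation)
  }
  while (n_classes > 1L && !conditions_met(tacs)) {
    attempt <- attempt + 1L
    if (attempt > 1000L)
      stop("could not reach the requested class separation in 1000 draws",
           call. = FALSE)
    tacs <- make_class_tacs(n_classes, dims[4], model = model,
                            seed = seed + 7919L * attempt)
  }

  # contiguous near-equal slabs in canonical voxel order
  labels <- as.integer(ceiling(seq_len(n_vox) * n_classes / n_vox))
  label_vol <- array(labels, dim = dims[1:3])

  clean <- tacs[labels, , drop = FALSE]          # n_vox x n_frames
  old <- .seed_rng(seed)
  if (noise == "gaussian") {
    noisy <- clean + if (noise_sigma > 0)
      matrix(stats::rnorm(length(clean), 0, noise_sigma), nrow(clean)) else 0
  } else {
    if (is.null(timing))
      stop("Poisson noise needs a `timing` object for frame durations",
           call. = FALSE)
    if (timing$n_frames != dims[4])
      stop("timing frame count does not match the phantom", call. = FALSE)
    dur <- matrix(timing$ends - timing$starts, nrow(clean), ncol(clean),
                  byrow = TRUE)
    noisy <- matrix(stats::rpois(length(clean), lambda = pmax(clean, 0) * dur),
                    nrow(clean)) / dur
  }
  .restore_rng(old)

  data <- array(noisy, dim = dims)
  list(image = dynamic_image(data), labels = label_vol, class_tacs = tacs,
       separations = sep(tacs), noise_sigma = noise_sigma, seed = seed)
}
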