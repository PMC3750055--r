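#' Distance between two TACs: Pearson correlation distance
#'
#' The correlation distance `1 - r`, with `r` the Pearson correlation of
#' the two curves. It ranges over \[0, 2\]: 0 for perfectly positively
#' correlated shapes (regardless of scale), 2 for perfect anticorrelation.
#' A constant (zero-variance) TAC has no defined correlation with
#' anything; such curves — flat background voxels, typically — are treated
#' as maximally distant and the distance is 2 (0 if both arguments are the
#' identical constant curve, preserving `d(a, a) == 0`).
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return distance in \[0, 2\].
#' @export
pearson_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("TAC length mismatch", call. = FALSE)
  if (length(a) < 2L)
    stop("correlation needs TACs of length >= 2", call. = FALSE)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) {
    if (isTRUE(all.equal(as.numeric(a), as.numeric(b)))) return(0)
    return(2)
  }
  1 - stats::cor(a, b)
}

#' Distance between two TACs: generalized p-norm
#'
#' `(sum_t |a(t) - b(t)|^p)^(1/p)`; `p = 1` is the Manhattan distance,
#' `p = 2` (the default) the Euclidean distance.
#'
#' @param a,b numeric vectors of equal length.
#' @param p norm order, > 0.
#' @return nonnegative distance.
#' @export
pnorm_distance <- function(a, b, p = 2) {
  if (length(a) != length(b))
    stop("TAC length mismatch", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    stop("p must be a positive number", call. = FALSE)
  sum(abs(a - b)^p)^(1 / p)
}

#' Image covariance matrix for the Mahalanobis metric
#'
#' The frames-by-frames sample covariance of the image, taking voxels as
#' observations and frames as variables (unbiased `n - 1` denominator).
#' Computed once per image and reused by every subsequent distance call.
#'
#' @param image a [dynamic_image()] with at least 2 voxels.
#' @return symmetric `n_frames x n_frames` covariance matrix.
#' @export
mahalanobis_init <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  X <- tac_matrix(image)
  if (nrow(X) < 2L)
    stop("covariance needs at least 2 voxels", call. = FALSE)
  stats::cov(X)
}

# Inverse of S, Tikhonov-regularized when S is singular or near-singular:
# image frames are often nearly collinear, so S + eps*I with
# eps = 1e-6 * trace(S)/n_frames keeps the inverse finite while perturbing
# well-conditioned matrices negligibly.
.mahalanobis_inverse <- function(S) {
  inv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    eps <- 1e-6 * sum(diag(S)) / nrow(S)
    if (eps == 0) eps <- 1e-12  # zero-variance image: fall back to scaled identity
    inv <- chol2inv(chol(S + diag(eps, nrow(S))))
  }
  inv
}

#' Distance between two TACs: Mahalanobis distance
#'
#' `sqrt((a - b)' S^-1 (a - b))` with `S` the image covariance matrix from
#' [mahalanobis_init()]. With `S` the identity it reduces to the Euclidean
#' distance; with `S = sigma^2 I`, to Euclidean / sigma. A singular `S` is
#' inverted after light Tikhonov regularization
#' (`S + 1e-6 * trace(S)/n_frames * I`).
#'
#' @param a,b numeric vectors of length `n_frames`.
#' @param S covariance matrix, or the precomputed inverse (pass
#'   `inverse = TRUE` to skip inversion).
#' @param inverse if TRUE, `S` is already the (regularized) inverse.
#' @return nonnegative distance.
#' @export
mahalanobis_distance <- function(a, b, S, inverse = FALSE) {
  if (length(a) != length(b))
    stop("TAC length mismatch", call. = FALSE)
  if (!is.matrix(S) || nrow(S) != length(a) || ncol(S) != length(a))
    stop("S must be an n_frames x n_frames matrix", call. = FALSE)
  inv <- if (inverse) S else .mahalanobis_inverse(S)
  d <- as.numeric(a) - as.numeric(b)
  val <- drop(t(d) %*% inv %*% d)
  sqrt(max(val, 0))
}

#' Construct a pluggable TAC metric
#'
#' A metric object pairs a distance function with its configuration and an
#' optional one-time initialization pass over the whole image
#' ([metric_init()]); techniques call [metric_distance()] afterwards.
#' Built-in names: `"pnorm"` (parameter `p`, default 2), `"pearson"`,
#' `"mahalanobis"` (requires init; caches the inverse image covariance).
#'
#' @param name metric name (case-insensitive), resolved in the registry.
#' @param ... metric parameters, e.g. `p = 1` for the p-norm.
#' @return object of class `tac_metric` with fields `name`,
#'   `requires_init`, `params`, `initialized`, `state`.
#' @export
tac_metric <- function(name, ...) {
  ctor <- registry_get("metrics", name)
  ctor(...)
}

.metric_skeleton <- function(name, requires_init, params, distance_fn,
                             init_fn = NULL, pairwise_fn = NULL) {
  structure(
    list(name = name, requires_init = requires_init, params = params,
         initialized = !requires_init, state = NULL,
         distance_fn = distance_fn, init_fn = init_fn,
         pairwise_fn = pairwise_fn),
    class = "tac_metric"
  )
}

#' @export
print.tac_metric <- function(x, ...) {
  p <- if (length(x$params)) paste0(" (", paste(names(x$params), unlist(x$params),
                                                sep = "=", collapse = ", "), ")") else ""
  cat(sprintf("<tac_metric> %s%s%s\n", x$name, p,
              if (x$requires_init && !x$initialized) " [needs init]" else ""))
  invisible(x)
}

#' One-time metric initialization over the image
#'
#' Called exactly once by a technique before its first
#' [metric_distance()]; metrics that need whole-image statistics (the
#' Mahalanobis covariance) compute and cache them here. Idempotent for
#' metrics that need no init.
#'
#' @param metric a [tac_metric()].
#' @param image the [dynamic_image()] about to be clustered.
#' @return the initialized metric.
#' @export
metric_init <- function(metric, image) {
  stopifnot(inherits(metric, "tac_metric"))
  if (!is.null(metric$init_fn)) metric <- metric$init_fn(metric, image)
  metric$initialized <- TRUE
  metric
}

#' Distance between two TACs under a metric object
#'
#' @param metric an initialized [tac_metric()].
#' @param a,b numeric TAC vectors.
#' @return nonnegative distance.
#' @export
metric_distance <- function(metric, a, b) {
  stopifnot(inherits(metric, "tac_metric"))
  if (!metric$initialized)
    stop(sprintf("metric '%s' used before metric_init()", metric$name),
         call. = FALSE)
  metric$distance_fn(metric, a, b)
}

# Distances from every row of X to every row of C (k x T), vectorized per
# metric where possible. Returns an nrow(X) x nrow(C) matrix.
metric_pairwise <- function(metric, X, C) {
  stopifnot(inherits(metric, "tac_metric"))
  if (!metric$initialized)
    stop(sprintf("metric '%s' used before metric_init()", metric$name),
         call. = FALSE)
  if (!is.null(metric$pairwise_fn)) return(metric$pairwise_fn(metric, X, C))
  out <- matrix(NA_real_, nrow(X), nrow(C))
  for (j in seq_len(nrow(C)))
    out[, j] <- apply(X, 1L, function(row) metric$distance_fn(metric, row, C[j, ]))
  out
}

# ---- built-in metric constructors -----------------------------------------

metric_pnorm_ctor <- function(p = 2) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    stop("p must be a positive number", call. = FALSE)
  pairwise <- if (p == 2) {
    function(metric, X, C) {
      # squared-expansion trick for the Euclidean case
      xx <- rowSums(X^2)
      cc <- rowSums(C^2)
      d2 <- outer(xx, cc, "+") - 2 * X %*% t(C)
      sqrt(pmax(d2, 0))
    }
  } else NULL
  .metric_skeleton("pnorm", FALSE, list(p = p),
                   function(metric, a, b) pnorm_distance(a, b, metric$params$p),
                   pairwise_fn = pairwise)
}

metric_pearson_ctor <- function() {
  pairwise <- function(metric, X, C) {
    sx <- apply(X, 1L, stats::sd)
    sc <- apply(C, 1L, stats::sd)
    Xs <- (X - rowMeans(X))
    Cs <- (C - rowMeans(C))
    r <- (Xs %*% t(Cs)) / (outer(sx, sc) * (ncol(X) - 1L))
    d <- 1 - r
    # zero-variance rows: maximally distant (flat voxels join no kinetic class)
    d[!is.finite(d)] <- 2
    d
  }
  .metric_skeleton("pearson", FALSE, list(),
                   function(metric, a, b) pearson_distance(a, b),
                   pairwise_fn = pairwise)
}

metric_mahalanobis_ctor <- function() {
  init <- function(metric, image) {
    S <- mahalanobis_init(image)
    metric$state <- list(S = S, S_inv = .mahalanobis_inverse(S))
    metric
  }
  dist_fn <- function(metric, a, b)
    mahalanobis_distance(a, b, metric$state$S_inv, inverse = TRUE)
  pairwise <- function(metric, X, C) {
    # d^2 = (x-c)' Sinv (x-c), expanded with the whitening product
    Sinv <- metric$state$S_inv
    XS <- X %*% Sinv
    CS <- C %*% Sinv
    d2 <- outer(rowSums(XS * X), rowSums(CS * C), "+") - 2 * X %*% t(CS)
    sqrt(pmax(d2, 0))
  }
  .metric_skeleton("mahalanobis", TRUE, list(), dist_fn,
                   init_fn = init, pairwise_fn = pairwise)
}
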