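# Package-level plugin registry. Built-ins are registered at load time;
# third-party packages (or scripts) add entries with register_technique()/
# register_metric() without touching core code — the moral equivalent of
# the original framework's classpath autodetection.
.registry <- new.env(parent = emptyenv())

.registry_reset <- function() {
  assign("techniques", list(), envir = .registry)
  assign("metrics", list(), envir = .registry)
  register_metric("pnorm", metric_pnorm_ctor)
  register_metric("pearson", metric_pearson_ctor)
  register_metric("mahalanobis", metric_mahalanobis_ctor)
  register_technique("kmeans", function(image, metric = NULL, k = 2L,
                                        max_iter = 100L, seed = 1L,
                                        init = "plusplus", ...) {
    if (is.null(metric)) metric <- tac_metric("pnorm", p = 2)
    tac_kmeans(image, k = k, metric = metric, max_iter = max_iter,
               seed = seed, init = init)
  })
  register_technique("leaderfollower", function(image, metric = NULL,
                                                threshold = 0.3,
                                                max_clusters = Inf, ...) {
    leader_follower(image, threshold = threshold, max_clusters = max_clusters)
  })
  register_technique("pca", function(image, metric = NULL, ...)
    pca_technique(image))
  register_technique("svd", function(image, metric = NULL, ...)
    svd_technique(image))
  register_technique("ica", function(image, metric = NULL, n_components = 2L,
                                     seed = 1L, max_iter = 200L,
                                     tol = 1e-6, ...) {
    ica_technique(image, n_components = n_components, seed = seed,
                  max_iter = max_iter, tol = tol)
  })
  invisible(NULL)
}

.registry_table <- function(kind) get(kind, envir = .registry)

registry_put <- function(kind, name, ctor, overwrite = FALSE) {
  stopifnot(is.function(ctor))
  key <- tolower(name)
  tab <- .registry_table(kind)
  if (!overwrite && key %in% names(tab))
    stop(sprintf("a %s named '%s' is already registered", sub("s$", "", kind),
                 key), call. = FALSE)
  tab[[key]] <- ctor
  assign(kind, tab, envir = .registry)
  invisible(key)
}

#' Resolve a registered technique or metric constructor by name
#'
#' @param kind `"techniques"` or `"metrics"`.
#' @param name case-insensitive plugin name.
#' @return the registered constructor function.
#' @export
registry_get <- function(kind = c("techniques", "metrics"), name) {
  kind <- match.arg(kind)
  tab <- .registry_table(kind)
  key <- tolower(name)
  if (!key %in% names(tab))
    stop(sprintf("unknown %s '%s'; available: %s", sub("s$", "", kind), name,
                 paste(sort(names(tab)), collapse = ", ")), call. = FALSE)
  tab[[key]]
}

#' Register a clustering technique plugin
#'
#' The constructor must be a function `(image, metric, ...)` returning a
#' [cluster_result()]. Names are case-insensitive and must be unique.
#'
#' @param name plugin name.
#' @param constructor technique function.
#' @param overwrite replace an existing entry of the same name.
#' @return the normalized name, invisibly.
#' @export
register_technique <- function(name, constructor, overwrite = FALSE)
  registry_put("techniques", name, constructor, overwrite)

#' Register a TAC metric plugin
#'
#' The constructor must be a function of the metric's parameters returning
#' a `tac_metric` object (see [tac_metric()]).
#'
#' @param name plugin name.
#' @param constructor metric constructor.
#' @param overwrite replace an existing entry of the same name.
#' @return the normalized name, invisibly.
#' @export
register_metric <- function(name, constructor, overwrite = FALSE)
  registry_put("metrics", name, constructor, overwrite)

#' List registered techniques
#' @return sorted character vector of technique names.
#' @export
list_techniques <- function() sort(names(.registry_table("techniques")))

#' List registered metrics
#' @return sorted character vector of metric names.
#' @export
list_metrics <- function() sort(names(.registry_table("metrics")))

.onLoad <- function(libname, pkgname) .registry_reset()
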