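#' Run the full clustering pipeline
#'
#' The end-to-end workflow: load the 4D image, build and initialize the
#' metric (its one-time `init()` pass runs exactly once, before any
#' distance evaluation), run the selected technique, and write the
#' outputs to `out_dir`:
#' \itemize{
#'   \item `<stem>_labels.nii.gz` — the pseudo-dynamic `n+1`-frame label
#'     image ([write_label_image()]);
#'   \item `<stem>_tacs.<ext>` — cluster mean TACs with frame timing
#'     ([write_tac_table()]), `<ext>` = csv/tsv/tac;
#'   \item `<stem>_tacs_info.txt` — the technique's extra info lines, if
#'     any;
#'   \item `<stem>_extra_<name>.nii.gz` — any extra images (component
#'     score maps).
#' }
#'
#' @param image_path path to the dynamic image, or a [dynamic_image()].
#' @param technique technique name (see [list_techniques()]).
#' @param metric optional metric name (see [list_metrics()]); techniques
#'   that take no metric ignore it.
#' @param params named list of technique/metric parameters (e.g.
#'   `list(k = 10, init = "plusplus", p = 2)`); metric parameters are the
#'   ones named in the metric constructor's signature.
#' @param timing_path optional path to a frame timing file.
#' @param out_dir output directory, created if missing.
#' @param format TAC table dialect: `"csv"`, `"tsv"` or `"pmod"`.
#' @param seed integer seed forwarded to stochastic techniques.
#' @param stem basename stem for output files (default: image file stem,
#'   or `"clustering"` for in-memory images).
#' @param verbose print progress and cluster sizes.
#' @return invisibly, a list with the `result` ([cluster_result()]) and
#'   the paths of all written `files`.
#' @export
run_pipeline <- function(image_path, technique, metric = NULL,
                         params = list(), timing_path = NULL,
                         out_dir = ".", format = c("csv", "tsv", "pmod"),
                         seed = 1L, stem = NULL, verbose = FALSE) {
  format <- match.arg(format)
  t_start <- proc.time()[["elapsed"]]

  if (inherits(image_path, "dynamic_image")) {
    image <- image_path
    if (is.null(stem)) stem <- "clustering"
  } else {
    image <- read_dynamic_image(image_path)
    if (is.null(stem))
      stem <- tools::file_path_sans_ext(basename(sub("\\.gz$", "", image_path)))
  }
  if (verbose)
    message(sprintf("image: %dx%dx%d voxels, %d frames",
                    image$n_x, image$n_y, image$n_z, image$n_frames))

  timing <- if (!is.null(timing_path))
    parse_timing_file(timing_path, image$n_frames) else NULL

  tech_ctor <- registry_get("techniques", technique)
  metric_obj <- NULL
  if (!is.null(metric)) {
    metric_ctor <- registry_get("metrics", metric)
    metric_args <- params[names(params) %in% names(formals(metric_ctor))]
    metric_obj <- do.call(metric_ctor, metric_args)
    metric_obj <- metric_init(metric_obj, image)
  }

  tech_args <- c(list(image = image, metric = metric_obj),
                 params[names(params) %in% setdiff(names(formals(tech_ctor)),
                                                   c("image", "metric", "..."))])
  unknown <- setdiff(names(params),
                     c(names(formals(tech_ctor)),
                       if (!is.null(metric)) names(formals(registry_get("metrics", metric)))))
  if (length(unknown))
    stop(sprintf("unknown parameter(s) %s for technique '%s'; valid: %s",
                 paste(unknown, collapse = ", "), technique,
                 paste(setdiff(names(formals(tech_ctor)),
                               c("image", "metric", "...")), collapse = ", ")),
         call. = FALSE)
  if ("seed" %in% names(formals(tech_ctor)) && !"seed" %in% names(tech_args))
    tech_args$seed <- seed
  result <- do.call(tech_ctor, tech_args)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ext <- switch(format, csv = "csv", tsv = "tsv", pmod = "tac")
  files <- character(0)

  label_path <- file.path(out_dir, paste0(stem, "_labels.nii.gz"))
  write_label_image(result, label_path)
  files <- c(files, label_path)

  tac_path <- file.path(out_dir, paste0(stem, "_tacs.", ext))
  write_tac_table(result, tac_path, timing = timing, format = format)
  files <- c(files, tac_path)
  if (!is.null(result$extra_info))
    files <- c(files, file.path(out_dir, paste0(stem, "_tacs_info.txt")))

  for (nm in names(result$extra_images)) {
    p <- file.path(out_dir, paste0(stem, "_extra_", nm, ".nii.gz"))
    RNifti::writeNifti(result$extra_images[[nm]], p, datatype = "double")
    files <- c(files, p)
  }

  if (verbose) {
    sizes <- vapply(result$clusters, function(cl) cl$size, integer(1))
    message(sprintf("clusters: %d (sizes %s)", result$n_clusters,
                    paste(sizes, collapse = ", ")))
    message(sprintf("elapsed: %.2f s", proc.time()[["elapsed"]] - t_start))
  }
  invisible(list(result = result, files = files))
}
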