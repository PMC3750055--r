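#' Read a 4D dynamic image
#'
#' Loads a NIfTI-1 (`.nii`, `.nii.gz`) or Analyze 7.5 (`.hdr`/`.img`)
#' volume as a [dynamic_image()]. The file must contain a temporal
#' sequence: a plain 3D volume (or a 4D volume with a single frame) is
#' rejected with a static-image error, since a static image has no
#' kinetics to cluster. 2D+time acquisitions load with `n_z = 1`.
#' Frame durations are never mined from image metadata — supply a timing
#' file ([parse_timing_file()]) for kinetic output.
#'
#' @param path path to the image file.
#' @return a [dynamic_image()].
#' @export
read_dynamic_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dir.exists(path))
    stop("DICOM series directories are not supported; convert the series to NIfTI first",
         call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (!ext %in% c("nii", "hdr", "img"))
    stop(sprintf("unrecognized image format '.%s' (expected .nii, .nii.gz or Analyze .hdr/.img)",
                 ext), call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  nd <- length(dim(arr))
  if (nd < 3L || nd > 4L)
    stop(sprintf("expected a 3D+time image, got a %dD array", nd), call. = FALSE)
  if (nd == 3L || dim(arr)[4] < 2L)
    stop("static image: the input has no time axis (or a single frame); a dynamic image is required",
         call. = FALSE)
  dynamic_image(arr)
}

#' Write a dynamic image or phantom to NIfTI
#'
#' @param image a [dynamic_image()] or a numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type (default `"double"` for lossless
#'   round-trips).
#' @return the path, invisibly.
#' @export
write_dynamic_image <- function(image, path, datatype = "double") {
  arr <- if (inherits(image, "dynamic_image")) image$data else image
  RNifti::writeNifti(arr, path, datatype = datatype)
  invisible(path)
}

#' Frame timing table
#'
#' Start and end times (seconds) of each frame of the dynamic
#' acquisition, required by downstream kinetic analysis because frame
#' durations are not read from image metadata.
#'
#' @param starts,ends numeric vectors of frame start/end times in
#'   seconds; same length, `starts[i] < ends[i]`, starts non-decreasing.
#' @return object of class `frame_timing` with fields `starts`, `ends`,
#'   `n_frames`.
#' @export
frame_timing <- function(starts, ends) {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (length(starts) != length(ends))
    stop("starts and ends must have the same length", call. = FALSE)
  if (any(starts >= ends))
    stop("every frame must have start < end", call. = FALSE)
  if (is.unsorted(starts))
    stop("frame start times must be non-decreasing", call. = FALSE)
  structure(list(starts = starts, ends = ends, n_frames = length(starts)),
            class = "frame_timing")
}

#' Parse a frame timing file
#'
#' Reads a two-column text file of frame start and end times (seconds),
#' one row per frame, separated by tabs or any run of spaces. Blank lines
#' and lines starting with `#` are ignored. The row count must equal the
#' expected number of frames.
#'
#' @param path path to the timing file.
#' @param n_frames expected number of frames.
#' @return a [frame_timing()].
#' @export
parse_timing_file <- function(path, n_frames) {
  if (!file.exists(path))
    stop(sprintf("timing file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) != n_frames)
    stop(sprintf("timing file has %d rows but the image has %d frames",
                 length(keep), n_frames), call. = FALSE)
  starts <- numeric(n_frames); ends <- numeric(n_frames)
  for (i in seq_along(keep)) {
    tok <- strsplit(trimws(lines[keep[i]]), "[ \t]+")[[1]]
    if (length(tok) != 2L)
      stop(sprintf("timing file line %d: expected 2 columns, got %d",
                   keep[i], length(tok)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(tok))
    if (any(is.na(vals)))
      stop(sprintf("timing file line %d: non-numeric token '%s'",
                   keep[i], tok[which(is.na(vals))[1]]), call. = FALSE)
    starts[i] <- vals[1]; ends[i] <- vals[2]
  }
  if (any(starts >= ends)) {
    bad <- which(starts >= ends)[1]
    stop(sprintf("timing file row %d: start (%g) must be < end (%g)",
                 bad, starts[bad], ends[bad]), call. = FALSE)
  }
  frame_timing(starts, ends)
}

#' Write a frame timing file
#'
#' @param timing a [frame_timing()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_timing_file <- function(timing, path) {
  stopifnot(inherits(timing, "frame_timing"))
  writeLines(sprintf("%.17g\t%.17g", timing$starts, timing$ends), path)
  invisible(path)
}

#' Write the pseudo-dynamic label image
#'
#' The display convention for a clustering of `n` clusters: a 4D NIfTI
#' with `n + 1` frames where frame `k` (`k = 1..n`) is zero everywhere
#' except the voxels of cluster `k`, which carry the value `k`, and frame
#' `n + 1` is the composite label volume (every voxel carries its cluster
#' number, 0 if unassigned). Stored as 16-bit unsigned integers.
#'
#' @param result a [cluster_result()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_label_image <- function(result, path) {
  stopifnot(inherits(result, "cluster_result"))
  lab <- result$label_volume
  n <- result$n_clusters
  out <- array(0L, dim = c(dim(lab), n + 1L))
  for (k in seq_len(n)) {
    frame <- array(0L, dim = dim(lab))
    frame[lab == k] <- k
    out[, , , k] <- frame
  }
  out[, , , n + 1L] <- lab
  RNifti::writeNifti(out, path, datatype = "uint16")
  invisible(path)
}

#' Write cluster mean TACs as a table
#'
#' One row per frame; the first two columns are the frame start and end
#' times from `timing` (or, when no timing is available, the frame
#' indices `0..n-1` and `1..n` as a documented fallback), followed by one
#' column per cluster mean TAC. Dialects: `"csv"` (comma separator,
#' header `start,end,cluster1,...`), `"tsv"` (same with tabs), `"pmod"`
#' (tab-separated with the PMOD .tac header
#' `start[seconds]  end[seconds]  cluster1 ...`). Values are written at
#' full float64 precision so the table round-trips losslessly. If the
#' result carries `extra_info` lines they are written next to the table
#' as `<stem>_info.txt`.
#'
#' @param result a [cluster_result()].
#' @param path output path.
#' @param timing optional [frame_timing()] matching the TAC length.
#' @param format `"csv"`, `"tsv"` or `"pmod"`.
#' @return the path, invisibly.
#' @export
write_tac_table <- function(result, path, timing = NULL,
                            format = c("csv", "tsv", "pmod")) {
  stopifnot(inherits(result, "cluster_result"))
  format <- match.arg(format)
  tacs <- cluster_mean_tacs(result)
  n_frames <- nrow(tacs)
  if (!is.null(timing)) {
    stopifnot(inherits(timing, "frame_timing"))
    if (timing$n_frames != n_frames)
      stop(sprintf("timing has %d frames but the TACs have %d",
                   timing$n_frames, n_frames), call. = FALSE)
    starts <- timing$starts; ends <- timing$ends
  } else {
    starts <- seq_len(n_frames) - 1; ends <- seq_len(n_frames)
  }
  sep <- if (format == "csv") "," else "\t"
  cols <- colnames(tacs)
  header <- if (format == "pmod")
    paste(c("start[seconds]", "end[seconds]", cols), collapse = sep)
  else paste(c("start", "end", cols), collapse = sep)
  body <- vapply(seq_len(n_frames), function(i) {
    paste(sprintf("%.17g", c(starts[i], ends[i], tacs[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  if (!is.null(result$extra_info)) {
    info_path <- file.path(dirname(path),
                           paste0(tools::file_path_sans_ext(basename(path)),
                                  "_info.txt"))
    writeLines(result$extra_info, info_path)
  }
  invisible(path)
}

#' Read back a TAC table written by [write_tac_table()]
#'
#' @param path path to the table.
#' @param format `"csv"`, `"tsv"` or `"pmod"`.
#' @return data.frame with columns `start`, `end`, `cluster1`, ...
#' @export
read_tac_table <- function(path, format = c("csv", "tsv", "pmod")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  names(df)[1:2] <- c("start", "end")
  df
}
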