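# Plain-file interfaces: multi-page TIFF stacks with a YAML sidecar (the
# TIFF writer stores 32-bit float samples in [0, 1], so stacks are scaled
# by their peak on write and the scale recorded in the sidecar), CSV
# traces and maps.

#' Write / read an image stack as multi-page TIFF
#'
#' One 32-bit float page per timepoint.  Values are divided by the stack
#' peak before writing (the TIFF writer requires samples in `[0, 1]`); the
#' scale factor and any extra metadata are stored in a YAML sidecar
#' (`<path>.yml`), and `read_stack_tiff()` undoes the scaling when the
#' sidecar is present.
#'
#' @param stack A size x size x time array, or a `ground_truth_stack`,
#'   `raw_frame_stack` or `hr_stack`.
#' @param path Output TIFF path.
#' @param metadata Named list of extra fields for the sidecar.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns a list with `frames` (3D array) and `metadata`.
#' @export
write_stack_tiff <- function(stack, path, metadata = list()) {
  frames <- if (is.array(stack) && length(dim(stack)) == 3L) stack
            else stack$frames
  peak <- max(frames, 0)
  scale <- if (peak > 0) peak else 1
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(t) frames[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- c(list(scale = scale, n_frames = dim(frames)[3],
                 size = dim(frames)[1]), metadata)
  if (inherits(stack, "raw_frame_stack")) {
    meta <- c(meta, list(angles = stack$angles, phases = stack$phases,
                         fringe_period = stack$fringe_period,
                         modulation_depth = stack$modulation_depth,
                         cutoff = stack$cutoff, seed = stack$seed,
                         noise_applied = stack$noise_applied))
  }
  yaml::write_yaml(meta, paste0(path, ".yml"), precision = 17L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- nrow(pages[[1]])
  frames <- array(unlist(pages), dim = c(n, ncol(pages[[1]]), length(pages)))
  meta <- list()
  sidecar <- paste0(path, ".yml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$scale)) frames <- frames * meta$scale
  }
  list(frames = frames, metadata = meta)
}

#' Rebuild a raw frame stack from a TIFF and its sidecar
#'
#' Ingests an externally stored (or previously exported) raw SIM stack for
#' metric-only runs.  The sidecar must record the acquisition parameters
#' (`angles`, `phases`, `fringe_period`, `modulation_depth`, `cutoff`).
#'
#' @param path TIFF path with a `<path>.yml` sidecar.
#' @return A `raw_frame_stack`.
#' @export
read_raw_stack <- function(path) {
  x <- read_stack_tiff(path)
  m <- x$metadata
  need <- c("angles", "phases", "fringe_period", "modulation_depth",
            "cutoff")
  missing <- need[!need %in% names(m)]
  if (length(missing)) {
    stop("sidecar lacks acquisition metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- dim(x$frames)[1]
  theta <- unlist(m$angles) * pi / 180
  structure(
    list(frames = x$frames,
         pattern_index = (seq_len(dim(x$frames)[3]) - 1L) %% 9L,
         noise_applied = isTRUE(m$noise_applied), seed = m$seed %||% NA,
         n_frames = dim(x$frames)[3], size = n,
         angles = unlist(m$angles), phases = unlist(m$phases),
         fringe_period = m$fringe_period,
         modulation_depth = m$modulation_depth,
         kvec = cbind(x = (n / m$fringe_period) * cos(theta),
                      y = (n / m$fringe_period) * sin(theta)),
         cutoff = m$cutoff),
    class = "raw_frame_stack"
  )
}

#' Export a modulation trace as CSV
#'
#' Two columns: `frame` (1-based, matching figure conventions) and `GTm`.
#'
#' @param trace A `modulation_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "modulation_trace"))
  utils::write.csv(
    data.frame(frame = seq_len(trace$n_frames), GTm = trace$values),
    path, row.names = FALSE)
  invisible(path)
}

#' Export the OTF as a single-page TIFF
#'
#' @param otf An `otf_model`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_otf_tiff <- function(otf, path) {
  stopifnot(inherits(otf, "otf_model"))
  tiff::writeTIFF(otf$transfer, path, bits.per.sample = 32L)
  invisible(path)
}

#' Export a spatiotemporal map as CSV
#'
#' Rows are radial bins, columns are modulation periods; the header row
#' carries the period axis and the first column the radius axis.
#'
#' @param map A `spatiotemporal_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "spatiotemporal_map"))
  df <- as.data.frame(map$matrix)
  names(df) <- paste0("Tm_", map$periods)
  df <- cbind(radius = map$radii, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spatiotemporal map written by [write_map_csv()]
#'
#' @param path CSV path.
#' @param metric,scheme Labels to attach (not stored in the CSV).
#' @return A `spatiotemporal_map`.
#' @export
read_map_csv <- function(path, metric = "rmse", scheme = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  periods <- as.numeric(sub("^Tm_", "", names(df)[-1]))
  structure(
    list(matrix = unname(as.matrix(df[, -1, drop = FALSE])),
         periods = periods, radii = df$radius, metric = metric,
         scheme = scheme, meta = NULL, failed = numeric(0)),
    class = "spatiotemporal_map"
  )
}
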