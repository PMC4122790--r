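#' @title Image sequence loading and frame metadata
#'
#' @description A movie is stored as one directory of raster images per
#'   channel (phase contrast plus up to three fluorescence channels).  Frames
#'   are ordered by the last integer group in the filename (ties broken
#'   lexicographically).  Alongside the originals, an 8-bit working copy is
#'   produced by one global min-max linear rescale over the whole sequence,
#'   so intensity dynamics across frames survive in the copy; measurements
#'   are always taken on the originals.
#'
#' @name imaging_io
NULL

CHANNEL_NAMES <- c("phase", "ch1", "ch2", "ch3")

#' Read one raster image as a numeric matrix
#'
#' PNG (assumed 8-bit, values 0..255) and TIFF (read at original bit depth)
#' are supported.  Multi-channel rasters are averaged to one grey plane.
#'
#' @param path file path
#' @return numeric matrix, rows = image rows
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE)
      storage.mode(x) <- "double"
      x
    },
    stop("unsupported raster format: ", ext)),
    error = function(e) stop("cannot read image file '", path, "': ",
                             conditionMessage(e)))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

# Frame index parsed from the last integer group in the filename.
parse_frame_index <- function(filenames) {
  base <- tools::file_path_sans_ext(basename(filenames))
  m <- regmatches(base, gregexpr("[0-9]+", base))
  vapply(m, function(g) if (length(g)) as.numeric(g[length(g)]) else NA_real_,
         numeric(1))
}

#' Load a channel's image sequence
#'
#' @param directory folder containing the frames of one channel
#' @param channel channel label, one of `"phase"`, `"ch1"`, `"ch2"`, `"ch3"`
#' @param pixel_size_um microns per pixel (> 0)
#' @param times optional per-frame acquisition times in minutes (strictly
#'   increasing); defaults to `dt_min * (0:(n-1))`
#' @param dt_min frame interval in minutes used when `times` is missing
#' @return a `frame_stack`: list with `channel`, `images` (8-bit working
#'   copies), `originals`, `time_min`, `excluded`, `note`, `pixel_size_um`
#' @export
load_sequence <- function(directory, channel = "phase", pixel_size_um = 1,
                          times = NULL, dt_min = 1) {
  channel <- match.arg(channel, CHANNEL_NAMES)
  files <- list.files(directory, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0) stop("no raster images found in ", directory)
  idx <- parse_frame_index(files)
  files <- files[order(idx, basename(files))]
  originals <- lapply(files, read_raster)
  dims <- vapply(originals, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension-mismatch: images in ", directory,
         " do not all share the same height and width")
  frame_stack(originals, channel = channel, pixel_size_um = pixel_size_um,
              times = times, dt_min = dt_min, source_files = files)
}

#' Build a frame stack from in-memory images
#'
#' @param originals list of numeric matrices (original bit depth)
#' @inheritParams load_sequence
#' @param source_files optional file paths the frames came from
#' @return a `frame_stack`
#' @export
frame_stack <- function(originals, channel = "phase", pixel_size_um = 1,
                        times = NULL, dt_min = 1, source_files = NULL) {
  channel <- match.arg(channel, CHANNEL_NAMES)
  n <- length(originals)
  if (n == 0) stop("empty image sequence")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  if (is.null(times)) times <- dt_min * (seq_len(n) - 1)
  if (length(times) != n || any(diff(times) <= 0))
    stop("frame times must be strictly increasing, one per frame")
  rng <- range(unlist(lapply(originals, range)))
  images <- lapply(originals, function(o) {
    if (rng[2] > rng[1]) round((o - rng[1]) * (255 / (rng[2] - rng[1])))
    else o * 0
  })
  structure(list(channel = channel, images = images, originals = originals,
                 time_min = as.numeric(times),
                 excluded = rep(FALSE, n),
                 note = rep(NA_character_, n),
                 pixel_size_um = pixel_size_um,
                 source_files = source_files),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf(
    "<frame_stack '%s': %d frames of %dx%d px, %.4g um/px, %d excluded>\n",
    x$channel, length(x$images), d[1], d[2], x$pixel_size_um,
    sum(x$excluded)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `frame_stack`
#' @return integer
#' @export
n_frames <- function(stack) length(stack$images)

#' Update per-frame metadata
#'
#' Frames marked excluded stay in the stack (exclusion is non-destructive)
#' but are skipped by segmentation and measurement.
#'
#' @param stack a `frame_stack`
#' @param frame_index 0-based frame index
#' @param time_min,excluded,note new values; omit to leave unchanged
#' @return the updated `frame_stack`
#' @export
set_frame_metadata <- function(stack, frame_index, time_min = NULL,
                               excluded = NULL, note = NULL) {
  i <- frame_index + 1L
  if (frame_index < 0 || i > n_frames(stack))
    stop("frame index ", frame_index, " out of range")
  if (!is.null(time_min)) {
    tm <- stack$time_min
    tm[i] <- time_min
    if (any(diff(tm) <= 0))
      stop("frame times must remain strictly increasing")
    stack$time_min <- tm
  }
  if (!is.null(excluded)) stack$excluded[i] <- isTRUE(excluded)
  if (!is.null(note)) stack$note[i] <- as.character(note)
  stack
}

#' Indices of frames that should be processed
#' @param stack a `frame_stack`
#' @return 0-based indices of the non-excluded frames
#' @export
active_frames <- function(stack) which(!stack$excluded) - 1L

#' Write the 8-bit working copies as a PNG sequence
#'
#' @param stack a `frame_stack`
#' @param directory output folder (created if missing)
#' @return invisibly, the written file paths
#' @export
save_working_copies <- function(stack, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory,
                     sprintf("%s_%04d.png", stack$channel,
                             seq_len(n_frames(stack)) - 1L))
  for (i in seq_along(paths))
    png::writePNG(pmin(pmax(stack$images[[i]], 0), 255) / 255, paths[i])
  invisible(paths)
}
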