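#' @title Quantitative measurements
#'
#' @description Per-cell, per-frame, per-channel statistics are always taken
#'   on the original images (any bit depth); the 8-bit working copies exist
#'   only for tracking.  The mask can be eroded before measuring (e.g. to
#'   exclude the membrane region from cytoplasmic fluorescence), and a
#'   user-defined cell-free background region provides a per-frame,
#'   per-channel scalar that is subtracted from cell means to give the
#'   background-corrected variables.  Cell length is the skeleton pixel
#'   count times the pixel size, a definition consistent with the tracking
#'   algorithm's skeleton machinery (and accordingly imprecise near the
#'   poles, by about the cell-width radius).
#'
#' @name measurements
NULL

#' Measure one region on one image
#'
#' @param mask a [pixel_mask()]
#' @param img numeric matrix, the original image
#' @param erode_px radius of the erosion disk applied before measuring
#' @return list with `area_px`, `mean`, `sd`, `min`, `max`, `integrated`
#'   (`mean * area_px`) computed over the (eroded) pixel set
#' @export
measure_roi <- function(mask, img, erode_px = 0L) {
  m <- mask_to_logical(mask, dim(img))
  if (erode_px > 0) m <- erode_disk(m, erode_px)
  if (!any(m))
    stop("erosion-too-large: mask is empty after erosion by ", erode_px)
  v <- img[m]
  list(area_px = sum(m), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       min = min(v), max = max(v), integrated = mean(v) * sum(m))
}

#' Measure and store the background means
#'
#' Computes the mean of the background region on every requested frame and
#' channel of the original images and stores the values.  Warns, listing
#' the frames, if the background region overlaps any saved cell mask.
#'
#' @param prj a `bt_project` with a background region set (see
#'   [set_background_roi()]) and channels attached
#' @param channels channels to measure (default: all attached)
#' @param frames 0-based frames (default: all non-excluded)
#' @return data.frame `frame`, `channel`, `value`, invisibly
#' @export
measure_background <- function(prj, channels = names(prj$stacks),
                               frames = NULL) {
  bg <- get_background_roi(prj)
  if (is.null(bg)) stop("no background region defined")
  if (is.null(frames)) frames <- active_frames(prj$stacks[[1]])
  overlap <- DBI::dbGetQuery(prj$db, "SELECT frame, rle_mask FROM roi")
  bad <- unique(overlap$frame[vapply(overlap$rle_mask, function(r)
    !masks_disjoint(bg, mask_from_rle(r)), logical(1))])
  if (length(bad))
    warning("background region overlaps cell masks in frame(s) ",
            paste(sort(bad), collapse = ", "))
  out <- list()
  for (ch in channels) {
    st <- prj$stacks[[ch]]
    bgm <- mask_to_logical(bg, dim(st$originals[[1]]))
    for (f in frames) {
      val <- mean(st$originals[[f + 1L]][bgm])
      DBI::dbExecute(prj$db,
        "INSERT OR REPLACE INTO background_mean VALUES (?, ?, ?)",
        params = list(as.integer(f), ch, val))
      out[[length(out) + 1L]] <- data.frame(frame = f, channel = ch,
                                            value = val)
    }
  }
  invisible(do.call(rbind, out))
}

background_mean_at <- function(prj, frame, channel) {
  row <- DBI::dbGetQuery(prj$db,
    "SELECT value FROM background_mean WHERE frame = ? AND channel = ?",
    params = list(as.integer(frame), channel))
  if (nrow(row) == 0) NA_real_ else row$value[1]
}

#' Measure all saved regions of a project
#'
#' Iterates over every saved ROI on the requested frames, measuring each
#' channel's original image, and writes the results to the measurement
#' table in long format.  Geometric variables (`area_px`, `area_um2`,
#' `length_um`) are stored once per ROI under the pseudo-channel `"geom"`.
#' When a background region has been measured, `mean_corrected` rows
#' (`mean - background mean`) are written as well; without a background
#' they are absent, not zero.
#'
#' @param prj a `bt_project`
#' @param channels fluorescence channels to measure (default all attached)
#' @param frames 0-based frames (default all non-excluded)
#' @param erode_px erosion radius applied to each mask before intensity
#'   statistics (geometry is always measured on the full mask)
#' @return number of measurement rows written, invisibly
#' @export
measure_cells <- function(prj, channels = names(prj$stacks), frames = NULL,
                          erode_px = 0L) {
  if (is.null(frames)) frames <- active_frames(prj$stacks[[1]])
  px <- project_pixel_size(prj)
  rois <- DBI::dbGetQuery(prj$db,
    "SELECT cell, frame, rle_mask FROM roi ORDER BY frame, cell")
  rois <- rois[rois$frame %in% frames, , drop = FALSE]
  dims <- dim(prj$stacks[[1]]$originals[[1]])
  n <- 0L
  put <- function(cell, frame, channel, variable, value) {
    DBI::dbExecute(prj$db,
      "INSERT OR REPLACE INTO measurement VALUES (?, ?, ?, ?, ?)",
      params = list(cell, as.integer(frame), channel, variable, value))
  }
  for (i in seq_len(nrow(rois))) {
    cell <- rois$cell[i]; f <- rois$frame[i]
    mask <- mask_from_rle(rois$rle_mask[i], f)
    mimg <- mask_to_logical(mask, dims)
    skel_len <- sum(thin(mimg))
    put(cell, f, "geom", "area_px", nrow(mask))
    put(cell, f, "geom", "area_um2", nrow(mask) * px^2)
    put(cell, f, "geom", "length_um", skel_len * px)
    n <- n + 3L
    for (ch in channels) {
      if (ch == "geom" || is.null(prj$stacks[[ch]])) next
      stt <- measure_roi(mask, prj$stacks[[ch]]$originals[[f + 1L]],
                         erode_px)
      for (v in c("mean", "sd", "min", "max", "integrated")) {
        put(cell, f, ch, v, stt[[v]])
        n <- n + 1L
      }
      bgv <- background_mean_at(prj, f, ch)
      if (!is.na(bgv)) {
        put(cell, f, ch, "mean_corrected", stt$mean - bgv)
        n <- n + 1L
      }
    }
  }
  log_event(prj, "measure", NA, list(channels = paste(channels,
    collapse = ","), erode_px = erode_px))
  invisible(n)
}

measurement_values <- function(prj, cell, variable, channel = NULL) {
  if (is.null(channel)) {
    DBI::dbGetQuery(prj$db,
      "SELECT m.frame, f.time_min, m.value FROM measurement m
       JOIN frame f ON f.frame_index = m.frame
       WHERE m.cell = ? AND m.variable = ? ORDER BY m.frame",
      params = list(cell, variable))
  } else {
    DBI::dbGetQuery(prj$db,
      "SELECT m.frame, f.time_min, m.value FROM measurement m
       JOIN frame f ON f.frame_index = m.frame
       WHERE m.cell = ? AND m.variable = ? AND m.channel = ?
       ORDER BY m.frame",
      params = list(cell, variable, channel))
  }
}

#' Growth rates of one cell
#'
#' Two complementary definitions are reported, both least-squares fits over
#' the cell's measured lifetime: the linear elongation rate (slope of
#' length versus time, um/h) and the exponential area growth rate (slope
#' of `log(area_um2)` versus time, 1/h).
#'
#' @param prj a `bt_project` with measurements taken
#' @param cell cell name
#' @return list with `elongation_um_per_h`, `exp_area_per_h`, and `n_frames`
#' @export
growth_rate <- function(prj, cell) {
  get_cell(prj, cell)
  len <- measurement_values(prj, cell, "length_um", "geom")
  area <- measurement_values(prj, cell, "area_um2", "geom")
  if (nrow(len) < 2)
    stop("not-defined: need measurements on at least 2 frames for '",
         cell, "'")
  th <- len$time_min / 60
  lin <- unname(coef(lm(len$value ~ th))[2])
  tha <- area$time_min / 60
  expo <- unname(coef(lm(log(area$value) ~ tha))[2])
  list(elongation_um_per_h = lin, exp_area_per_h = expo,
       n_frames = nrow(len))
}

#' Across-cell fluorescence ratio time course
#'
#' For every cell and frame, the ratio of background-corrected means
#' (numerator channel over denominator channel); then, per frame, the mean
#' and standard deviation across cells.  Cells whose denominator is not
#' positive at a frame are excluded there and counted in `n_excluded`.
#'
#' @param prj a `bt_project` with `mean_corrected` measurements for both
#'   channels
#' @param chan_num,chan_den numerator and denominator channels
#' @return data.frame `frame`, `time_min`, `mean_ratio`, `sd_ratio`, `n`,
#'   `n_excluded`
#' @export
ratio_timecourse <- function(prj, chan_num = "ch1", chan_den = "ch2") {
  df <- DBI::dbGetQuery(prj$db,
    "SELECT m1.frame AS frame, f.time_min AS time_min, m1.cell AS cell,
            m1.value AS num, m2.value AS den
     FROM measurement m1
     JOIN measurement m2 ON m1.cell = m2.cell AND m1.frame = m2.frame
     JOIN frame f ON f.frame_index = m1.frame
     WHERE m1.channel = ? AND m1.variable = 'mean_corrected'
       AND m2.channel = ? AND m2.variable = 'mean_corrected'
     ORDER BY m1.frame, m1.cell",
    params = list(chan_num, chan_den))
  if (nrow(df) == 0)
    stop("no background-corrected measurements for channels ",
         chan_num, "/", chan_den)
  out <- lapply(split(df, df$frame), function(d) {
    ok <- d$den > 0
    r <- d$num[ok] / d$den[ok]
    data.frame(frame = d$frame[1], time_min = d$time_min[1],
               mean_ratio = if (length(r)) mean(r) else NA_real_,
               sd_ratio = if (length(r) > 1) sd(r) else 0,
               n = sum(ok), n_excluded = sum(!ok))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$frame), ]
}
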