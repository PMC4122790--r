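#' @title Tracking driver
#'
#' @description Runs the per-frame propagation over a frame range, reading
#'   seed masks from the datastore and persisting every result immediately,
#'   so a long run can be resumed and inspected while it progresses.
#'
#' @name tracking
NULL

# Latest saved ROI of a cell strictly before `frame`, or NULL.
latest_roi_before <- function(prj, cell, frame) {
  row <- DBI::dbGetQuery(prj$db,
    "SELECT frame, rle_mask FROM roi WHERE cell = ? AND frame < ?
     ORDER BY frame DESC LIMIT 1", params = list(cell, as.integer(frame)))
  if (nrow(row) == 0) return(NULL)
  mask_from_rle(row$rle_mask[1], frame_index = row$frame[1])
}

roi_provenance_at <- function(prj, cell, frame) {
  row <- DBI::dbGetQuery(prj$db,
    "SELECT provenance FROM roi WHERE cell = ? AND frame = ?",
    params = list(cell, as.integer(frame)))
  if (nrow(row) == 0) NA_character_ else row$provenance[1]
}

#' Segment and track cells over a frame range
#'
#' For every non-excluded frame in `frames` (ascending), propagates each
#' listed cell that is active there from its most recent saved mask,
#' persisting each new mask with provenance `auto` as soon as it is
#' computed.  A frame where the cell already has a manual mask (a user
#' correction or a daughter outline from a division annotation) is left
#' untouched and seeds the following frames.  A cell that raises a
#' cell-lost error is flagged `needs-attention` in the event log and is not
#' propagated further in this run; the other cells continue.
#'
#' @param prj a `bt_project` with the channel stacks attached
#' @param cells character vector of cell names to track
#' @param frames 0-based frame indices to process
#' @param channel channel whose working images drive the edge maps
#' @param params a [seg_params()]
#' @param method auto-threshold method for the edge maps
#' @return a report: list with `auto`, `manual`, `failed` counts, the
#'   per-cell failure messages, and the processed frame indices
#' @export
segment_range <- function(prj, cells, frames, channel = "phase",
                          params = seg_params(), method = "isodata") {
  stack <- prj$stacks[[channel]]
  if (is.null(stack)) stop("channel '", channel, "' is not attached")
  frames <- sort(as.integer(frames))
  # precondition: every listed cell has a seed mask before the range
  for (nm in cells) {
    if (!cell_exists(prj, nm)) stop("unknown cell '", nm, "'")
    if (is.null(latest_roi_before(prj, nm, frames[1])) &&
        is.na(roi_provenance_at(prj, nm, frames[1])))
      stop("cell '", nm, "' has no seed mask before frame ", frames[1])
  }
  n_auto <- 0L; n_manual <- 0L
  failures <- character(0)
  live <- sort(cells)
  processed <- integer(0)
  for (f in frames) {
    if (stack$excluded[f + 1L]) next
    todo <- live[vapply(live, function(nm) {
      nm %in% active_cells(prj, f) &&
        !identical(roi_provenance_at(prj, nm, f), "manual")
    }, logical(1))]
    n_manual <- n_manual + sum(vapply(live, function(nm)
      identical(roi_provenance_at(prj, nm, f), "manual"), logical(1)))
    if (length(todo)) {
      prev <- list()
      for (nm in todo) {
        pm <- latest_roi_before(prj, nm, f)
        if (is.null(pm)) next
        prev[[nm]] <- pm
      }
      if (length(prev)) {
        res <- segment_frame(prev, stack$images[[f + 1L]], params,
                             method = method, frame_index = f)
        for (nm in names(res$masks)) {
          save_roi(prj, nm, f, res$masks[[nm]], "auto")
          n_auto <- n_auto + 1L
        }
        for (nm in names(res$failed)) {
          failures[nm] <- sprintf("frame %d: %s", f, res$failed[[nm]])
          log_event(prj, "needs-attention", f,
                    list(cell = nm, reason = res$failed[[nm]]))
          live <- setdiff(live, nm)
        }
      }
    }
    processed <- c(processed, f)
  }
  log_event(prj, "segment", NA, list(
    cells = paste(cells, collapse = ","),
    frames = sprintf("%d:%d", frames[1], frames[length(frames)]),
    channel = channel, w = params$cell_width,
    p = params$max_pole_elongation, a = params$max_area_increase,
    method = method))
  list(auto = n_auto, manual = n_manual, failed = length(failures),
       failures = failures, frames = processed)
}

#' Export outline overlays as a PNG sequence
#'
#' Writes, for each processed frame, the working image with every saved
#' cell outline superimposed: red for automatic selections, green for
#' manual ones.
#'
#' @param prj a `bt_project`
#' @param directory output folder
#' @param channel channel whose working copies form the background
#' @return invisibly, the written file paths
#' @export
export_overlays <- function(prj, directory, channel = "phase") {
  stack <- prj$stacks[[channel]]
  if (is.null(stack)) stop("channel '", channel, "' is not attached")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  dims <- dim(stack$images[[1]])
  rois <- DBI::dbGetQuery(prj$db,
    "SELECT cell, frame, rle_mask, provenance FROM roi ORDER BY frame, cell")
  paths <- character(0)
  for (f in sort(unique(rois$frame))) {
    g <- pmin(pmax(stack$images[[f + 1L]], 0), 255) / 255
    rgb <- array(rep(g, 3), c(dims, 3))
    sel <- rois[rois$frame == f, ]
    for (i in seq_len(nrow(sel))) {
      m <- mask_to_logical(mask_from_rle(sel$rle_mask[i]), dims)
      outline <- m & !erode_disk(m, 1)
      ch <- if (sel$provenance[i] == "manual") 2L else 1L
      plane <- rgb[, , ch]; plane[outline] <- 1
      rgb[, , ch] <- plane
      for (other in setdiff(1:3, ch)) {
        plane <- rgb[, , other]; plane[outline] <- 0
        rgb[, , other] <- plane
      }
    }
    p <- file.path(directory, sprintf("overlay_%04d.png", f))
    png::writePNG(rgb, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
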