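#' Replay a ground-truthed movie through the tracking workflow
#'
#' Validation utility: builds a project from a simulated movie, outlines
#' the founder cells from the ground truth at frame 0 (playing the user's
#' role), then walks the movie frame by frame, annotating each division
#' with the truth daughter masks when it occurs (division detection is
#' user-driven by design) and propagating every cell in between with the
#' segmentation algorithm.  Returns per-cell, per-frame agreement with the
#' ground truth.
#'
#' @param sim result of [simulate_movie()]
#' @param params a [seg_params()]
#' @param method auto-threshold method for edge maps
#' @param db_path datastore path (default: temporary file)
#' @return list: `project`, `iou` (data.frame cell, frame, iou, swap),
#'   `mean_iou`, `identity_swaps` (count of auto masks overlapping a wrong
#'   truth cell more than their own), `report` (from [segment_range()])
#' @export
benchmark_tracking <- function(sim, params = seg_params(),
                               method = "isodata",
                               db_path = tempfile(fileext = ".db")) {
  truth <- sim$truth
  prj <- project_open(db_path,
                      pixel_size_um = truth$config$pixel_size_um)
  for (st in sim$stacks) project_add_channel(prj, st)
  nf <- n_frames(sim$stacks$phase)
  lin <- truth$lineage
  roots <- lin$name[is.na(lin$parent)]
  for (r in roots)
    create_initial_cell(prj, r, truth$masks[[1]][[r]], 0)
  reports <- list()
  for (f in seq_len(nf - 1)) {
    divs <- lin[!is.na(lin$end_frame) & lin$end_frame == f - 1L &
                  lin$fate == "divided", , drop = FALSE]
    for (p in divs$name)
      record_division(prj, p, f, truth$masks[[f + 1L]][[paste0(p, "A")]],
                      truth$masks[[f + 1L]][[paste0(p, "B")]])
    reports[[f]] <- segment_range(prj, active_cells(prj, f), f,
                                  channel = "phase", params = params,
                                  method = method)
  }
  rows <- list()
  swaps <- 0L
  for (f in seq_len(nf - 1)) {
    tm <- truth$masks[[f + 1L]]
    for (nm in names(tm)) {
      got <- tryCatch(load_roi(prj, nm, f), error = function(e) NULL)
      if (is.null(got) || !identical(attr(got, "provenance"), "auto")) next
      ious <- vapply(names(tm), function(other)
        mask_iou(got, tm[[other]]), numeric(1))
      swap <- names(tm)[which.max(ious)] != nm
      swaps <- swaps + swap
      rows[[length(rows) + 1]] <- data.frame(cell = nm, frame = f,
                                             iou = ious[[nm]], swap = swap)
    }
  }
  iou <- do.call(rbind, rows)
  list(project = prj, iou = iou, mean_iou = mean(iou$iou),
       identity_swaps = swaps,
       report = list(auto = sum(vapply(reports, `[[`, integer(1), "auto")),
                     failed = sum(vapply(reports, `[[`, integer(1),
                                         "failed"))))
}
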