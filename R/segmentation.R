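#' @title Skeleton-guided propagation of cell regions
#'
#' @description The tracking algorithm for worm-shaped cells growing in
#'   closely packed microcolonies.  It assumes that cells change only
#'   slightly between consecutive frames, have a roughly fixed width, and
#'   grow almost exclusively along their length.  For each frame an edge map
#'   is built once (Sobel gradient, auto-threshold, Zhang-Suen thinning);
#'   each cell's previous-frame region is then thinned to its skeleton,
#'   re-fitted to the new edges, elongated at the poles, and finally
#'   reconstructed by smearing a disk along the fitted pixels.  Cells are
#'   processed round-robin in alphabetical name order; where two cells
#'   compete for pixels the earlier cell wins.
#'
#' @name segmentation
NULL

cell_lost <- function(msg) {
  stop(structure(class = c("cell_lost", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Segmentation parameters
#'
#' The three pixel-valued parameters of the propagation algorithm.
#' `cell_width` is the radius of the disk used both for the edge-distance
#' test and for reconstruction; `max_pole_elongation` is the radius of the
#' half-disc probed beyond each pole; `max_area_increase` caps the pixel
#' growth of a cell between consecutive frames.  The defaults (3, 10, 35)
#' are the values used for mycobacteria imaged at about 0.13 um/px.
#'
#' @param cell_width disk radius w in pixels (>= 1)
#' @param max_pole_elongation half-disc radius p in pixels (>= 0)
#' @param max_area_increase maximal area increase a in pixels per frame step
#' @return a list of class `seg_params`
#' @export
seg_params <- function(cell_width = 3L, max_pole_elongation = 10L,
                       max_area_increase = 35L) {
  w <- as.integer(cell_width); p <- as.integer(max_pole_elongation)
  a <- as.integer(max_area_increase)
  if (w < 1L) stop("cell_width must be >= 1")
  if (p < 0L || a < 0L) stop("pole elongation and area increase must be >= 0")
  structure(list(cell_width = w, max_pole_elongation = p,
                 max_area_increase = a), class = "seg_params")
}

#' Sobel gradient magnitude
#'
#' Convolves the image with the standard 3x3 Sobel kernels (border handled
#' by edge replication), takes `sqrt(Gx^2 + Gy^2)` and linearly rescales the
#' result to 0..255 (a constant image stays all-zero).
#'
#' @param img numeric matrix (8-bit working copy)
#' @return numeric matrix of rounded magnitudes in 0..255
#' @export
edge_magnitude <- function(img) {
  img <- as.matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  # pad by 1 with edge replication
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- img
  p[1, ] <- p[2, ]; p[nr + 2, ] <- p[nr + 1, ]
  p[, 1] <- p[, 2]; p[, nc + 2] <- p[, nc + 1]
  sub <- function(dr, dc) p[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc]
  # columns increase to the right, rows increase downward
  gx <- (sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)) -
        (sub(-1, -1) + 2 * sub(0, -1) + sub(1, -1))
  gy <- (sub(1, -1) + 2 * sub(1, 0) + sub(1, 1)) -
        (sub(-1, -1) + 2 * sub(-1, 0) + sub(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx == 0) return(mag)
  round(mag * (255 / mx))
}

#' Build the per-frame edge map
#'
#' Sobel gradient magnitude, auto-threshold (IsoData by default), then
#' Zhang-Suen thinning of the binary edges to one-pixel width.
#'
#' @param img numeric matrix (8-bit working copy)
#' @param method auto-threshold method, see [auto_threshold()]
#' @return logical matrix of thinned edge pixels
#' @export
build_edge_map <- function(img, method = "isodata") {
  thin(auto_threshold(edge_magnitude(img), method))
}

# Distance of every pixel to the nearest edge pixel (exact Euclidean).
edge_distance <- function(edges) {
  if (!any(edges)) cell_lost("no edge pixels detected anywhere in the frame")
  as.matrix(EBImage::distmap(1 - (edges != 0)))
}

#' Re-fit a skeleton to the current frame's edges
#'
#' Probes the previous-frame skeleton pixels and their neighbourhood
#' (everything within `w` of the skeleton) against the new frame's edge
#' map, admitting a pixel iff the disk of radius `w` around it fits inside
#' the detected cell boundary, i.e. its Euclidean distance to the nearest
#' edge pixel is at least `w`.  The admitted set is a narrow band along
#' the cell's new medial axis: smearing the disk of radius `w` along it
#' (see [reconstruct()]) reproduces the cell up to its edges rather than
#' inflating it.  A skeleton drawn slightly off the cell midline is
#' thereby re-centred onto the axis the edges delimit.
#'
#' @param skel a `skeleton` from [skeletonize_mask()]
#' @param edges logical edge map (see [build_edge_map()])
#' @param w cell-width radius in pixels
#' @param dist optional precomputed edge-distance matrix (computed from
#'   `edges` when missing)
#' @param claimed optional logical matrix of pixels already owned by earlier
#'   cells in this frame's round-robin
#' @return logical matrix of the adjusted pixel set
#' @export
adjust_skeleton_area <- function(skel, edges, w, dist = NULL, claimed = NULL) {
  if (is.null(dist)) dist <- edge_distance(edges)
  sk_img <- mask_to_logical(skel$pixels, skel$dim)
  admissible <- dist >= w - 0.5 & dist <= w + 2 & dilate_disk(sk_img, w)
  if (!is.null(claimed)) admissible <- admissible & !claimed
  if (!any(admissible))
    cell_lost(paste0("no pixel near the skeleton is at least the cell-width",
                     " radius away from the detected edges"))
  # keep only the admissible components closest to the skeleton, so the
  # adjusted set cannot jump across an edge/halo ring onto foreign ground;
  # the contact radius widens progressively to tolerate frame-to-frame
  # cell displacement
  lab <- label_components8(admissible)
  keep <- integer(0)
  for (rad in seq_len(w)) {
    keep <- setdiff(unique(lab[dilate_disk(sk_img, rad)]), 0L)
    if (length(keep)) break
  }
  if (length(keep) == 0)
    cell_lost("adjusted area lost contact with the previous skeleton")
  admissible & matrix(lab %in% keep, nrow(lab), ncol(lab))
}

#' Probe the poles for elongation
#'
#' For each endpoint of the thinned adjusted set, estimates the pole
#' direction as the unit vector from the skeleton pixel `k` steps inward to
#' the endpoint, then probes the half-disc of radius `p` oriented away from
#' the cell.  Candidates must pass the same disk-fit test as the adjusted
#' area (edge distance >= `w`) and
#' are admitted in order of increasing distance from the endpoint; admission
#' stops as soon as the projected reconstructed area would exceed
#' `prev_area + a`.  Zero admitted pixels is a valid outcome (a pole that
#' did not grow).
#'
#' @param adjusted logical matrix from [adjust_skeleton_area()]
#' @param edges logical edge map
#' @param params a [seg_params()]
#' @param prev_area pixel area of the cell in the previous frame
#' @param k steps walked inward along the skeleton to estimate the pole
#'   direction
#' @inheritParams adjust_skeleton_area
#' @return logical matrix of admitted elongation pixels (disjoint from
#'   `adjusted`)
#' @export
elongate_poles <- function(adjusted, edges, params, prev_area,
                           dist = NULL, claimed = NULL, k = 5L) {
  w <- params$cell_width; p <- params$max_pole_elongation
  a <- params$max_area_increase
  nr <- nrow(adjusted); nc <- ncol(adjusted)
  elong <- matrix(FALSE, nr, nc)
  if (p == 0L || !any(adjusted)) return(elong)
  if (is.null(dist)) dist <- edge_distance(edges)
  sk2 <- thin(adjusted)
  eps <- skeleton_endpoints(sk2)
  if (nrow(eps) == 0) return(elong)
  eps <- eps[order(eps[, 1L], eps[, 2L]), , drop = FALSE]

  recon <- dilate_disk(adjusted, w)
  if (!is.null(claimed)) recon <- recon & !claimed
  area <- sum(recon)
  cap <- prev_area + a
  doff <- disk_offsets(w)

  poff <- disk_offsets(p)
  poff <- poff[!(poff[, 1L] == 0L & poff[, 2L] == 0L), , drop = FALSE]

  for (e in seq_len(nrow(eps))) {
    ep <- eps[e, ]
    inward <- skeleton_walk_inward(sk2, ep, k)
    dirv <- c(ep[1L] - inward[[1L]], ep[2L] - inward[[2L]])
    if (all(dirv == 0)) {
      cand_off <- poff      # degenerate single-pixel skeleton: full disc
    } else {
      dot <- poff[, 1L] * dirv[1L] + poff[, 2L] * dirv[2L]
      cand_off <- poff[dot > 0, , drop = FALSE]
    }
    if (nrow(cand_off) == 0) next
    d2 <- cand_off[, 1L]^2 + cand_off[, 2L]^2
    cand_off <- cand_off[order(d2, cand_off[, 1L], cand_off[, 2L]), ,
                         drop = FALSE]
    # repeat passes so pixels whose connecting neighbour is admitted later
    # in the distance order still get their turn
    repeat {
      admitted_any <- FALSE
      for (i in seq_len(nrow(cand_off))) {
        r <- ep[1L] + cand_off[i, 1L]; cc <- ep[2L] + cand_off[i, 2L]
        if (r < 0L || cc < 0L || r >= nr || cc >= nc) next
        r1 <- r + 1L; c1 <- cc + 1L
        if (adjusted[r1, c1] || elong[r1, c1]) next
        if (!is.null(claimed) && claimed[r1, c1]) next
        if (dist[r1, c1] < w - 0.5 || dist[r1, c1] > w + 2) next
        # elongation must stay contiguous with the cell: no jumping across
        # an edge or halo ring
        nb <- adjusted[max(1, r1 - 1):min(nr, r1 + 1),
                       max(1, c1 - 1):min(nc, c1 + 1)] |
          elong[max(1, r1 - 1):min(nr, r1 + 1),
                max(1, c1 - 1):min(nc, c1 + 1)]
        if (!any(nb)) next
        # projected reconstructed area if this pixel is admitted
        nrs <- r1 + doff[, 1L]; ncs <- c1 + doff[, 2L]
        ok <- nrs >= 1L & nrs <= nr & ncs >= 1L & ncs <= nc
        lin <- nrs[ok] + (ncs[ok] - 1L) * nr
        if (!is.null(claimed)) lin <- lin[!claimed[lin]]
        added <- lin[!recon[lin]]
        if (area + length(added) > cap) return(elong)   # hard cap reached
        elong[r1, c1] <- TRUE
        recon[added] <- TRUE
        area <- area + length(added)
        admitted_any <- TRUE
      }
      if (!admitted_any) break
    }
  }
  elong
}

#' Reconstruct the cell area from its guide pixels
#'
#' Smears the Euclidean disk of radius `w` along the guide set (the adjusted
#' skeleton area plus pole elongation pixels): a pixel belongs to the result
#' iff some guide pixel lies within distance `w`.  The result is clipped to
#' the image and reduced to its largest 8-connected component.
#'
#' @param guide logical matrix of guide pixels
#' @param w disk radius in pixels
#' @param frame_index frame index to attach to the returned mask
#' @return a [pixel_mask()]
#' @export
reconstruct <- function(guide, w, frame_index = 0L) {
  if (!any(guide)) stop("reconstruct: empty guide set")
  mask_from_logical(largest_component8(dilate_disk(guide, w)), frame_index)
}

#' Propagate all cells into one frame
#'
#' Builds the frame's edge map once, then runs the per-cell propagation
#' (skeletonize, re-fit, elongate, reconstruct) round-robin in the order
#' given.  Pixels claimed by an earlier cell are removed from later cells'
#' candidate sets, making the algorithm's order dependence explicit: a
#' contested strip between touching cells goes to the alphabetically
#' earlier cell.  If the reconstructed area still exceeds
#' `prev_area + max_area_increase` (possible when re-fitting shifts the
#' skeleton), pixels farthest from the guide set are trimmed until the cap
#' holds, so the area constraint is satisfied on every propagation.
#'
#' @param prev_masks named list of [pixel_mask()]s, one per cell, from the
#'   previous processed frame; processed in alphabetical name order
#' @param frame_img numeric matrix (8-bit working copy of the new frame)
#' @param params a [seg_params()]
#' @param method auto-threshold method for the edge map
#' @param frame_index index recorded on the output masks
#' @return list with `masks` (named list of [pixel_mask()]s for the cells
#'   that succeeded) and `failed` (named character vector of cell-lost
#'   messages)
#' @export
segment_frame <- function(prev_masks, frame_img, params = seg_params(),
                          method = "isodata", frame_index = 0L) {
  stopifnot(is.list(prev_masks), !is.null(names(prev_masks)))
  ord <- order(names(prev_masks))
  prev_masks <- prev_masks[ord]
  dims <- dim(frame_img)
  edges <- tryCatch(build_edge_map(frame_img, method), error = function(e) e)
  failed <- character(0)
  masks <- list()
  if (inherits(edges, "error") || !any(edges)) {
    msg <- if (inherits(edges, "error")) conditionMessage(edges)
    else "no edge pixels detected anywhere in the frame"
    failed <- setNames(rep(msg, length(prev_masks)), names(prev_masks))
    return(list(masks = masks, failed = failed,
                edges = matrix(FALSE, dims[1], dims[2])))
  }
  dist <- edge_distance(edges)
  w <- params$cell_width

  # phase 1: every cell's adjusted medial band.  Pixels falling in more
  # than one band go to the cell whose previous-frame skeleton is nearest
  # (alphabetical order breaks exact ties), so a neighbour's band cannot
  # creep along another cell's axis from frame to frame.  Each band is
  # then reserved for its owner.
  bands <- list()
  skels <- list()
  for (nm in names(prev_masks)) {
    res <- tryCatch({
      skel <- skeletonize_mask(prev_masks[[nm]], dims)
      list(band = adjust_skeleton_area(skel, edges, w, dist = dist),
           skel = skel)
    }, cell_lost = function(e) e)
    if (inherits(res, "cell_lost")) {
      failed[nm] <- conditionMessage(res)
    } else {
      bands[[nm]] <- res$band
      skels[[nm]] <- res$skel
    }
  }
  if (length(bands) > 1) {
    overlap <- Reduce(`+`, bands) > 1
    if (any(overlap)) {
      pix <- which(overlap)
      dsk <- vapply(names(bands), function(nm) {
        skm <- mask_to_logical(skels[[nm]]$pixels, dims)
        as.matrix(EBImage::distmap(!skm))[pix]
      }, numeric(length(pix)))
      dsk <- matrix(dsk, nrow = length(pix))
      winner <- max.col(-dsk, ties.method = "first")
      for (ci in seq_along(bands))
        bands[[ci]][pix[winner != ci]] <- FALSE
    }
  }
  band_union <- Reduce(`|`, c(list(matrix(FALSE, dims[1L], dims[2L])),
                              bands))

  # phase 2: elongation and raw reconstruction per cell.  Elongation may
  # not enter the body around a neighbour's axis (no wrapping around a
  # thin band).
  raw <- list()
  for (nm in names(bands)) {
    prev <- prev_masks[[nm]]
    adj <- bands[[nm]]
    reserved <- band_union & !adj       # other cells' axes
    blocked <- dilate_disk(reserved, params$cell_width - 1L) & !adj
    res <- tryCatch({
      el <- elongate_poles(adj, edges, params, mask_area(prev),
                           dist = dist, claimed = blocked)
      recon <- dilate_disk(adj | el, w) & !reserved
      if (!any(recon)) cell_lost("reconstructed area is empty")
      recon
    }, cell_lost = function(e) e)
    if (inherits(res, "cell_lost")) failed[nm] <- conditionMessage(res)
    else raw[[nm]] <- res
  }

  # phase 3: pixels reconstructed by several cells go to the cell with the
  # nearest adjusted band; exact ties follow the round-robin order (the
  # alphabetically earlier cell wins).  Then the area cap is enforced by
  # trimming pixels farthest from the cell's own band.
  if (length(raw) > 1) {
    overlap <- Reduce(`+`, raw) > 1
    if (any(overlap)) {
      pix <- which(overlap)
      db <- vapply(names(raw), function(nm)
        as.matrix(EBImage::distmap(!bands[[nm]]))[pix],
        numeric(length(pix)))
      db <- matrix(db, nrow = length(pix))
      winner <- max.col(-db, ties.method = "first")
      for (ci in seq_along(raw)) raw[[ci]][pix[winner != ci]] <- FALSE
    }
  }
  for (nm in names(raw)) {
    recon <- largest_component8(raw[[nm]])
    cap <- mask_area(prev_masks[[nm]]) + params$max_area_increase
    if (sum(recon) > cap) {
      dg <- as.matrix(EBImage::distmap(!bands[[nm]]))
      idx <- which(recon)
      drop <- idx[order(-dg[idx], -idx)][seq_len(sum(recon) - cap)]
      recon[drop] <- FALSE
      recon <- largest_component8(recon)
    }
    if (!any(recon)) {
      failed[nm] <- "reconstructed area is empty"
    } else {
      masks[[nm]] <- mask_from_logical(recon, frame_index)
    }
  }
  list(masks = masks, failed = failed, edges = edges)
}
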