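#' @title Translational frame registration
#'
#' @description The motorized stage introduces a small translational shift
#'   between successive frames that must be corrected before segmentation.
#'   Registration here is integer-pixel and purely translational: the shift
#'   between each pair of consecutive frames is estimated on one reference
#'   channel (phase contrast by default) by maximizing the normalized
#'   cross-correlation of the overlap, drifts are accumulated relative to
#'   frame 0, and the identical correction is applied to every channel.
#'
#' @name registration
NULL

#' Estimate the integer shift between two images
#'
#' Finds the integer `(dy, dx)`, with `|dy|, |dx| <= max_shift`, maximizing
#' the normalized cross-correlation of the overlapping region, under the
#' model `moving[r, c] ~ ref[r - dy, c - dx]` (i.e. the returned vector is
#' the drift of `moving` relative to `ref`).  Ties are broken by smallest
#' `|dy| + |dx|`, then smallest `dy`, then `dx`; images with zero variance
#' in the overlap score 0, so two constant images yield `(0, 0)`.
#'
#' @param ref,moving numeric matrices of identical dimensions
#' @param max_shift maximum shift magnitude in pixels (>= 0)
#' @return integer vector `c(dy, dx)` with attribute `"ncc"`, the winning
#'   correlation
#' @export
estimate_shift <- function(ref, moving, max_shift = 5L) {
  if (!all(dim(ref) == dim(moving)))
    stop("images must have identical dimensions")
  max_shift <- as.integer(max_shift)
  if (max_shift < 0) stop("max_shift must be >= 0")
  if (max_shift >= min(dim(ref)) / 2)
    stop("max_shift too large for the image size")
  nr <- nrow(ref); nc <- ncol(ref)
  best <- c(0L, 0L); best_ncc <- -Inf
  for (dy in -max_shift:max_shift) {
    rr <- max(1L, 1L - dy):min(nr, nr - dy)
    for (dx in -max_shift:max_shift) {
      cc <- max(1L, 1L - dx):min(nc, nc - dx)
      a <- ref[rr, cc]
      b <- moving[rr + dy, cc + dx]
      ncc <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(as.vector(a),
                                                      as.vector(b))
      better <- ncc > best_ncc + 1e-12 ||
        (abs(ncc - best_ncc) <= 1e-12 && shift_tiebreak(dy, dx, best))
      if (better) { best <- c(dy, dx); best_ncc <- ncc }
    }
  }
  structure(setNames(best, c("dy", "dx")), ncc = best_ncc)
}

# TRUE when (dy, dx) wins the tie against the current best.
shift_tiebreak <- function(dy, dx, best) {
  l1 <- abs(dy) + abs(dx); l1b <- abs(best[1]) + abs(best[2])
  if (l1 != l1b) return(l1 < l1b)
  if (dy != best[1]) return(dy < best[1])
  dx < best[2]
}

# Shift image content by (dy, dx): out[r, c] = img[r - dy, c - dx], vacated
# pixels filled with `fill`.
apply_shift <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  rr <- max(1L, 1L + dy):min(nr, nr + dy)
  cc <- max(1L, 1L + dx):min(nc, nc + dx)
  if (length(rr) && length(cc) && rr[1] <= rr[length(rr)] &&
      cc[1] <= cc[length(cc)])
    out[rr, cc] <- img[rr - dy, cc - dx, drop = FALSE]
  out
}

# Most frequent rounded intensity of an image (the modal background value).
modal_value <- function(img) {
  v <- round(as.vector(img))
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])
}

#' Register a multi-channel movie
#'
#' Estimates pairwise shifts between consecutive frames on the reference
#' channel, accumulates them into per-frame drifts relative to frame 0, and
#' applies the inverse drift to every channel (working copies and
#' originals).  Vacated canvas pixels are filled with each frame's modal
#' background value.  A pairwise correlation peak below `ncc_floor` is
#' recorded as a warning and contributes a zero pairwise shift.
#'
#' @param stacks named list of `frame_stack`s (all channels of the project)
#' @param max_shift per-step maximum shift in pixels
#' @param reference_channel channel used for estimation
#' @param ncc_floor minimum acceptable correlation peak
#' @return list with `shifts` (n x 2 integer matrix of cumulative drifts),
#'   `stacks` (registered copies), and `warnings` (character)
#' @export
register_sequence <- function(stacks, max_shift = 5L,
                              reference_channel = "phase", ncc_floor = 0.2) {
  if (inherits(stacks, "frame_stack")) stacks <- setNames(
    list(stacks), stacks$channel)
  ref <- stacks[[reference_channel]]
  if (is.null(ref)) stop("reference channel '", reference_channel,
                         "' not present")
  n <- n_frames(ref)
  if (n < 2) stop("need at least two frames to register")
  shifts <- matrix(0L, n, 2, dimnames = list(NULL, c("dy", "dx")))
  warnings <- character(0)
  for (k in 2:n) {
    s <- estimate_shift(ref$images[[k - 1]], ref$images[[k]], max_shift)
    if (attr(s, "ncc") < ncc_floor) {
      warnings <- c(warnings, sprintf(
        "frame %d: correlation peak %.3f below floor %.2f; using (0,0)",
        k - 1L, attr(s, "ncc"), ncc_floor))
      s <- c(dy = 0L, dx = 0L)
    }
    shifts[k, ] <- shifts[k - 1, ] + s
  }
  out <- lapply(stacks, function(st) {
    for (k in which(rowSums(abs(shifts)) > 0)) {
      dy <- shifts[k, 1]; dx <- shifts[k, 2]
      st$images[[k]] <- apply_shift(st$images[[k]], -dy, -dx,
                                    modal_value(st$images[[k]]))
      st$originals[[k]] <- apply_shift(st$originals[[k]], -dy, -dx,
                                       modal_value(st$originals[[k]]))
    }
    st
  })
  list(shifts = shifts, stacks = out, warnings = warnings)
}
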