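#' @title Pixel masks (regions of interest)
#'
#' @description A `pixel_mask` is the region of interest of one cell in one
#'   frame: a set of integer pixel coordinates.  Coordinates are `(row, col)`,
#'   0-based, origin at the top-left corner, everywhere in this package
#'   including the datastore.
#'
#' @param coords integer matrix with two columns (`row`, `col`), one pixel per
#'   row; duplicates are removed.
#' @param frame_index 0-based frame the mask belongs to.
#' @return An object of class `pixel_mask`: an n x 2 integer matrix with
#'   columns `row` and `col`, sorted by row then column, carrying a
#'   `frame_index` attribute.
#' @examples
#' m <- pixel_mask(cbind(row = c(0, 0, 1), col = c(0, 1, 0)), frame_index = 0)
#' mask_area(m)
#' @export
pixel_mask <- function(coords, frame_index = 0L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("mask coordinates must be a two-column (row, col) matrix")
  storage.mode(coords) <- "integer"
  if (anyNA(coords)) stop("mask coordinates contain NA")
  if (any(coords < 0L)) stop("mask coordinates must be >= 0 (0-based)")
  coords <- unique(coords)
  ord <- order(coords[, 1L], coords[, 2L])
  coords <- coords[ord, , drop = FALSE]
  colnames(coords) <- c("row", "col")
  structure(coords, frame_index = as.integer(frame_index), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask: %d px, frame %d>\n", nrow(x),
              attr(x, "frame_index")))
  invisible(x)
}

#' Number of pixels in a mask
#' @param mask a [pixel_mask()]
#' @return integer pixel count
#' @export
mask_area <- function(mask) nrow(mask)

#' Convert a mask to a logical image
#'
#' @param mask a [pixel_mask()] (0-based coordinates)
#' @param dim image dimensions `c(nrow, ncol)`
#' @return logical matrix with `TRUE` at mask pixels
#' @export
mask_to_logical <- function(mask, dim) {
  if (nrow(mask) > 0 &&
      (max(mask[, 1L]) >= dim[1L] || max(mask[, 2L]) >= dim[2L]))
    stop("mask pixels outside image bounds")
  m <- matrix(FALSE, dim[1L], dim[2L])
  if (nrow(mask) > 0) m[mask[, 1L] + 1L + mask[, 2L] * dim[1L]] <- TRUE
  m
}

#' Convert a logical image to a mask
#' @param img logical (or 0/1) matrix
#' @param frame_index frame the mask belongs to
#' @return a [pixel_mask()] of the `TRUE` pixels, 0-based
#' @export
mask_from_logical <- function(img, frame_index = 0L) {
  idx <- which(img != 0, arr.ind = TRUE)
  pixel_mask(cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L), frame_index)
}

#' Offsets of the exact Euclidean disk of radius r
#'
#' All integer offsets `(dr, dc)` with `dr^2 + dc^2 <= r^2`.  For `r = 3`
#' there are 29 such offsets.
#' @param r disk radius in pixels (>= 0)
#' @return integer matrix of offsets, columns `dr`, `dc`
#' @export
disk_offsets <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 0L)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  as.matrix(g[order(g$dr^2 + g$dc^2, g$dr, g$dc), ])
}

# Shift a logical matrix by (dr, dc), filling with FALSE.
shift_logical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) && length(sc) && sr[1] <= sr[length(sr)] && sc[1] <= sc[length(sc)])
    out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

#' Dilate a logical image with an exact Euclidean disk
#'
#' A pixel is set in the output iff some input pixel lies within Euclidean
#' distance `r` of it.  Pixels outside the image are clipped.
#' @param img logical matrix
#' @param r disk radius in pixels
#' @return logical matrix of the same dimensions
#' @export
dilate_disk <- function(img, r) {
  img <- img != 0
  if (r == 0) return(img)
  off <- disk_offsets(r)
  out <- img
  for (i in seq_len(nrow(off))) {
    if (off[i, 1L] == 0L && off[i, 2L] == 0L) next
    out <- out | shift_logical(img, off[i, 1L], off[i, 2L])
  }
  out
}

#' Erode a logical image with an exact Euclidean disk
#'
#' A pixel survives iff every pixel within Euclidean distance `r` of it is
#' set; pixels beyond the image border count as background.
#' @inheritParams dilate_disk
#' @return logical matrix of the same dimensions
#' @export
erode_disk <- function(img, r) {
  img <- img != 0
  if (r == 0) return(img)
  off <- disk_offsets(r)
  out <- img
  for (i in seq_len(nrow(off))) {
    if (off[i, 1L] == 0L && off[i, 2L] == 0L) next
    out <- out & shift_logical(img, off[i, 1L], off[i, 2L])
  }
  out
}

# 8-connected component labels of a logical matrix.  Returns an integer
# matrix, 0 = background.  Pure frontier-based flood fill; masks are small.
label_components8 <- function(img) {
  img <- img != 0
  nr <- nrow(img); nc <- ncol(img)
  lab <- matrix(0L, nr, nc)
  todo <- which(img)
  nb <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  current <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    current <- current + 1L
    frontier <- s
    lab[s] <- current
    while (length(frontier)) {
      cand <- rep(frontier, each = 8L) + nb
      rowpos <- ((rep(frontier, each = 8L) - 1L) %% nr) + 1L
      # reject wrap-around across matrix columns and out-of-range indices
      drow <- rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L), length(frontier))
      ok <- cand >= 1L & cand <= nr * nc
      ok <- ok & (((cand - 1L) %% nr) + 1L - rowpos) == drow
      cand <- unique(cand[ok])
      cand <- cand[img[cand] & lab[cand] == 0L]
      lab[cand] <- current
      frontier <- cand
    }
  }
  lab
}

# Largest 8-connected component of a logical matrix (ties: component
# containing the smallest linear index).  Returns logical matrix.
largest_component8 <- function(img) {
  lab <- label_components8(img)
  if (all(lab == 0L)) return(img & FALSE)
  sizes <- tabulate(lab)
  keep <- which(sizes == max(sizes))[1L]
  lab == keep
}

#' Run-length encode a mask
#'
#' Row-wise run-length encoding used by the datastore: for each image row
#' containing mask pixels, `"row:c1-c2,c3-c4"` (0-based, inclusive), rows
#' joined by `";"`.  Deterministic: rows ascending, runs ascending.
#' @param mask a [pixel_mask()]
#' @return a single character string (empty string for an empty mask)
#' @export
mask_to_rle <- function(mask) {
  if (nrow(mask) == 0) return("")
  parts <- vapply(split(mask[, 2L], mask[, 1L]), function(cols) {
    cols <- sort(cols)
    brk <- c(0L, which(diff(cols) != 1L), length(cols))
    runs <- vapply(seq_len(length(brk) - 1L), function(i) {
      seg <- cols[(brk[i] + 1L):brk[i + 1L]]
      sprintf("%d-%d", seg[1L], seg[length(seg)])
    }, character(1))
    paste(runs, collapse = ",")
  }, character(1))
  paste(sprintf("%s:%s", names(parts), parts), collapse = ";")
}

#' Decode a run-length encoded mask
#' @param rle string produced by [mask_to_rle()]
#' @param frame_index frame to attach to the decoded mask
#' @return a [pixel_mask()]
#' @export
mask_from_rle <- function(rle, frame_index = 0L) {
  if (is.na(rle) || !nzchar(rle))
    return(pixel_mask(matrix(integer(0), 0, 2), frame_index))
  rows <- strsplit(rle, ";", fixed = TRUE)[[1]]
  coords <- do.call(rbind, lapply(rows, function(part) {
    kv <- strsplit(part, ":", fixed = TRUE)[[1]]
    r <- as.integer(kv[1])
    runs <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    cols <- unlist(lapply(strsplit(runs, "-", fixed = TRUE), function(ab) {
      a <- as.integer(ab[1]); b <- as.integer(ab[2]); a:b
    }))
    cbind(row = rep(r, length(cols)), col = cols)
  }))
  pixel_mask(coords, frame_index)
}

# Intersection-over-union of two masks (as coordinate sets).
#' Intersection-over-union of two masks
#' @param a,b [pixel_mask()] objects
#' @return IoU in `[0, 1]`; 0 if both empty
#' @export
mask_iou <- function(a, b) {
  ka <- paste(a[, 1L], a[, 2L]); kb <- paste(b[, 1L], b[, 2L])
  inter <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  if (uni == 0) return(0)
  inter / uni
}
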