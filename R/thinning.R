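#' Zhang-Suen thinning
#'
#' The classical two-subiteration parallel thinning algorithm.  Each pass
#' runs subiteration 1 then subiteration 2; within a subiteration all
#' deletable pixels are removed simultaneously.  A border pixel `P1` with
#' neighbours `P2..P9` (clockwise from north) is deleted in subiteration 1
#' when `2 <= B(P1) <= 6`, `A(P1) == 1`, `P2*P4*P6 == 0` and
#' `P4*P6*P8 == 0`, where `B` is the number of set neighbours and `A` the
#' number of 0-to-1 transitions in the cyclic sequence `P2..P9`.
#' Subiteration 2 replaces the last two conditions by `P2*P4*P8 == 0` and
#' `P2*P6*P8 == 0`.  Passes repeat until no pixel is deleted.
#'
#' The result is one pixel wide and preserves the 8-connectivity of every
#' input component (up to the algorithm's known degeneracies, e.g. an
#' isolated 2x2 square vanishes).
#'
#' @param binary logical or 0/1 matrix
#' @return logical matrix of the same dimensions
#' @export
thin <- function(binary) {
  p <- binary != 0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- zs_deletable(p, sub)
      if (any(del)) {
        p[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

# Deletability map for one Zhang-Suen subiteration, computed for the whole
# image at once from the eight shifted neighbour planes.
zs_deletable <- function(p, sub) {
  # shift_logical(p, dr, dc) moves content down/right, so the plane holding
  # each pixel's NORTH neighbour is the image shifted by (+1, 0):
  N <- shift_logical(p, 1L, 0L); S <- shift_logical(p, -1L, 0L)
  E <- shift_logical(p, 0L, -1L); W <- shift_logical(p, 0L, 1L)
  NE <- shift_logical(p, 1L, -1L); SE <- shift_logical(p, -1L, -1L)
  SW <- shift_logical(p, -1L, 1L); NW <- shift_logical(p, 1L, 1L)
  b <- N + NE + E + SE + S + SW + W + NW
  seqs <- list(N, NE, E, SE, S, SW, W, NW, N)
  a <- matrix(0L, nrow(p), ncol(p))
  for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
  if (sub == 1L) {
    cond <- !(N & E & S) & !(E & S & W)
  } else {
    cond <- !(N & E & W) & !(N & S & W)
  }
  p & b >= 2 & b <= 6 & a == 1L & cond
}

#' Skeletonize a cell mask
#'
#' Renders the mask as a binary image and thins it with [thin()].  The
#' skeleton's endpoints are the skeleton pixels with exactly one set
#' 8-neighbour; a single-pixel skeleton counts as two coincident poles.
#'
#' @param prev a nonempty, 8-connected [pixel_mask()]
#' @param dim image dimensions `c(nrow, ncol)`
#' @return a list of class `skeleton` with elements `pixels` (a
#'   [pixel_mask()]), `endpoints` (m x 2 integer matrix, 0-based) and `dim`
#' @export
skeletonize_mask <- function(prev, dim) {
  if (nrow(prev) == 0) stop("cell-lost: empty mask cannot be skeletonized")
  sk <- thin(mask_to_logical(prev, dim))
  if (!any(sk)) stop("cell-lost: mask thinned to the empty set")
  structure(list(pixels = mask_from_logical(sk, attr(prev, "frame_index")),
                 endpoints = skeleton_endpoints(sk),
                 dim = dim),
            class = "skeleton")
}

# Endpoints of a thinned logical image: set pixels with exactly one set
# 8-neighbour.  A lone isolated pixel (zero neighbours) is also returned,
# treated downstream as two coincident poles.
skeleton_endpoints <- function(sk) {
  nb <- shift_logical(sk, 1L, 0L) + shift_logical(sk, -1L, 0L) +
    shift_logical(sk, 0L, 1L) + shift_logical(sk, 0L, -1L) +
    shift_logical(sk, 1L, 1L) + shift_logical(sk, 1L, -1L) +
    shift_logical(sk, -1L, 1L) + shift_logical(sk, -1L, -1L)
  idx <- which(sk & nb <= 1L, arr.ind = TRUE)
  cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
}

# Walk k steps inward along the skeleton from an endpoint; returns the
# 0-based (row, col) of the pixel reached.  If a branch point or the other
# end is closer than k steps, the farthest available pixel is used.  At an
# ambiguous step (several unvisited skeleton neighbours) the one farthest
# from the endpoint is taken, ties broken by linear index.
skeleton_walk_inward <- function(sk, endpoint, k) {
  nr <- nrow(sk)
  start <- endpoint[1L] + 1L + endpoint[2L] * nr   # 1-based linear index
  cur <- start
  visited <- start
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  drow <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  er <- endpoint[1L]; ec <- endpoint[2L]
  for (step in seq_len(k)) {
    cand <- cur + offs
    rowpos <- ((cur - 1L) %% nr) + 1L
    ok <- cand >= 1L & cand <= length(sk) &
      (((cand - 1L) %% nr) + 1L - rowpos) == drow
    cand <- cand[ok]
    cand <- cand[sk[cand] & !(cand %in% visited)]
    if (length(cand) == 0L) break
    if (length(cand) > 1L) {
      cr <- (cand - 1L) %% nr; cc <- (cand - 1L) %/% nr
      d2 <- (cr - er)^2 + (cc - ec)^2
      cand <- cand[order(-d2, cand)][1L]
    }
    visited <- c(visited, cand)
    cur <- cand
  }
  c(row = ((cur - 1L) %% nr), col = (cur - 1L) %/% nr)
}
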