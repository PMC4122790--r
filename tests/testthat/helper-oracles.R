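# Independent oracles used across the suite.  These are deliberately naive
# (per-pixel loops, exhaustive scans) and share no code with the package
# implementations they check.

# Literal per-pixel transcription of the two-subiteration thinning rules.
# P2..P9 are the neighbours clockwise from north; A = number of 0->1
# transitions in the cyclic sequence P2..P9; B = number of set neighbours.
oracle_thin <- function(img) {
  p <- (img != 0) * 1L
  nr <- nrow(p); nc <- ncol(p)
  val <- function(m, r, c) if (r < 1 || c < 1 || r > nr || c > nc) 0L else m[r, c]
  neighbours <- function(m, r, c) {
    c(P2 = val(m, r - 1, c),     P3 = val(m, r - 1, c + 1),
      P4 = val(m, r, c + 1),     P5 = val(m, r + 1, c + 1),
      P6 = val(m, r + 1, c),     P7 = val(m, r + 1, c - 1),
      P8 = val(m, r, c - 1),     P9 = val(m, r - 1, c - 1))
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- matrix(FALSE, nr, nc)
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        if (p[r, c] == 0L) next
        nb <- neighbours(p, r, c)
        B <- sum(nb)
        if (B < 2 || B > 6) next
        cyc <- c(nb, nb[1])
        A <- sum(cyc[-length(cyc)] == 0L & cyc[-1] == 1L)
        if (A != 1) next
        if (sub == 1) {
          if (nb["P2"] * nb["P4"] * nb["P6"] != 0) next
          if (nb["P4"] * nb["P6"] * nb["P8"] != 0) next
        } else {
          if (nb["P2"] * nb["P4"] * nb["P8"] != 0) next
          if (nb["P2"] * nb["P6"] * nb["P8"] != 0) next
        }
        del[r, c] <- TRUE
      }
      if (any(del)) { p[del] <- 0L; changed <- TRUE }
    }
    if (!changed) return(p == 1L)
  }
}

# All thresholds t in [min(v), max(v)) satisfying the IsoData fixed point
# t = floor((mean(v <= t) + mean(v > t)) / 2), by exhaustive scan.
oracle_isodata_fixed_points <- function(v) {
  cands <- min(v):(max(v) - 1L)
  keep <- vapply(cands, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    length(lo) > 0 && length(hi) > 0 &&
      t == floor((mean(lo) + mean(hi)) / 2)
  }, logical(1))
  cands[keep]
}

# Brute-force Euclidean-disk dilation / erosion by direct enumeration.
oracle_dilate <- function(img, w) {
  img <- img != 0
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(FALSE, nr, nc)
  on <- which(img, arr.ind = TRUE)
  if (nrow(on) == 0) return(out)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d2 <- (on[, 1] - r)^2 + (on[, 2] - c)^2
    if (min(d2) <= w^2) out[r, c] <- TRUE
  }
  out
}

oracle_erode <- function(img, w) {
  img <- img != 0
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!img[r, c]) next
    keep <- TRUE
    for (dr in -w:w) for (dc in -w:w) {
      if (dr^2 + dc^2 > w^2) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || cc < 1 || rr > nr || cc > nc || !img[rr, cc]) keep <- FALSE
    }
    out[r, c] <- keep
  }
  out
}

# Seeded random blob: union of discs along a short random walk, rendered
# into an n x n logical matrix.  Used to exercise thinning and morphology.
random_blob <- function(n = 64, steps = 25, radius = 4) {
  pos <- c(sample(n, 1), sample(n, 1))
  img <- matrix(FALSE, n, n)
  for (s in seq_len(steps)) {
    pos <- pmin(pmax(pos + sample(-2:2, 2, replace = TRUE), 1 + radius),
                n - radius)
    for (dr in -radius:radius) for (dc in -radius:radius)
      if (dr^2 + dc^2 <= radius^2) img[pos[1] + dr, pos[2] + dc] <- TRUE
  }
  img
}

# Random sparse pixel mask within an n x n frame.
random_mask <- function(n = 64, npix = 50, frame_index = 0L) {
  idx <- sample(n * n, npix)
  pixel_mask(cbind(row = (idx - 1L) %% n, col = (idx - 1L) %/% n), frame_index)
}
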