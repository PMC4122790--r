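# brute-force 3x3 Sobel with edge replication, used as convolution oracle
oracle_sobel <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  at <- function(r, c) img[min(max(r, 1), nr), min(max(c, 1), nc)]
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    gx[r, c] <- (at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1)) -
      (at(r - 1, c - 1) + 2 * at(r, c - 1) + at(r + 1, c - 1))
    gy[r, c] <- (at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1)) -
      (at(r - 1, c - 1) + 2 * at(r - 1, c) + at(r - 1, c + 1))
  }
  sqrt(gx^2 + gy^2)
}

test_that("Sobel magnitude matches direct convolution, flat fields are zero", {
  expect_true(all(edge_magnitude(matrix(57, 12, 12)) == 0))
  # vertical step of height 8: |Gx| = 32 on the two columns flanking the step
  img <- cbind(matrix(10, 10, 5), matrix(18, 10, 5))
  raw <- oracle_sobel(img)
  expect_true(all(raw[, 5:6] == 32))
  expect_equal(edge_magnitude(img), round(raw * 255 / max(raw)))
  # transposing the input transposes the output (Gx <-> Gy symmetry)
  set.seed(8)
  r <- matrix(sample(0:255, 100, TRUE), 10, 10)
  expect_equal(edge_magnitude(t(r)), t(edge_magnitude(r)))
})

test_that("reconstruct smears the exact Euclidean disk", {
  guide <- matrix(FALSE, 15, 15); guide[8, 8] <- TRUE
  m <- reconstruct(guide, 3)
  expect_equal(mask_area(m), 29)
  # brute force: every offset with dr^2 + dc^2 <= 9
  expect_identical(mask_to_logical(m, c(15, 15)), oracle_dilate(guide, 3))
  expect_identical(mask_to_logical(reconstruct(guide, 0), c(15, 15)), guide)
})

test_that("reconstruction is sandwiched between guide and its dilation", {
  set.seed(12)
  for (i in 1:25) {
    guide <- matrix(FALSE, 30, 30)
    # connected-ish random guide: a short random walk
    p <- c(15, 15)
    for (s in 1:15) {
      p <- pmin(pmax(p + sample(-1:1, 2, TRUE), 2), 29)
      guide[p[1], p[2]] <- TRUE
    }
    w <- sample(1:3, 1)
    rec <- mask_to_logical(reconstruct(guide, w), c(30, 30))
    expect_true(all(rec[guide]))                       # guide inside result
    expect_true(all(!rec | oracle_dilate(guide, w)))   # result inside dilation
  }
})

# a straight synthetic cell: two horizontal edge lines 2w+1 = 7 rows apart
straight_cell_edges <- function(nr = 15, nc = 40, top = 5) {
  e <- matrix(FALSE, nr, nc)
  e[top, 3:(nc - 2)] <- TRUE
  e[top + 7, 3:(nc - 2)] <- TRUE
  e
}

test_that("the adjusted area contains the midline and re-centres an offset skeleton", {
  edges <- straight_cell_edges()
  # midline rows 8 and 9 are 3 px from both edge rows (5 and 12)
  dims <- c(15, 40)
  sk_mid <- skeletonize_mask(pixel_mask(cbind(7L, 7:31)), dims)  # row 8 1-based
  adj <- adjust_skeleton_area(sk_mid, edges, 3)
  skm <- mask_to_logical(sk_mid$pixels, dims)
  expect_true(all(adj[skm]))            # adjusted superset of the skeleton
  # brute-force distance check of every admitted pixel
  d <- matrix(0, 15, 40)
  ep <- which(edges, arr.ind = TRUE)
  for (r in 1:15) for (c in 1:40)
    d[r, c] <- sqrt(min((ep[, 1] - r)^2 + (ep[, 2] - c)^2))
  expect_true(all(d[adj] >= 2.5 & d[adj] <= 5))
  # skeleton drawn 1 px off the midline yields the same adjusted set away
  # from the skeleton's ends (the probing neighbourhood differs by one
  # pixel at its corners)
  sk_off <- skeletonize_mask(pixel_mask(cbind(6L, 7:31)), dims)
  adj_off <- adjust_skeleton_area(sk_off, edges, 3)
  expect_identical(adj_off[, 12:28], adj[, 12:28])
  expect_true(all(adj_off[skm]))   # still re-centred onto the midline
})

test_that("an empty edge map loses the cell", {
  dims <- c(15, 40)
  sk <- skeletonize_mask(pixel_mask(cbind(7L, 7:31)), dims)
  expect_error(adjust_skeleton_area(sk, matrix(FALSE, 15, 40), 3),
               "no edge pixels")
})

test_that("pole elongation is oriented away from the cell and off at p = 0", {
  edges <- straight_cell_edges(15, 60)
  dims <- c(15, 60)
  sk <- skeletonize_mask(pixel_mask(cbind(7L, 7:29)), dims)
  adj <- adjust_skeleton_area(sk, edges, 3)
  prev_area <- sum(dilate_disk(adj, 3))   # cell area consistent with band
  el <- elongate_poles(adj, edges, seg_params(), prev_area = prev_area)
  expect_true(any(el))
  idx <- which(el, arr.ind = TRUE)
  band <- range(which(apply(adj, 2, any)))   # column extent of the band
  # all elongation pixels lie beyond the band's ends, none in the middle
  expect_true(all(idx[, 2] < band[1] + 3 | idx[, 2] > band[2] - 3))
  el0 <- elongate_poles(adj, edges, seg_params(max_pole_elongation = 0),
                        prev_area = 160)
  expect_false(any(el0))
})

test_that("the area cap stops pole admission once the budget is spent", {
  edges <- straight_cell_edges(15, 60)
  dims <- c(15, 60)
  sk <- skeletonize_mask(pixel_mask(cbind(7L, 7:29)), dims)
  adj <- adjust_skeleton_area(sk, edges, 3)
  base <- sum(dilate_disk(adj, 3))
  # exhausted budget: nothing may be admitted
  el0 <- elongate_poles(adj, edges, seg_params(), prev_area = base - 35)
  expect_false(any(el0))
  # generous budget grows strictly more than a tight one
  el_tight <- elongate_poles(adj, edges, seg_params(max_area_increase = 10),
                             prev_area = base)
  el_wide <- elongate_poles(adj, edges, seg_params(max_area_increase = 60),
                            prev_area = base)
  expect_lt(sum(dilate_disk(adj | el_tight, 3)), base + 10 + 1)
  expect_gt(sum(el_wide), sum(el_tight))
})

test_that("an isolated cell segments identically regardless of listing order", {
  cfg <- sim_config(seed = 11, n_frames = 3, division_length_um = 99)
  sim <- simulate_movie(cfg)
  prev <- list(A = sim$truth$masks[[1]]$A)
  r1 <- segment_frame(prev, sim$stacks$phase$images[[2]], frame_index = 1)
  r2 <- segment_frame(prev, sim$stacks$phase$images[[2]], frame_index = 1)
  expect_identical(unclass(r1$masks$A), unclass(r2$masks$A))  # deterministic
  expect_gte(mask_iou(r1$masks$A, sim$truth$masks[[2]]$A), 0.75)
})

test_that("every propagated mask respects the configured area increase", {
  cfg <- sim_config(seed = 7, n_frames = 10)
  sim <- simulate_movie(cfg)
  prev <- list(A = sim$truth$masks[[1]]$A)
  for (f in 1:9) {
    res <- segment_frame(prev, sim$stacks$phase$images[[f + 1]],
                         frame_index = f)
    expect_lte(mask_area(res$masks$A), mask_area(prev$A) + 35)
    prev <- res$masks
  }
})

test_that("propagation is a fixed point on a frozen, noise-free movie", {
  cfg <- sim_config(seed = 9, n_frames = 6, elongation_rate_um_per_h = 0,
                    noise_sd = 0, division_length_um = 99)
  sim <- simulate_movie(cfg)
  prev <- list(A = sim$truth$masks[[1]]$A)
  got <- list()
  for (f in 1:5) {
    res <- segment_frame(prev, sim$stacks$phase$images[[f + 1]],
                         frame_index = f)
    got[[f]] <- res$masks$A
    prev <- res$masks
  }
  for (f in 2:5) expect_equal(mask_iou(got[[f - 1]], got[[f]]), 1)
})

test_that("round-robin conservation: no pixel belongs to two cells", {
  cfg <- sim_config(seed = 1, n_frames = 14)
  sim <- simulate_movie(cfg)
  # start from the first frame with two cells
  f2 <- which(vapply(sim$truth$masks, length, integer(1)) >= 2)[1]
  prev <- sim$truth$masks[[f2]]
  for (f in f2:(length(sim$truth$masks) - 1)) {
    res <- segment_frame(prev, sim$stacks$phase$images[[f + 1]],
                         frame_index = f)
    all_px <- do.call(rbind, lapply(res$masks, unclass))
    expect_equal(nrow(all_px), nrow(unique(all_px)))
    prev <- res$masks
  }
})

test_that("a corrupted frame flags cells and manual correction resumes tracking", {
  cfg <- sim_config(seed = 6, n_frames = 9, division_length_um = 99)
  sim <- simulate_movie(cfg)
  st <- corrupt(sim$stacks$phase, 4, "collapse")
  prev <- list(A = sim$truth$masks[[1]]$A)
  for (f in 1:3)
    prev <- segment_frame(prev, st$images[[f + 1]], frame_index = f)$masks
  res4 <- segment_frame(prev, st$images[[5]], frame_index = 4)
  expect_named(res4$failed, "A")          # collapsed frame: cell lost
  # the user fixes frame 4 with the true outline; tracking resumes
  prev <- list(A = sim$truth$masks[[5]]$A)
  for (f in 5:8)
    prev <- segment_frame(prev, st$images[[f + 1]], frame_index = f)$masks
  expect_gte(mask_iou(prev$A, sim$truth$masks[[9]]$A), 0.75)
})
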