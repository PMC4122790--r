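# project with custom image stacks, ready for measuring
measure_project <- function(stacks, pixel_size = 0.1) {
  prj <- project_open(tempfile(fileext = ".db"),
                      pixel_size_um = pixel_size)
  for (st in stacks) project_add_channel(prj, st)
  prj
}

const_stack <- function(value, n = 4, dim = 24, channel = "ch1", ...) {
  frame_stack(replicate(n, matrix(value, dim, dim), simplify = FALSE),
              channel = channel, ...)
}

disk_mask <- function(ctr = c(11, 11), r = 3) {
  off <- disk_offsets(r)
  pixel_mask(cbind(ctr[1] + off[, 1], ctr[2] + off[, 2]))
}

test_that("statistics over a constant field are exact", {
  img <- matrix(100, 24, 24)
  m <- disk_mask()
  s <- measure_roi(m, img)
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 0)
  expect_equal(s$area_px, 29)
  expect_equal(s$integrated, 2900)
})

test_that("eroding a disk by its radius leaves the centre pixel", {
  img <- matrix(1, 24, 24)
  m <- disk_mask(c(11, 11), 3)
  s <- measure_roi(m, img, erode_px = 3)
  expect_equal(s$area_px, 1)
  # independent check: brute-force erosion of the same disk
  expect_equal(sum(oracle_erode(mask_to_logical(m, c(24, 24)), 3)), 1)
  expect_error(measure_roi(m, img, erode_px = 5), "erosion-too-large")
})

test_that("integrated equals mean times area on random masks and images", {
  set.seed(14)
  for (i in 1:20) {
    img <- matrix(runif(900, 0, 4095), 30, 30)
    m <- random_mask(30, sample(5:200, 1))
    s <- measure_roi(m, img)
    expect_equal(s$integrated, s$mean * s$area_px)
  }
})

test_that("a dim 1-px rim lowers the full-mask mean but not the eroded one", {
  img <- matrix(0, 24, 24)
  mfull <- disk_mask(c(11, 11), 4)
  core <- erode_disk(mask_to_logical(mfull, c(24, 24)), 1)
  img[mask_to_logical(mfull, c(24, 24))] <- 50   # rim value
  img[core] <- 200                               # bright interior
  s_full <- measure_roi(mfull, img)
  s_erode <- measure_roi(mfull, img, erode_px = 1)
  expect_gt(s_erode$mean, s_full$mean)
  expect_equal(s_erode$mean, 200)
})

test_that("background correction subtracts the per-frame background mean", {
  ch1 <- const_stack(100, n = 3, channel = "ch1")
  prj <- measure_project(list(ch1))
  create_initial_cell(prj, "A", disk_mask(), 0)
  save_roi(prj, "A", 1, disk_mask(), "auto")
  save_roi(prj, "A", 2, disk_mask(), "auto")
  set_background_roi(prj, pixel_mask(cbind(0:2, 20L)))
  # no background measured yet: no mean_corrected rows at all
  measure_cells(prj, "ch1")
  expect_equal(run_sql(prj, "SELECT count(*) n FROM measurement
    WHERE variable = 'mean_corrected'")$n, 0)
  # constant background 40
  prj$stacks$ch1$originals <- lapply(prj$stacks$ch1$originals, function(m) {
    m[, 21] <- 40; m
  })
  measure_background(prj, "ch1")
  measure_cells(prj, "ch1")
  mc <- run_sql(prj, "SELECT value FROM measurement
    WHERE variable = 'mean_corrected' ORDER BY frame")
  expect_equal(mc$value, rep(60, 3))
  project_close(prj)
})

test_that("a drifting background leaves the corrected trace flat", {
  imgs <- lapply(0:4, function(f) {
    m <- matrix(30 + 7 * f, 20, 20)     # background drifts linearly
    m[8:12, 8:12] <- 130 + 7 * f        # cell tracks the same drift
    m
  })
  st <- frame_stack(imgs, channel = "ch1")
  prj <- measure_project(list(st))
  create_initial_cell(prj, "A",
                      pixel_mask(as.matrix(expand.grid(7:11, 7:11))), 0)
  for (f in 1:4)
    save_roi(prj, "A", f,
             pixel_mask(as.matrix(expand.grid(7:11, 7:11)), f), "auto")
  set_background_roi(prj, pixel_mask(cbind(0:4, 1L)))
  measure_background(prj, "ch1")
  measure_cells(prj, "ch1")
  mc <- run_sql(prj, "SELECT value FROM measurement
    WHERE variable = 'mean_corrected' ORDER BY frame")
  expect_equal(mc$value, rep(100, 5))
  project_close(prj)
})

test_that("the background overlap warning lists the offending frames", {
  ch1 <- const_stack(10, n = 2)
  prj <- measure_project(list(ch1))
  create_initial_cell(prj, "A", disk_mask(), 0)
  set_background_roi(prj, disk_mask())   # overlaps the cell
  expect_warning(measure_background(prj, "ch1"), "frame\\(s\\) 0")
  project_close(prj)
})

test_that("a steadily elongating cell has an exact linear elongation rate", {
  # bar masks growing 5 px per 10-min frame at 0.1 um/px: 3.0 um/h
  n <- 10
  imgs <- replicate(n, matrix(0, 40, 90), simplify = FALSE)
  st <- frame_stack(imgs, channel = "ch1", pixel_size_um = 0.1, dt_min = 10)
  prj <- measure_project(list(st))
  bar <- function(len, f) pixel_mask(
    as.matrix(expand.grid(row = 18:20, col = 4 + seq_len(len))), f)
  create_initial_cell(prj, "A", bar(20, 0), 0)
  for (f in 1:(n - 1)) save_roi(prj, "A", f, bar(20 + 5 * f, f), "auto")
  measure_cells(prj, character(0))       # geometry only
  gr <- growth_rate(prj, "A")
  expect_equal(gr$elongation_um_per_h, 3.0, tolerance = 1e-8)
  expect_equal(gr$n_frames, n)
  # constant-size cell: both rates are zero
  prj2 <- measure_project(list(const_stack(5, n = 4)))
  create_initial_cell(prj2, "B", disk_mask(), 0)
  for (f in 1:3) save_roi(prj2, "B", f, disk_mask(), "auto")
  measure_cells(prj2, character(0))
  gr2 <- growth_rate(prj2, "B")
  expect_equal(gr2$elongation_um_per_h, 0)
  expect_equal(gr2$exp_area_per_h, 0)
  expect_error(growth_rate(prj2, "missing"), "unknown cell")
  project_close(prj); project_close(prj2)
})

test_that("programmed exponential area growth is recovered within 5%", {
  cfg <- sim_config(seed = 5, n_frames = 20, growth_model =
                      "exponential_area", area_rate_h = 0.4,
                    division_length_um = 999)
  sim <- simulate_movie(cfg)
  prj <- measure_project(sim$stacks["phase"], pixel_size = cfg$pixel_size_um)
  create_initial_cell(prj, "A", sim$truth$masks[[1]]$A, 0)
  for (f in 1:19) save_roi(prj, "A", f, sim$truth$masks[[f + 1]]$A, "manual")
  measure_cells(prj, character(0))
  gr <- growth_rate(prj, "A")
  expect_lt(abs(gr$exp_area_per_h - 0.4) / 0.4, 0.05)
  project_close(prj)
})

test_that("ratio time course is exact on constant channels", {
  g <- const_stack(300, n = 3, channel = "ch1")
  r <- const_stack(100, n = 3, channel = "ch2")
  prj <- measure_project(list(g, r))
  for (nm in c("A", "B")) {
    ctr <- if (nm == "A") c(6, 6) else c(16, 16)
    create_initial_cell(prj, nm, disk_mask(ctr), 0)
    for (f in 1:2) save_roi(prj, nm, f, disk_mask(ctr), "auto")
  }
  set_background_roi(prj, pixel_mask(cbind(0:2, 22L)))
  prj$stacks$ch1$originals <- lapply(prj$stacks$ch1$originals,
                                     function(m) { m[, 23] <- 0; m })
  prj$stacks$ch2$originals <- lapply(prj$stacks$ch2$originals,
                                     function(m) { m[, 23] <- 0; m })
  measure_background(prj)
  measure_cells(prj)
  rt <- ratio_timecourse(prj, "ch1", "ch2")
  expect_equal(rt$mean_ratio, rep(3, 3))
  expect_equal(rt$sd_ratio, rep(0, 3))
  expect_equal(rt$n, rep(2, 3))
  # zero denominator for one cell in one frame: n decremented there
  DBI::dbExecute(prj$db, "UPDATE measurement SET value = 0 WHERE
    cell = 'B' AND frame = 1 AND channel = 'ch2' AND
    variable = 'mean_corrected'")
  rt2 <- ratio_timecourse(prj, "ch1", "ch2")
  expect_equal(rt2$n, c(2, 1, 2))
  expect_equal(rt2$n_excluded, c(0, 1, 0))
  # the shipped SQL query agrees with the R computation
  sq <- run_sql(prj, ratio_query("ch1", "ch2"))
  expect_equal(sq$mean_ratio, rt2$mean_ratio)
  expect_equal(sq$n, rt2$n)
  expect_equal(sq$sd_ratio, rt2$sd_ratio, tolerance = 1e-12)
  project_close(prj)
})

test_that("area in square microns is exactly area_px times pixel_size^2", {
  st <- const_stack(1, n = 2, channel = "ch1")
  prj <- measure_project(list(st), pixel_size = 0.129)
  create_initial_cell(prj, "A", disk_mask(), 0)
  measure_cells(prj, "ch1")
  g <- run_sql(prj, "SELECT variable, value FROM measurement
    WHERE channel = 'geom' AND frame = 0")
  expect_equal(g$value[g$variable == "area_um2"],
               29 * 0.129^2)
  project_close(prj)
})
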