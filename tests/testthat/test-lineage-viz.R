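viz_project <- function(n_frames = 30, dt = 10) {
  prj <- project_open(tempfile(fileext = ".db"), pixel_size_um = 0.1)
  st <- frame_stack(replicate(n_frames, matrix(0, 16, 16),
                              simplify = FALSE), dt_min = dt)
  project_add_channel(prj, st)
  prj
}

tiny_mask <- function(r, f = 0L) pixel_mask(cbind(r, 2L), f)

# build a complete binary lineage of the given depth; divisions spread
# over the movie
make_lineage <- function(prj, depth, n_frames) {
  create_initial_cell(prj, "A", tiny_mask(0L), 0)
  gen_frames <- round(seq(4, n_frames - 3, length.out = depth))
  cells <- "A"
  for (g in seq_len(depth)) {
    f <- gen_frames[g]
    nxt <- character(0)
    for (i in seq_along(cells)) {
      record_division(prj, cells[i], f, tiny_mask(2L * i, f),
                      tiny_mask(2L * i + 1L, f))
      nxt <- c(nxt, paste0(cells[i], c("A", "B")))
    }
    cells <- nxt
  }
  cells
}

# brute-force crossing check on a layout: vertical branches sharing a lane
# with overlapping lifetimes, or a division connector crossing a branch
count_crossings <- function(lay) {
  nd <- lay$nodes
  crossings <- 0L
  for (i in seq_len(nrow(nd))) for (j in seq_len(nrow(nd))) {
    if (j <= i) next
    if (nd$x[i] == nd$x[j] &&
        nd$y_birth[i] < nd$y_end[j] && nd$y_birth[j] < nd$y_end[i])
      crossings <- crossings + 1L
  }
  for (k in seq_len(nrow(lay$edges))) {
    p <- nd[nd$cell == lay$edges$parent[k], ]
    d <- nd[nd$cell == lay$edges$child[k], ]
    x0 <- min(p$x, d$x); x1 <- max(p$x, d$x); y <- p$y_end
    for (i in seq_len(nrow(nd))) {
      if (nd$cell[i] %in% c(lay$edges$parent[k], lay$edges$child[k])) next
      if (nd$x[i] > x0 && nd$x[i] < x1 &&
          nd$y_birth[i] < y && nd$y_end[i] > y)
        crossings <- crossings + 1L
    }
  }
  crossings
}

test_that("a never-dividing cell is a single branch spanning the movie", {
  prj <- viz_project(101, dt = 10)   # frames 0..100 at 10 min
  create_initial_cell(prj, "A", tiny_mask(0L), 0)
  lay <- layout_tree(prj, "A")
  expect_equal(nrow(lay$nodes), 1)
  expect_equal(lay$nodes$y_end - lay$nodes$y_birth, 1000)
  project_close(prj)
})

test_that("one division gives a Y with the parent segment at the division time", {
  prj <- viz_project(30, dt = 10)
  create_initial_cell(prj, "A", tiny_mask(0L), 0)
  record_division(prj, "A", 12, tiny_mask(1L, 12L), tiny_mask(3L, 12L))
  lay <- layout_tree(prj, "A")
  nd <- lay$nodes
  expect_equal(nd$y_end[nd$cell == "A"] - nd$y_birth[nd$cell == "A"], 120)
  expect_equal(nd$y_birth[nd$cell %in% c("AA", "AB")], c(120, 120))
  # A sits midway between its daughters, A-daughter left of B-daughter
  expect_lt(nd$x[nd$cell == "AA"], nd$x[nd$cell == "AB"])
  expect_equal(nd$x[nd$cell == "A"],
               mean(nd$x[nd$cell %in% c("AA", "AB")]))
  project_close(prj)
})

test_that("complete lineages up to depth 4 lay out without crossings", {
  for (depth in 2:4) {
    prj <- viz_project(40)
    leaves <- make_lineage(prj, depth, 40)
    lay <- layout_tree(prj, "A")
    nd <- lay$nodes
    expect_equal(nrow(nd), 2^(depth + 1) - 1)
    lanes <- nd$x[nd$cell %in% leaves]
    expect_equal(sort(lanes), seq_len(2^depth))   # distinct unit lanes
    expect_equal(count_crossings(lay), 0)
    project_close(prj)
  }
})

test_that("a missing daughter is an integrity error", {
  prj <- viz_project(20)
  create_initial_cell(prj, "A", tiny_mask(0L), 0)
  record_division(prj, "A", 8, tiny_mask(1L, 8L), tiny_mask(3L, 8L))
  DBI::dbExecute(prj$db, "DELETE FROM cell WHERE name = 'AB'")
  expect_error(layout_tree(prj, "A"), "missing a daughter")
  expect_error(layout_tree(prj, "AA"), "not an initial cell")
  project_close(prj)
})

read_branch_segments <- function(svg_path) {
  doc <- xml2::read_xml(svg_path)
  lines <- xml2::xml_find_all(doc, ".//*[local-name()='line'][@data-cell]")
  data.frame(
    cell = xml2::xml_attr(lines, "data-cell"),
    frame = as.integer(xml2::xml_attr(lines, "data-frame")),
    y1 = as.numeric(xml2::xml_attr(lines, "y1")),
    y2 = as.numeric(xml2::xml_attr(lines, "y2")),
    width = as.numeric(xml2::xml_attr(lines, "stroke-width")),
    color = xml2::xml_attr(lines, "stroke"))
}

# inject a measurement row directly (layout/render tests need no images);
# the ROI is saved only once per (cell, frame) because re-saving a ROI
# cascades away its measurements
put_meas <- function(prj, cell, frame, channel, variable, value) {
  have <- DBI::dbGetQuery(prj$db,
    "SELECT count(*) n FROM roi WHERE cell = ? AND frame = ?",
    params = list(cell, frame))$n
  if (have == 0)
    save_roi(prj, cell, frame, tiny_mask(0L, frame), "auto")
  DBI::dbExecute(prj$db,
    "INSERT OR REPLACE INTO measurement VALUES (?, ?, ?, ?, ?)",
    params = list(cell, frame, channel, variable, value))
}

test_that("rendered branch extents equal lifetimes and widths follow the variable", {
  prj <- viz_project(21, dt = 10)
  create_initial_cell(prj, "A", tiny_mask(0L), 0)
  for (f in 0:20) {
    put_meas(prj, "A", f, "geom", "area_um2", 1 + 0.1 * f)  # linear growth
    put_meas(prj, "A", f, "ch1", "mean_corrected", 50)
  }
  out <- tempfile(fileext = ".svg")
  info <- render_tree(prj, layout_tree(prj, "A"), style_map(), out)
  expect_length(info$missing, 0)
  seg <- read_branch_segments(out)
  # an open-ended cell spans up to the last frame time: 20 drawn intervals
  expect_equal(nrow(seg), 20)
  # time fidelity: total vertical extent = lifetime / scale, exactly
  expect_equal(max(seg$y2) - min(seg$y1), 200 / info$min_per_px)
  # per-frame extents are one frame interval each
  expect_true(all(abs((seg$y2 - seg$y1) - 10 / info$min_per_px) < 1e-9))
  # affine width map: widths increase linearly with the variable
  seg <- seg[order(seg$frame), ]
  dw <- diff(seg$width)
  expect_true(all(dw > 0))
  expect_lt(diff(range(dw)), 1e-6)
  # constant colour variable: one colour along the branch
  expect_length(unique(seg$color), 1)
  project_close(prj)
})

test_that("a step in the colour variable changes the branch colour class", {
  prj <- viz_project(21, dt = 10)
  prj$stacks$phase <- set_frame_metadata(prj$stacks$phase, 10,
                                         note = "switch to acetate")
  project_add_channel(prj, prj$stacks$phase)
  create_initial_cell(prj, "A", tiny_mask(0L), 0)
  for (f in 0:20) {
    put_meas(prj, "A", f, "geom", "area_um2", 2)
    put_meas(prj, "A", f, "ch1", "mean_corrected",
             if (f >= 10) 300 else 50)   # induction step
  }
  out <- tempfile(fileext = ".svg")
  render_tree(prj, layout_tree(prj, "A"), style_map(), out)
  seg <- read_branch_segments(out)
  # colours before and after the switch are distinct classes
  pre <- unique(seg$color[seg$frame < 10])
  post <- unique(seg$color[seg$frame >= 10])
  expect_length(pre, 1); expect_length(post, 1)
  expect_false(pre == post)
  # widths uniform (constant width variable)
  expect_lt(diff(range(seg$width)), 1e-9)
  # the annotated event line is drawn at its time
  doc <- xml2::read_xml(out)
  ev <- xml2::xml_find_first(doc, ".//*[local-name()='line'][@data-event]")
  expect_false(inherits(ev, "xml_missing"))
  expect_match(xml2::xml_attr(ev, "data-event"), "acetate")
  project_close(prj)
})

test_that("frames lacking the styled variables fall back to neutral style", {
  prj <- viz_project(10, dt = 10)
  create_initial_cell(prj, "A", tiny_mask(0L), 0)
  for (f in 0:4) {
    put_meas(prj, "A", f, "geom", "area_um2", 2)
    put_meas(prj, "A", f, "ch1", "mean_corrected", 10)
  }
  out <- tempfile(fileext = ".svg")
  info <- render_tree(prj, layout_tree(prj, "A"), style_map(), out)
  expect_gt(length(info$missing), 0)
  seg <- read_branch_segments(out)
  expect_true(all(seg$color[seg$frame > 4] == "#bbbbbb"))
  project_close(prj)
})
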