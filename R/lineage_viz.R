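#' @title Lineage tree visualization
#'
#' @description One tree is drawn per initial cell.  Time runs down the
#'   vertical axis (minutes), branch points are division events, and two
#'   measured variables decorate the tree: one mapped linearly to branch
#'   width, the other through a sequential colour map to branch colour.
#'   Styling is per-frame piecewise constant along each branch.  Daughter
#'   "A" is laid out left of daughter "B", so figures are reproducible.
#'
#' @name lineage_viz
NULL

#' Compute the tree layout for one initial cell
#'
#' Leaves occupy consecutive unit lanes; every internal cell sits at the
#' midpoint of its two daughters.  The vertical extent of each cell runs
#' from the time of its birth frame to the time of the frame after its end
#' (so a branch's length is exactly the cell's lifetime in minutes).
#'
#' @param prj a `bt_project`
#' @param root name of an initial cell
#' @return a list of class `tree_layout`: `nodes` (data.frame cell, x,
#'   y_birth, y_end, fate), `edges` (data.frame parent, child), `root`
#' @export
layout_tree <- function(prj, root) {
  tab <- lineage_table(prj)
  if (!root %in% tab$name) stop("unknown root cell '", root, "'")
  if (!is.na(tab$parent[tab$name == root]))
    stop("'", root, "' is not an initial cell")
  fams <- tab[tab$name == root | startsWith(tab$name, root), ]
  frames <- DBI::dbGetQuery(prj$db,
    "SELECT frame_index, time_min FROM frame ORDER BY frame_index")
  if (nrow(frames) == 0) stop("no frame times recorded")
  tmax <- max(frames$time_min)
  time_of <- function(f) {
    i <- match(f, frames$frame_index)
    ifelse(is.na(i), tmax, frames$time_min[i])
  }
  # integrity: a divided cell must have both daughters on record
  for (nm in fams$name[fams$fate == "divided"]) {
    if (!all(paste0(nm, c("A", "B")) %in% fams$name))
      stop("inconsistent lineage: divided cell '", nm,
           "' is missing a daughter")
  }
  lane <- 0
  nodes <- list()
  edges <- list()
  assign_x <- function(nm) {
    row <- fams[fams$name == nm, ]
    daughters <- paste0(nm, c("A", "B"))
    if (row$fate == "divided" && all(daughters %in% fams$name)) {
      xa <- assign_x(daughters[1])          # A goes left
      xb <- assign_x(daughters[2])
      x <- (xa + xb) / 2
      edges[[length(edges) + 1]] <<- data.frame(parent = nm,
                                                child = daughters)
    } else {
      lane <<- lane + 1
      x <- lane
    }
    y0 <- time_of(row$birth_frame)
    y1 <- if (is.na(row$end_frame)) tmax else time_of(row$end_frame + 1L)
    nodes[[length(nodes) + 1]] <<- data.frame(cell = nm, x = x,
                                              y_birth = y0, y_end = y1,
                                              fate = row$fate)
    x
  }
  assign_x(root)
  nodes <- do.call(rbind, nodes)
  structure(list(nodes = nodes[order(nodes$cell), ],
                 edges = if (length(edges)) do.call(rbind, edges)
                 else data.frame(parent = character(0),
                                 child = character(0)),
                 root = root),
            class = "tree_layout")
}

#' Style mapping for a rendered tree
#'
#' @param width_var variable mapped to branch width (e.g. `"area_um2"`)
#' @param color_var variable mapped to branch colour (e.g. a channel's
#'   `"mean_corrected"`)
#' @param width_channel,color_channel measurement channels the variables
#'   live under (`"geom"` for the geometric variables)
#' @param width_range branch width range in pixels (`c(min, max)`)
#' @param palette colour map name passed to [grDevices::hcl.colors()]
#' @param color_domain optional fixed `c(min, max)` domain for the colour
#'   scale; defaults to the observed range; values outside are clamped
#' @return a list of class `style_map`
#' @export
style_map <- function(width_var = "area_um2", color_var = "mean_corrected",
                      width_channel = "geom", color_channel = "ch1",
                      width_range = c(2, 14), palette = "viridis",
                      color_domain = NULL) {
  stopifnot(width_range[1] > 0, width_range[2] >= width_range[1])
  structure(list(width_var = width_var, color_var = color_var,
                 width_channel = width_channel,
                 color_channel = color_channel,
                 width_range = width_range, palette = palette,
                 color_domain = color_domain), class = "style_map")
}

svg_esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))

#' Render a lineage tree to SVG
#'
#' Each branch is drawn as one vertical line segment per measured frame,
#' with `stroke-width` an affine function of the width variable and
#' `stroke` taken from the colour map; frames without a measurement use a
#' neutral grey hairline (and are reported).  Censored cells end with an
#' open circle, dead cells with a filled one.  Horizontal connectors mark
#' divisions; dashed horizontal lines mark annotated events (frame notes),
#' e.g. a medium switch.  A colour bar and width reference are included.
#' Every per-frame segment carries `data-cell` and `data-frame` attributes
#' so the emitted primitives can be read back programmatically.
#'
#' @param prj a `bt_project` with measurements
#' @param layout a [layout_tree()] result
#' @param style a [style_map()]
#' @param out output file path (`.svg`)
#' @param lane_px horizontal pixels per lane
#' @param min_per_px vertical minutes per pixel
#' @return invisibly, a list with the output path, the y-axis scale, and
#'   any cells/frames that lacked the styling variables
#' @export
render_tree <- function(prj, layout, style = style_map(), out,
                        lane_px = 60, min_per_px = 2) {
  nodes <- layout$nodes
  frames <- DBI::dbGetQuery(prj$db,
    "SELECT frame_index, time_min, note FROM frame ORDER BY frame_index")
  meas <- DBI::dbGetQuery(prj$db,
    "SELECT cell, frame, channel, variable, value FROM measurement")
  getvar <- function(cell, frame, var, chan) {
    v <- meas$value[meas$cell == cell & meas$frame == frame &
                      meas$variable == var & meas$channel == chan]
    if (length(v)) v[1] else NA_real_
  }
  margin <- 40
  width_px <- max(nodes$x) * lane_px + 2 * margin + 120  # room for legend
  tmax <- max(nodes$y_end)
  height_px <- tmax / min_per_px + 2 * margin
  xpix <- function(x) margin + x * lane_px
  ypix <- function(t) margin + t / min_per_px

  wv <- meas$value[meas$variable == style$width_var &
                     meas$channel == style$width_channel]
  cvals <- meas$value[meas$variable == style$color_var &
                        meas$channel == style$color_channel]
  wdom <- if (length(wv)) range(wv) else c(0, 1)
  cdom <- style$color_domain %||%
    (if (length(cvals)) range(cvals) else c(0, 1))
  pal <- hcl.colors(64, style$palette)
  wmap <- function(v) {
    if (wdom[2] == wdom[1]) return(mean(style$width_range))
    v <- pmin(pmax(v, wdom[1]), wdom[2])
    style$width_range[1] + (v - wdom[1]) / (wdom[2] - wdom[1]) *
      diff(style$width_range)
  }
  cmap <- function(v) {
    if (cdom[2] == cdom[1]) return(pal[32])
    v <- pmin(pmax(v, cdom[1]), cdom[2])
    pal[1 + round((v - cdom[1]) / (cdom[2] - cdom[1]) * 63)]
  }

  el <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
    width_px, height_px),
    '<rect width="100%" height="100%" fill="white"/>')
  missing <- character(0)

  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    x <- xpix(nd$x)
    fr <- frames[frames$time_min >= nd$y_birth &
                   frames$time_min < nd$y_end, , drop = FALSE]
    if (nrow(fr) == 0) next
    for (k in seq_len(nrow(fr))) {
      t0 <- fr$time_min[k]
      t1 <- if (k < nrow(fr)) fr$time_min[k + 1] else nd$y_end
      wv1 <- getvar(nd$cell, fr$frame_index[k], style$width_var,
                    style$width_channel)
      cv1 <- getvar(nd$cell, fr$frame_index[k], style$color_var,
                    style$color_channel)
      if (is.na(wv1) || is.na(cv1)) {
        missing <- c(missing, sprintf("%s@%d", nd$cell, fr$frame_index[k]))
        sw <- 1; colr <- "#bbbbbb"
      } else {
        sw <- wmap(wv1); colr <- cmap(cv1)
      }
      el <- c(el, sprintf(
        paste0('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" ',
               'stroke="%s" stroke-width="%.3f" data-cell="%s" ',
               'data-frame="%d"/>'),
        x, ypix(t0), x, ypix(t1), colr, sw, svg_esc(nd$cell),
        fr$frame_index[k]))
    }
    # terminal marker
    if (nd$fate %in% c("censored", "ignored")) {
      el <- c(el, sprintf(
        '<circle cx="%.2f" cy="%.2f" r="3" fill="white" stroke="black"/>',
        x, ypix(nd$y_end)))
    } else if (nd$fate == "dead") {
      el <- c(el, sprintf(
        '<circle cx="%.2f" cy="%.2f" r="3" fill="black"/>',
        x, ypix(nd$y_end)))
    }
    # cell name at mid-branch
    el <- c(el, sprintf(
      '<text x="%.2f" y="%.2f" font-size="8" fill="#555">%s</text>',
      x + 4, ypix((nd$y_birth + nd$y_end) / 2), svg_esc(nd$cell)))
  }
  # division connectors
  for (i in seq_len(nrow(layout$edges))) {
    p <- nodes[nodes$cell == layout$edges$parent[i], ]
    d <- nodes[nodes$cell == layout$edges$child[i], ]
    el <- c(el, sprintf(
      paste0('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="black" ',
             'stroke-width="1" data-connector="%s"/>'),
      xpix(p$x), ypix(p$y_end), xpix(d$x), ypix(d$y_birth),
      svg_esc(d$cell)))
  }
  # event annotations: dashed horizontal lines at noted frames
  noted <- frames[!is.na(frames$note) & nzchar(frames$note), , drop = FALSE]
  for (i in seq_len(nrow(noted))) {
    y <- ypix(noted$time_min[i])
    el <- c(el, sprintf(
      paste0('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="red" ',
             'stroke-dasharray="6,4" stroke-width="1" data-event="%s"/>'),
      margin / 2, y, width_px - 120, y, svg_esc(noted$note[i])),
      sprintf('<text x="%.2f" y="%.2f" font-size="9" fill="red">%s</text>',
              margin / 2, y - 3, svg_esc(noted$note[i])))
  }
  # legend: colour bar + width reference
  lx <- width_px - 100
  for (j in 1:64) {
    el <- c(el, sprintf(
      '<rect x="%.1f" y="%.1f" width="12" height="2" fill="%s"/>',
      lx, margin + (64 - j) * 2, pal[j]))
  }
  el <- c(el,
    sprintf('<text x="%.1f" y="%.1f" font-size="8">%.3g</text>',
            lx + 15, margin + 130, cdom[1]),
    sprintf('<text x="%.1f" y="%.1f" font-size="8">%.3g</text>',
            lx + 15, margin + 6, cdom[2]),
    sprintf('<text x="%.1f" y="%.1f" font-size="9">%s</text>',
            lx, margin - 10, svg_esc(style$color_var)),
    sprintf(paste0('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" ',
                   'stroke="black" stroke-width="%.1f"/>'),
            lx, margin + 160, lx + 30, margin + 160, style$width_range[2]),
    sprintf('<text x="%.1f" y="%.1f" font-size="8">%s = %.3g</text>',
            lx, margin + 175, svg_esc(style$width_var), wdom[2]))
  el <- c(el, "</svg>")
  writeLines(el, out)
  invisible(list(path = out, min_per_px = min_per_px, margin = margin,
                 lane_px = lane_px, missing = missing))
}
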