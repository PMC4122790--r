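#' @title Ground-truthed synthetic movies
#'
#' @description Generates multi-channel time-lapse movies of worm-shaped
#'   cells that reproduce the segmentation challenges of mycobacterial
#'   microcolonies: closely packed cells whose shared boundaries often show
#'   no edge contrast, no visible division site, and small frame-to-frame
#'   change.  Cells are constant-width tubes around elongating poly-line
#'   backbones; growth is strictly polar and, after a division, directed
#'   away from the septum (the new pole lags, as in mycobacteria), so
#'   daughters stay abutting end to end.  Two fluorescence channels are
#'   rendered from per-cell expression levels: an inducible channel that
#'   steps up by a configurable fold at the medium-switch frame, and a
#'   constitutive reference channel.  Every frame comes with ground-truth
#'   masks and a lineage/measurement table, and a fixed seed fully
#'   determines the output.
#'
#' @name synthetic
NULL

#' Simulation configuration
#'
#' Defaults describe a slow-growing mycobacterium-like colony imaged every
#' 10 minutes at 0.129 um/px: cells about 0.9 um wide, elongating at
#' 1.2 um/h, dividing near 6 um with per-cell jitter, with a 6-fold step
#' induction of the `ch1` reporter at the switch frame.
#'
#' @param seed integer seed; fully determines the movie
#' @param image_size canvas side in pixels
#' @param pixel_size_um microns per pixel
#' @param n_frames number of frames
#' @param dt_min minutes between frames
#' @param initial_cells number of founder cells (1 or 2)
#' @param cell_width_um full cell width; the tube radius in pixels is
#'   derived as `round((cell_width_um / pixel_size_um - 1) / 2)`
#' @param elongation_rate_um_per_h polar elongation rate (linear growth
#'   model)
#' @param division_length_um mean length at division
#' @param division_jitter_um SD of the per-cell division length
#' @param initial_length_um founder length at frame 0
#' @param noise_sd additive Gaussian noise SD, 8-bit units, all channels
#' @param halo_strength brightness of the phase halo above background
#' @param contact_edge_fraction probability that the shared boundary of a
#'   touching cell pair shows no edge contrast
#' @param switch_frame 0-based frame of the medium switch
#' @param induction_fold fold change of the inducible channel at the switch
#' @param gfp_baseline pre-switch mean level of the inducible channel
#' @param constitutive_level mean level of the reference channel
#' @param fluor_background background level of the fluorescence channels
#' @param phase_background background level of the phase channel
#' @param wiggle_sd SD (radians) of the per-step growth direction wander
#' @param growth_model `"linear"` (polar, um/h) or `"exponential_area"`
#'   (area grows as `exp(area_rate_h * t)`, straight cell, no wander)
#' @param area_rate_h exponential area growth rate, 1/h
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, image_size = 192L, pixel_size_um = 0.129,
                       n_frames = 30L, dt_min = 10, initial_cells = 1L,
                       cell_width_um = 0.9,
                       elongation_rate_um_per_h = 1.2,
                       division_length_um = 6, division_jitter_um = 0.4,
                       initial_length_um = 4.5,
                       noise_sd = 4, halo_strength = 60,
                       contact_edge_fraction = 0.5,
                       switch_frame = 15L, induction_fold = 6,
                       gfp_baseline = 25, constitutive_level = 100,
                       fluor_background = 20, phase_background = 128,
                       wiggle_sd = 0.04,
                       growth_model = c("linear", "exponential_area"),
                       area_rate_h = 0.4) {
  growth_model <- match.arg(growth_model)
  stopifnot(elongation_rate_um_per_h >= 0, division_length_um > 0,
            induction_fold >= 1, noise_sd >= 0, initial_cells >= 1,
            contact_edge_fraction >= 0, contact_edge_fraction <= 1)
  cfg <- as.list(environment())
  cfg$radius_px <- max(1L, as.integer(round(
    (cell_width_um / pixel_size_um - 1) / 2)))
  cfg$px_per_frame <- elongation_rate_um_per_h * dt_min / 60 / pixel_size_um
  structure(cfg, class = "sim_config")
}

# --- backbone mechanics -----------------------------------------------------

new_sim_cell <- function(name, backbone, grow_end, parent, birth, cfg) {
  list(name = name, backbone = backbone, grow_end = grow_end,
       parent = parent, birth = birth,
       div_len_px = max(10, rnorm(1, cfg$division_length_um,
                                  cfg$division_jitter_um) /
                          cfg$pixel_size_um),
       g_level = cfg$gfp_baseline * exp(rnorm(1, 0, 0.1)),
       r_level = cfg$constitutive_level * exp(rnorm(1, 0, 0.1)))
}

# extend the backbone by `amount` points at the given end ("head" = row 1)
extend_backbone <- function(bb, amount, end, wiggle_sd) {
  while (amount >= 1) {
    n <- nrow(bb)
    if (end == "head") {
      tangent <- bb[1, ] - bb[2, ]
    } else {
      tangent <- bb[n, ] - bb[n - 1, ]
    }
    ang <- atan2(tangent[1], tangent[2]) + rnorm(1, 0, wiggle_sd)
    step <- c(sin(ang), cos(ang))
    if (end == "head") bb <- rbind(bb[1, ] + step, bb)
    else bb <- rbind(bb, bb[n, ] + step)
    amount <- amount - 1
  }
  list(backbone = bb, residual = amount)
}

grow_sim_cell <- function(cell, px, cfg) {
  pending <- (cell$pending %||% 0) + px
  ends <- switch(cell$grow_end, both = c("head", "tail"),
                 head = "head", tail = "tail")
  # alternate between ends for bipolar growth
  while (pending >= 1) {
    for (e in ends) {
      if (pending < 1) break
      r <- extend_backbone(cell$backbone, 1, e, cfg$wiggle_sd)
      cell$backbone <- r$backbone
      pending <- pending - 1
    }
  }
  cell$pending <- pending
  cell
}

divide_sim_cell <- function(cell, frame, cfg) {
  n <- nrow(cell$backbone)
  u <- runif(1, 0.4, 0.6)          # septum lands in the middle 20%
  cut <- max(2L, min(n - 2L, as.integer(round(u * n))))
  a <- new_sim_cell(paste0(cell$name, "A"),
                    cell$backbone[seq_len(cut), , drop = FALSE],
                    "head", cell$name, frame, cfg)
  b <- new_sim_cell(paste0(cell$name, "B"),
                    cell$backbone[(cut + 1L):n, , drop = FALSE],
                    "tail", cell$name, frame, cfg)
  # expression levels are inherited with small partition noise
  a$g_level <- cell$g_level * exp(rnorm(1, 0, 0.05))
  b$g_level <- cell$g_level * exp(rnorm(1, 0, 0.05))
  a$r_level <- cell$r_level * exp(rnorm(1, 0, 0.05))
  b$r_level <- cell$r_level * exp(rnorm(1, 0, 0.05))
  list(a, b)
}

# minimal distance between two backbones (subsampled), with the distance of
# each closest point from its backbone's nearest pole (in points)
backbone_min_dist <- function(b1, b2) {
  i1 <- seq(1, nrow(b1), by = 2); i2 <- seq(1, nrow(b2), by = 2)
  d2 <- outer(b1[i1, 1], b2[i2, 1], "-")^2 + outer(b1[i1, 2], b2[i2, 2], "-")^2
  w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  k1 <- i1[w[1]]; k2 <- i2[w[2]]
  list(d = sqrt(min(d2)), p1 = b1[k1, ], p2 = b2[k2, ],
       end1 = min(k1 - 1, nrow(b1) - k1), end2 = min(k2 - 1, nrow(b2) - k2))
}

# unit vector pointing from the given tip (1 = head, 2 = tail) into the cell
axis_away_from_tip <- function(bb, tip) {
  n <- nrow(bb)
  k <- min(6L, n - 1L)
  v <- if (tip == 1) bb[1 + k, ] - bb[1, ] else bb[n - k, ] - bb[n, ]
  l <- sqrt(sum(v^2))
  if (l < 1e-9) c(1, 0) else v / l
}

siblings <- function(a, b) {
  identical(a$parent, b$parent) && !is.null(a$parent)
}

# Resolve packing.  Pole-to-pole contacts (cells abutting end to end in a
# chain, e.g. freshly divided siblings or cousins growing at the septum)
# relax to a small tip separation along the axis -- polar growth pushes the
# chain apart, as in a real microcolony.  Flank contacts relax laterally,
# gently, until the tubes are tangent.
repel_cells <- function(cells, cfg) {
  target_flank <- 2 * cfg$radius_px + 1
  target_pole <- 3
  if (length(cells) < 2) return(cells)
  # per-cell displacement budget per frame keeps apparent motion small, as
  # in a slowly rearranging microcolony; residual overlap is resolved when
  # the disjoint truth masks are assigned
  budget <- rep(1.75, length(cells))
  for (iter in 1:6) {
    moved <- FALSE
    for (i in seq_along(cells)) for (j in seq_along(cells)) {
      if (j <= i) next
      # a pair whose tips are close is in the pole (chain) regime; the
      # flank rule is suspended there, otherwise the two targets fight at
      # bent chain junctions and drag cells sideways
      b1 <- cells[[i]]$backbone; b2 <- cells[[j]]$backbone
      tips1 <- b1[c(1, nrow(b1)), , drop = FALSE]
      tips2 <- b2[c(1, nrow(b2)), , drop = FALSE]
      td2 <- outer(tips1[, 1], tips2[, 1], "-")^2 +
        outer(tips1[, 2], tips2[, 2], "-")^2
      tw <- which(td2 == min(td2), arr.ind = TRUE)[1, ]
      pole_contact <- sqrt(min(td2)) <= 5
      if (pole_contact) {
        md <- list(d = sqrt(min(td2)), p1 = tips1[tw[1], ],
                   p2 = tips2[tw[2], ])
      } else {
        md <- backbone_min_dist(b1, b2)
      }
      target <- if (pole_contact) target_pole else target_flank
      if (!pole_contact && siblings(cells[[i]], cells[[j]])) next
      if (md$d < target - 0.5) {
        shift <- (target - md$d) / 2
        if (pole_contact) {
          # chain expansion: each cell retreats along its own axis, away
          # from the contacting tip
          diri <- axis_away_from_tip(b1, tw[1])
          dirj <- axis_away_from_tip(b2, tw[2])
        } else {
          dir <- md$p1 - md$p2
          if (sqrt(sum(dir^2)) < 1e-9) dir <- c(1, 0)
          dir <- dir / sqrt(sum(dir^2))
          diri <- dir; dirj <- -dir
          shift <- min(0.5, shift)
        }
        si <- min(shift, budget[i]); sj <- min(shift, budget[j])
        if (si <= 0 && sj <= 0) next
        cells[[i]]$backbone <- sweep(cells[[i]]$backbone, 2, diri * si, "+")
        cells[[j]]$backbone <- sweep(cells[[j]]$backbone, 2, dirj * sj, "+")
        budget[i] <- budget[i] - si; budget[j] <- budget[j] - sj
        if (si > 0.01 || sj > 0.01) moved <- TRUE
      }
    }
    if (!moved) break
  }
  cells
}

# --- rasterization and rendering --------------------------------------------

raster_backbone <- function(bb, n) {
  px <- unique(cbind(pmin(pmax(round(bb[, 1]), 1), n),
                     pmin(pmax(round(bb[, 2]), 1), n)))
  px
}

tube_mask <- function(bb_px, r, n) {
  off <- disk_offsets(r)
  rows <- rep(bb_px[, 1], each = nrow(off)) + off[, 1]
  cols <- rep(bb_px[, 2], each = nrow(off)) + off[, 2]
  keep <- rows >= 1 & rows <= n & cols >= 1 & cols <= n
  m <- matrix(FALSE, n, n)
  m[cbind(rows[keep], cols[keep])] <- TRUE
  m
}

# disjoint per-cell truth masks: contested pixels go to the nearest backbone
assign_truth_masks <- function(cells, cfg) {
  n <- cfg$image_size; r <- cfg$radius_px
  tubes <- lapply(cells, function(cl)
    tube_mask(raster_backbone(cl$backbone, n), r, n))
  names(tubes) <- vapply(cells, `[[`, character(1), "name")
  if (length(tubes) > 1) {
    overlap <- Reduce(`+`, tubes) > 1
    if (any(overlap)) {
      pix <- which(overlap, arr.ind = TRUE)
      dists <- vapply(cells, function(cl) {
        bb <- cl$backbone
        vapply(seq_len(nrow(pix)), function(k)
          min((bb[, 1] - pix[k, 1])^2 + (bb[, 2] - pix[k, 2])^2), numeric(1))
      }, numeric(nrow(pix)))
      dists <- matrix(dists, nrow = nrow(pix))
      winner <- max.col(-dists, ties.method = "first")
      for (ci in seq_along(tubes)) {
        lose <- pix[winner != ci, , drop = FALSE]
        tubes[[ci]][lose] <- FALSE
      }
    }
  }
  tubes
}

render_phase <- function(tubes, cells, cfg, edge_visible) {
  n <- cfg$image_size
  img <- matrix(cfg$phase_background, n, n)
  un <- Reduce(`|`, tubes)
  img[un] <- cfg$phase_background - 58
  # the phase halo decays smoothly away from the cell body (as real halos
  # do), so the only sharp contour is the cell boundary itself
  dh <- as.matrix(EBImage::distmap(!un))
  halo <- !un & dh <= 6
  img[halo] <- cfg$phase_background +
    cfg$halo_strength * exp(-(dh[halo] - 1) / 1.5)
  # contact bands: visible pairs get a bright separation line; invisible
  # pairs get their halo suppressed so the shared boundary has no contrast
  if (length(tubes) > 1) {
    nm <- names(tubes)
    for (i in seq_along(tubes)) for (j in seq_along(tubes)) {
      if (j <= i) next
      key <- paste(sort(c(nm[i], nm[j])), collapse = "|")
      if (is.null(edge_visible[[key]])) next
      band <- dilate_disk(tubes[[i]], 2) & dilate_disk(tubes[[j]], 2)
      if (isTRUE(edge_visible[[key]])) {
        line <- dilate_disk(tubes[[i]], 1) & dilate_disk(tubes[[j]], 1)
        img[line] <- cfg$phase_background + cfg$halo_strength
      } else {
        img[band & !un] <- cfg$phase_background - 58
      }
    }
  }
  img + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n)
}

render_fluor <- function(tubes, levels, cfg) {
  n <- cfg$image_size
  img <- matrix(cfg$fluor_background, n, n)
  for (i in seq_along(tubes)) img[tubes[[i]]] <- cfg$fluor_background +
    levels[i]
  img + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n)
}

clip8 <- function(img) pmin(pmax(round(img), 0), 255)

# --- the simulator ----------------------------------------------------------

#' Simulate a ground-truthed movie
#'
#' @param cfg a [sim_config()]
#' @return list with `stacks` (named `frame_stack`s: `phase`, `ch1`
#'   inducible, `ch2` constitutive), and `truth`: `masks` (per frame, a
#'   named list of [pixel_mask()]s), `lineage` (data.frame name, parent,
#'   birth_frame, end_frame, fate), `cells` (per-cell per-frame true
#'   length, area and expression levels), `truncated` (TRUE when the
#'   colony hit the canvas border and the movie stopped early), and the
#'   config
#' @export
simulate_movie <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$image_size
  founders <- list()
  for (i in seq_len(cfg$initial_cells)) {
    len0 <- cfg$initial_length_um / cfg$pixel_size_um
    ang <- runif(1, 0, pi)
    if (cfg$growth_model == "exponential_area") ang <- 0
    ctr <- if (cfg$initial_cells == 1) c(n / 2, n / 2)
    else c(n * i / (cfg$initial_cells + 1), n / 2)
    ts <- seq(-len0 / 2, len0 / 2, by = 1)
    bb <- cbind(ctr[1] + ts * sin(ang), ctr[2] + ts * cos(ang))
    founders[[i]] <- new_sim_cell(LETTERS[i], bb, "both", NULL, 0L, cfg)
  }
  cells <- founders
  lineage <- list()
  for (cl in cells) lineage[[cl$name]] <- list(parent = NA_character_,
                                               birth = 0L, end = NA_integer_,
                                               fate = "censored")
  wiggle <- if (cfg$growth_model == "exponential_area") 0 else cfg$wiggle_sd
  cfg_run <- cfg; cfg_run$wiggle_sd <- wiggle
  width_px <- 2 * cfg$radius_px + 1
  cap_px <- nrow(disk_offsets(cfg$radius_px)) - width_px  # straight-tube caps
  edge_visible <- list()
  phase <- list(); ch1 <- list(); ch2 <- list()
  truth_masks <- list(); truth_rows <- list()
  truncated <- FALSE
  for (f in seq_len(cfg$n_frames) - 1L) {
    if (f > 0) {
      t_h <- f * cfg$dt_min / 60
      grown <- list()
      for (cl in cells) {
        if (cfg$growth_model == "exponential_area") {
          n0 <- cfg$initial_length_um / cfg$pixel_size_um
          a0 <- width_px * n0 + cap_px
          target <- (a0 * exp(cfg$area_rate_h * t_h) - cap_px) / width_px
          px <- max(0, target - nrow(cl$backbone))
        } else {
          px <- cfg$px_per_frame
        }
        cl <- grow_sim_cell(cl, px, cfg_run)
        if (cfg$growth_model == "linear" &&
            nrow(cl$backbone) >= cl$div_len_px) {
          ds <- divide_sim_cell(cl, f, cfg)
          lineage[[cl$name]]$end <- f - 1L
          lineage[[cl$name]]$fate <- "divided"
          for (d in ds) lineage[[d$name]] <- list(parent = cl$name,
                                                  birth = f,
                                                  end = NA_integer_,
                                                  fate = "censored")
          grown <- c(grown, ds)
        } else {
          grown <- c(grown, list(cl))
        }
      }
      cells <- repel_cells(grown, cfg)
    }
    # truncation: colony reaching the canvas border stops the movie
    margin <- cfg$radius_px + 3
    for (cl in cells) {
      if (min(cl$backbone) < margin || max(cl$backbone) > n - margin) {
        truncated <- TRUE
        break
      }
    }
    if (truncated) break
    ord <- order(vapply(cells, `[[`, character(1), "name"))
    cells <- cells[ord]
    tubes <- assign_truth_masks(cells, cfg)
    # decide, once per pair, whether a new contact shows an edge
    if (length(tubes) > 1) {
      nm <- names(tubes)
      for (i in seq_along(cells)) for (j in seq_along(cells)) {
        if (j <= i) next
        key <- paste(sort(c(nm[i], nm[j])), collapse = "|")
        if (!is.null(edge_visible[[key]])) next
        md <- backbone_min_dist(cells[[i]]$backbone, cells[[j]]$backbone)
        if (md$d <= 2 * cfg$radius_px + 2.5)
          edge_visible[[key]] <- runif(1) >= cfg$contact_edge_fraction
      }
    }
    induced <- f >= cfg$switch_frame
    g_levels <- vapply(cells, function(cl)
      cl$g_level * if (induced) cfg$induction_fold else 1, numeric(1))
    r_levels <- vapply(cells, `[[`, numeric(1), "r_level")
    phase[[length(phase) + 1]] <- clip8(render_phase(tubes, cells, cfg,
                                                     edge_visible))
    ch1[[length(ch1) + 1]] <- clip8(render_fluor(tubes, g_levels, cfg))
    ch2[[length(ch2) + 1]] <- clip8(render_fluor(tubes, r_levels, cfg))
    truth_masks[[length(truth_masks) + 1]] <- lapply(tubes, function(tb)
      mask_from_logical(tb, f))
    for (i in seq_along(cells)) {
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        cell = cells[[i]]$name, frame = f,
        length_px = nrow(cells[[i]]$backbone),
        length_um = nrow(cells[[i]]$backbone) * cfg$pixel_size_um,
        area_px = sum(tubes[[i]]),
        area_um2 = sum(tubes[[i]]) * cfg$pixel_size_um^2,
        g_level = g_levels[i], r_level = r_levels[i])
    }
  }
  nf <- length(phase)
  if (nf == 0) stop("simulation produced no frames (canvas too small)")
  times <- cfg$dt_min * (seq_len(nf) - 1)
  mk <- function(frames, channel) {
    st <- frame_stack(frames, channel = channel,
                      pixel_size_um = cfg$pixel_size_um, times = times)
    st
  }
  lin <- do.call(rbind, lapply(names(lineage), function(nm)
    data.frame(name = nm, parent = lineage[[nm]]$parent,
               birth_frame = lineage[[nm]]$birth,
               end_frame = lineage[[nm]]$end, fate = lineage[[nm]]$fate)))
  lin <- lin[order(lin$name), ]
  rownames(lin) <- NULL
  list(stacks = list(phase = mk(phase, "phase"), ch1 = mk(ch1, "ch1"),
                     ch2 = mk(ch2, "ch2")),
       truth = list(masks = truth_masks, lineage = lin,
                    cells = do.call(rbind, truth_rows),
                    truncated = truncated, config = cfg))
}

#' Corrupt one frame of a stack
#'
#' Produces realistic failure fixtures: `"blur"` applies a strong Gaussian
#' blur (an out-of-focus frame), `"collapse"` flattens the frame to its
#' modal intensity (an illumination failure).  Working copy and original
#' are both affected.
#'
#' @param stack a `frame_stack`
#' @param frame 0-based frame index
#' @param mode `"blur"` or `"collapse"`
#' @return the modified `frame_stack`
#' @export
corrupt <- function(stack, frame, mode = c("blur", "collapse")) {
  mode <- match.arg(mode)
  i <- frame + 1L
  stopifnot(i >= 1, i <= n_frames(stack))
  fx <- function(img) {
    if (mode == "blur") as.matrix(EBImage::gblur(img, sigma = 6))
    else matrix(modal_value(img), nrow(img), ncol(img))
  }
  stack$images[[i]] <- round(fx(stack$images[[i]]))
  stack$originals[[i]] <- fx(stack$originals[[i]])
  stack
}
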