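#' @title Lineage bookkeeping
#'
#' @description Cells are named binomially: initial cells get single letters
#'   (A, B, ...) and each division appends "A" or "B" to the parent's name,
#'   so cell A divides into AA and AB, and AB into ABA and ABB.  The
#'   generation of a cell is `nchar(name) - 1`.  Division events are
#'   annotated by the user: the annotated frame is the first frame of the
#'   daughters' existence, and the parent's last frame is the one before.
#'   Daughter "A" is the first mask supplied; the order is recorded but no
#'   pole identity is implied.
#'
#' @name lineage
NULL

cell_exists <- function(prj, name) {
  DBI::dbGetQuery(prj$db, "SELECT count(*) n FROM cell WHERE name = ?",
                  params = list(name))$n > 0
}

get_cell <- function(prj, name) {
  row <- DBI::dbGetQuery(prj$db, "SELECT * FROM cell WHERE name = ?",
                         params = list(name))
  if (nrow(row) == 0) stop("unknown cell '", name, "'")
  row
}

#' Create an initial (root) cell
#'
#' @param prj a `bt_project`
#' @param name a single capital letter A-Z, not yet used
#' @param mask the user-delineated [pixel_mask()] of the cell
#' @param frame 0-based frame of the outline (usually 0)
#' @return the cell's database row, invisibly
#' @export
create_initial_cell <- function(prj, name, mask, frame = 0L) {
  if (!grepl("^[A-Z]$", name))
    stop("initial cells are named with a single letter A-Z, got '", name, "'")
  if (cell_exists(prj, name)) stop("cell '", name, "' already exists")
  if (nrow(mask) == 0) stop("initial mask is empty")
  DBI::dbExecute(prj$db,
    "INSERT INTO cell (name, parent, birth_frame) VALUES (?, NULL, ?)",
    params = list(name, as.integer(frame)))
  save_roi(prj, name, frame, mask, "manual")
  log_event(prj, "create-cell", frame, list(name = name))
  invisible(get_cell(prj, name))
}

masks_disjoint <- function(a, b) {
  !any(paste(a[, 1], a[, 2]) %in% paste(b[, 1], b[, 2]))
}

#' Record a division event
#'
#' The parent's fate becomes `divided` with its last frame set to
#' `frame - 1`; two daughters named `parent + "A"` and `parent + "B"` are
#' born at `frame` with the supplied manual masks, from which subsequent
#' propagation seeds.
#'
#' @param prj a `bt_project`
#' @param parent name of the dividing cell
#' @param frame 0-based first frame of the daughters' existence (must not be
#'   an excluded frame)
#' @param maskA,maskB disjoint, nonempty daughter masks; `maskA` belongs to
#'   the daughter whose name ends in "A"
#' @return names of the two daughters, invisibly
#' @export
record_division <- function(prj, parent, frame, maskA, maskB) {
  p <- get_cell(prj, parent)
  if (p$fate != "censored")
    stop("cell '", parent, "' cannot divide: fate is already '", p$fate, "'")
  if (frame <= p$birth_frame)
    stop("division frame must come after the parent's birth")
  excl <- DBI::dbGetQuery(prj$db,
    "SELECT excluded FROM frame WHERE frame_index = ?",
    params = list(as.integer(frame)))
  if (nrow(excl) > 0 && excl$excluded[1] == 1)
    stop("cannot annotate a division on an excluded frame")
  if (nrow(maskA) == 0 || nrow(maskB) == 0)
    stop("daughter masks must be nonempty")
  if (!masks_disjoint(maskA, maskB))
    stop("daughter masks overlap")
  DBI::dbExecute(prj$db,
    "UPDATE cell SET fate = 'divided', end_frame = ? WHERE name = ?",
    params = list(as.integer(frame) - 1L, parent))
  for (d in c("A", "B")) {
    dn <- paste0(parent, d)
    DBI::dbExecute(prj$db,
      "INSERT INTO cell (name, parent, birth_frame) VALUES (?, ?, ?)",
      params = list(dn, parent, as.integer(frame)))
  }
  save_roi(prj, paste0(parent, "A"), frame, maskA, "manual")
  save_roi(prj, paste0(parent, "B"), frame, maskB, "manual")
  log_event(prj, "division", frame, list(parent = parent))
  invisible(c(paste0(parent, "A"), paste0(parent, "B")))
}

#' Set a cell's state from a frame onward
#'
#' `ignored` cells are dropped from processing entirely; `dead` cells keep
#' their last mask for display but are likewise skipped by segmentation and
#' excluded from measurement aggregates; `active` reverses an earlier mark.
#' Free-form annotations go through [record_cell_property()].
#'
#' @param prj a `bt_project`
#' @param cell cell name
#' @param frame 0-based frame from which the state applies
#' @param state `"ignored"`, `"dead"` or `"active"`
#' @export
set_cell_state <- function(prj, cell, frame, state) {
  if (!state %in% c("ignored", "dead", "active"))
    stop("unknown state label '", state,
         "' (use ignored / dead / active, or record_cell_property)")
  cl <- get_cell(prj, cell)
  if (frame < cl$birth_frame) stop("state frame precedes the cell's birth")
  DBI::dbExecute(prj$db,
    "INSERT OR REPLACE INTO cell_state (cell, from_frame, state)
     VALUES (?, ?, ?)", params = list(cell, as.integer(frame), state))
  if (state %in% c("ignored", "dead")) {
    DBI::dbExecute(prj$db,
      "UPDATE cell SET fate = ?, end_frame = ? WHERE name = ?
         AND fate = 'censored'",
      params = list(state, as.integer(frame) - 1L, cell))
  }
  log_event(prj, "state", frame, list(cell = cell, state = state))
  invisible(NULL)
}

#' Attach a free-form property to a cell from a frame onward
#'
#' @param prj a `bt_project`
#' @param cell cell name
#' @param frame 0-based frame
#' @param property arbitrary label, e.g. `"exits-field"`
#' @export
record_cell_property <- function(prj, cell, frame, property) {
  get_cell(prj, cell)
  log_event(prj, "property", frame,
            list(cell = cell, property = property))
  invisible(NULL)
}

#' Properties recorded for a cell
#' @inheritParams record_cell_property
#' @return data.frame with `frame` and `property`
#' @export
cell_properties <- function(prj, cell) {
  ev <- DBI::dbGetQuery(prj$db,
    "SELECT frame, payload FROM event WHERE type = 'property'")
  if (nrow(ev) == 0) return(data.frame(frame = integer(0),
                                       property = character(0)))
  pl <- lapply(ev$payload, jsonlite::fromJSON)
  keep <- vapply(pl, function(x) identical(x$cell, cell), logical(1))
  data.frame(frame = ev$frame[keep],
             property = vapply(pl[keep], `[[`, character(1), "property"))
}

# Effective state of a cell at a frame: the state row with the largest
# from_frame <= frame, defaulting to "active".
cell_state_at <- function(prj, cell, frame) {
  row <- DBI::dbGetQuery(prj$db,
    "SELECT state FROM cell_state WHERE cell = ? AND from_frame <= ?
     ORDER BY from_frame DESC LIMIT 1",
    params = list(cell, as.integer(frame)))
  if (nrow(row) == 0) "active" else row$state[1]
}

#' Cells alive and trackable at a frame
#'
#' A cell is active at frame `f` when it has been born (`birth_frame <= f`),
#' has not ended (`end_frame` open or `>= f`), and is not marked ignored or
#' dead at `f`.
#'
#' @param prj a `bt_project`
#' @param frame 0-based frame index
#' @return character vector of cell names, alphabetical
#' @export
active_cells <- function(prj, frame) {
  cand <- DBI::dbGetQuery(prj$db,
    "SELECT name FROM cell WHERE birth_frame <= ?1
       AND (end_frame IS NULL OR end_frame >= ?1) ORDER BY name",
    params = list(as.integer(frame)))$name
  cand[vapply(cand, function(nm)
    cell_state_at(prj, nm, frame) == "active", logical(1))]
}

#' Interdivision time of a divided cell
#'
#' Defined as `time(end_frame + 1) - time(birth_frame)`: the time from the
#' cell's first frame to its daughters' first frame.  Undefined for cells
#' that never divided (dead, ignored or still-censored cells).  Initial
#' cells already present at the start of the movie are flagged
#' left-censored, since their true birth was not observed.
#'
#' @param prj a `bt_project`
#' @param cell cell name
#' @return time in minutes, with attribute `"censored"` set to `TRUE` for
#'   left-censored initial cells
#' @export
interdivision_time <- function(prj, cell) {
  cl <- get_cell(prj, cell)
  if (cl$fate != "divided")
    stop("not-defined: cell '", cell, "' has no recorded division (fate ",
         cl$fate, ")")
  tms <- DBI::dbGetQuery(prj$db,
    "SELECT frame_index, time_min FROM frame WHERE frame_index IN (?, ?)",
    params = list(cl$birth_frame, cl$end_frame + 1L))
  if (nrow(tms) < 2) stop("frame times missing for cell '", cell, "'")
  t0 <- tms$time_min[match(cl$birth_frame, tms$frame_index)]
  t1 <- tms$time_min[match(cl$end_frame + 1L, tms$frame_index)]
  structure(t1 - t0,
            censored = is.na(cl$parent) && cl$birth_frame == 0L)
}

#' The lineage table
#' @param prj a `bt_project`
#' @return data.frame of all cell records (name, parent, birth_frame,
#'   end_frame, fate), alphabetical
#' @export
lineage_table <- function(prj) {
  DBI::dbGetQuery(prj$db, "SELECT * FROM cell ORDER BY name")
}
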