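#' @title The project datastore
#'
#' @description All project state — frame metadata, registration shifts,
#'   cells, regions of interest, division and annotation events, and
#'   measurements — lives in one SQLite file.  Copying that file (plus the
#'   image folders) to another machine moves the whole analysis.  Masks are
#'   stored as row-wise run-length-encoded text; measurements are stored in
#'   long format (`variable`, `value`) so new derived variables need no
#'   schema change.
#'
#' @name datastore
NULL

DB_SCHEMA_VERSION <- "1"

db_tables <- c("project", "channel", "frame", "cell", "cell_state", "roi",
               "background_roi", "background_mean", "measurement", "event")

#' Create or open a project database
#'
#' Creates the schema on an empty path; on an existing valid project file it
#' is a no-op.  A file that is not a project database (corrupted, or some
#' other SQLite schema) raises an error and is never overwritten.
#'
#' @param path file path for the SQLite database
#' @return an open DBI connection with foreign keys enforced
#' @export
init_db <- function(path) {
  existed <- file.exists(path) && file.size(path) > 0
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  if (existed) {
    tabs <- tryCatch(DBI::dbListTables(con), error = function(e) NULL)
    if (is.null(tabs) || !("project" %in% tabs)) {
      DBI::dbDisconnect(con)
      stop("'", path, "' exists but is not a valid project database; ",
           "refusing to overwrite")
    }
    ver <- DBI::dbGetQuery(con,
      "SELECT value FROM project WHERE key = 'schema_version'")$value
    if (!identical(ver, DB_SCHEMA_VERSION)) {
      DBI::dbDisconnect(con)
      stop("schema version mismatch: file has ", ver, ", expected ",
           DB_SCHEMA_VERSION)
    }
    return(con)
  }
  for (sql in c(
    "CREATE TABLE project (key TEXT PRIMARY KEY, value TEXT)",
    "CREATE TABLE channel (name TEXT PRIMARY KEY, directory TEXT)",
    "CREATE TABLE frame (
       frame_index INTEGER PRIMARY KEY,
       time_min REAL NOT NULL,
       excluded INTEGER NOT NULL DEFAULT 0,
       note TEXT,
       shift_dy INTEGER NOT NULL DEFAULT 0,
       shift_dx INTEGER NOT NULL DEFAULT 0)",
    "CREATE TABLE cell (
       name TEXT PRIMARY KEY,
       parent TEXT REFERENCES cell(name) ON DELETE CASCADE,
       birth_frame INTEGER NOT NULL,
       end_frame INTEGER,
       fate TEXT NOT NULL DEFAULT 'censored'
         CHECK (fate IN ('divided', 'dead', 'ignored', 'censored')))",
    "CREATE TABLE cell_state (
       cell TEXT NOT NULL REFERENCES cell(name) ON DELETE CASCADE,
       from_frame INTEGER NOT NULL,
       state TEXT NOT NULL,
       PRIMARY KEY (cell, from_frame))",
    "CREATE TABLE roi (
       cell TEXT NOT NULL REFERENCES cell(name) ON DELETE CASCADE,
       frame INTEGER NOT NULL REFERENCES frame(frame_index),
       rle_mask TEXT NOT NULL,
       provenance TEXT NOT NULL CHECK (provenance IN ('auto', 'manual')),
       PRIMARY KEY (cell, frame))",
    "CREATE TABLE background_roi (
       id INTEGER PRIMARY KEY CHECK (id = 1),
       rle_mask TEXT NOT NULL)",
    "CREATE TABLE measurement (
       cell TEXT NOT NULL,
       frame INTEGER NOT NULL,
       channel TEXT NOT NULL,
       variable TEXT NOT NULL,
       value REAL,
       PRIMARY KEY (cell, frame, channel, variable),
       FOREIGN KEY (cell, frame) REFERENCES roi(cell, frame)
         ON DELETE CASCADE)",
    "CREATE TABLE background_mean (
       frame INTEGER NOT NULL REFERENCES frame(frame_index),
       channel TEXT NOT NULL,
       value REAL NOT NULL,
       PRIMARY KEY (frame, channel))",
    "CREATE TABLE event (
       id INTEGER PRIMARY KEY AUTOINCREMENT,
       type TEXT NOT NULL,
       frame INTEGER,
       payload TEXT)"))
    DBI::dbExecute(con, sql)
  DBI::dbExecute(con,
    "INSERT INTO project (key, value) VALUES ('schema_version', ?)",
    params = list(DB_SCHEMA_VERSION))
  con
}

#' Open a project
#'
#' A project bundles the datastore connection, the pixel size, and the
#' loaded channel stacks.  It is an environment, so the stacks added with
#' [project_add_channel()] travel with it by reference.
#'
#' @param db_path path of the SQLite datastore (created if missing)
#' @param pixel_size_um microns per pixel, stored in the project table
#' @return an environment of class `bt_project`
#' @export
project_open <- function(db_path, pixel_size_um = NULL) {
  prj <- new.env(parent = emptyenv())
  prj$db <- init_db(db_path)
  prj$path <- db_path
  prj$stacks <- list()
  if (!is.null(pixel_size_um)) {
    DBI::dbExecute(prj$db, "INSERT OR REPLACE INTO project VALUES
      ('pixel_size_um', ?)", params = list(as.character(pixel_size_um)))
  }
  class(prj) <- "bt_project"
  prj
}

#' @export
print.bt_project <- function(x, ...) {
  ncell <- DBI::dbGetQuery(x$db, "SELECT count(*) n FROM cell")$n
  nroi <- DBI::dbGetQuery(x$db, "SELECT count(*) n FROM roi")$n
  cat(sprintf("<bt_project '%s': channels [%s], %d cells, %d ROIs>\n",
              x$path, paste(names(x$stacks), collapse = ", "), ncell, nroi))
  invisible(x)
}

#' Close a project's database connection
#' @param prj a `bt_project`
#' @export
project_close <- function(prj) DBI::dbDisconnect(prj$db)

project_pixel_size <- function(prj) {
  ps <- DBI::dbGetQuery(prj$db,
    "SELECT value FROM project WHERE key = 'pixel_size_um'")$value
  if (length(ps)) as.numeric(ps)
  else if (length(prj$stacks)) prj$stacks[[1]]$pixel_size_um
  else 1
}

#' Attach a channel stack to a project
#'
#' Registers the channel and syncs the frame table (times, exclusions,
#' notes) from the stack.  All channels of one project must agree on frame
#' count and image dimensions.
#'
#' @param prj a `bt_project`
#' @param stack a `frame_stack`
#' @param directory optional source directory recorded in the channel table
#' @return the project, invisibly
#' @export
project_add_channel <- function(prj, stack, directory = NA_character_) {
  if (length(prj$stacks)) {
    ref <- prj$stacks[[1]]
    if (n_frames(ref) != n_frames(stack) ||
        !all(dim(ref$images[[1]]) == dim(stack$images[[1]])))
      stop("channel '", stack$channel,
           "' does not match the project's frame count or dimensions")
  }
  prj$stacks[[stack$channel]] <- stack
  DBI::dbExecute(prj$db,
    "INSERT OR REPLACE INTO channel VALUES (?, ?)",
    params = list(stack$channel, directory))
  old <- DBI::dbGetQuery(prj$db,
    "SELECT frame_index, shift_dy, shift_dx FROM frame")
  for (i in seq_len(n_frames(stack))) {
    j <- match(i - 1L, old$frame_index)
    DBI::dbExecute(prj$db,
      "INSERT OR REPLACE INTO frame
         (frame_index, time_min, excluded, note, shift_dy, shift_dx)
       VALUES (?, ?, ?, ?, ?, ?)",
      params = list(i - 1L, stack$time_min[i], as.integer(stack$excluded[i]),
                    stack$note[i],
                    if (is.na(j)) 0L else old$shift_dy[j],
                    if (is.na(j)) 0L else old$shift_dx[j]))
  }
  invisible(prj)
}

#' Register all channels of a project and log the shifts
#'
#' Runs [register_sequence()] on the project's stacks, replaces them with
#' the registered versions, and records the per-frame cumulative shifts in
#' the frame table.
#'
#' @param prj a `bt_project`
#' @inheritParams register_sequence
#' @return the shift matrix, invisibly
#' @export
project_register <- function(prj, max_shift = 5L,
                             reference_channel = "phase", ncc_floor = 0.2) {
  reg <- register_sequence(prj$stacks, max_shift, reference_channel,
                           ncc_floor)
  prj$stacks <- reg$stacks
  for (k in seq_len(nrow(reg$shifts)))
    DBI::dbExecute(prj$db,
      "UPDATE frame SET shift_dy = ?, shift_dx = ? WHERE frame_index = ?",
      params = list(reg$shifts[k, 1], reg$shifts[k, 2], k - 1L))
  for (w in reg$warnings) log_event(prj, "registration-warning", NA, w)
  log_event(prj, "register", NA,
            list(max_shift = max_shift, channel = reference_channel))
  invisible(reg$shifts)
}

#' Record an event in the project log
#'
#' @param prj a `bt_project`
#' @param type short event type label
#' @param frame frame index the event refers to, or `NA`
#' @param payload character string or list (serialized to JSON)
#' @export
log_event <- function(prj, type, frame = NA, payload = NULL) {
  if (is.list(payload))
    payload <- jsonlite::toJSON(payload, auto_unbox = TRUE)
  DBI::dbExecute(prj$db, "INSERT INTO event (type, frame, payload)
    VALUES (?, ?, ?)",
    params = list(type, as.integer(frame), as.character(payload %||% NA)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a cell's region of interest
#'
#' Each save is one autocommitted statement, so masks written during a long
#' segmentation run are durable even if the process dies.  Overwriting an
#' existing ROI drops any measurements stored for it (they describe the
#' old pixel set and must be re-measured).
#'
#' @param prj a `bt_project`
#' @param cell cell name
#' @param frame 0-based frame index
#' @param mask a [pixel_mask()]
#' @param provenance `"auto"` (algorithm) or `"manual"` (user supplied)
#' @export
save_roi <- function(prj, cell, frame, mask, provenance = c("auto",
                                                            "manual")) {
  provenance <- match.arg(provenance)
  DBI::dbExecute(prj$db,
    "INSERT OR REPLACE INTO roi (cell, frame, rle_mask, provenance)
     VALUES (?, ?, ?, ?)",
    params = list(cell, as.integer(frame), mask_to_rle(mask), provenance))
  invisible(NULL)
}

#' Load a cell's region of interest
#'
#' @inheritParams save_roi
#' @return a [pixel_mask()] with attribute `"provenance"`
#' @export
load_roi <- function(prj, cell, frame) {
  row <- DBI::dbGetQuery(prj$db,
    "SELECT rle_mask, provenance FROM roi WHERE cell = ? AND frame = ?",
    params = list(cell, as.integer(frame)))
  if (nrow(row) == 0)
    stop("not-found: no ROI for cell ", cell, " at frame ", frame)
  m <- mask_from_rle(row$rle_mask[1], frame_index = frame)
  attr(m, "provenance") <- row$provenance[1]
  m
}

#' Define the background region
#'
#' One frame-independent pixel region assumed to contain no cells; its
#' per-frame, per-channel mean intensity is subtracted from cell means to
#' form the background-corrected variables.
#'
#' @param prj a `bt_project`
#' @param mask a [pixel_mask()]
#' @export
set_background_roi <- function(prj, mask) {
  DBI::dbExecute(prj$db,
    "INSERT OR REPLACE INTO background_roi (id, rle_mask) VALUES (1, ?)",
    params = list(mask_to_rle(mask)))
  invisible(NULL)
}

#' @rdname set_background_roi
#' @return `get_background_roi`: the stored [pixel_mask()], or `NULL`
#' @export
get_background_roi <- function(prj) {
  row <- DBI::dbGetQuery(prj$db, "SELECT rle_mask FROM background_roi")
  if (nrow(row) == 0) return(NULL)
  mask_from_rle(row$rle_mask[1])
}

#' Run a read-only SQL query
#'
#' The editor-style entry point for querying the datastore.  Only a single
#' `SELECT` (or `WITH ... SELECT`) statement is accepted; write statements
#' are rejected.
#'
#' @param prj a `bt_project`
#' @param query SQL text
#' @return a data.frame of the result rows
#' @export
run_sql <- function(prj, query) {
  lines <- strsplit(query, "\n", fixed = TRUE)[[1]]
  q <- trimws(paste(lines[!startsWith(trimws(lines), "--")],
                    collapse = "\n"))
  if (!grepl("^(select|with)\\b", tolower(q)))
    stop("only read-only SELECT queries are allowed here")
  if (grepl(";.*\\S", sub("^[^;]*", "", q)))
    stop("only a single statement is allowed")
  DBI::dbGetQuery(prj$db, q)
}

#' The shipped green-to-red ratio query
#'
#' Returns the SQL computing, per frame, the across-cell mean and standard
#' deviation of the background-corrected green-to-red fluorescence ratio
#' (numerator channel / denominator channel, cells with non-positive
#' denominator excluded), the query behind the induction time-course plot.
#'
#' @param num,den numerator and denominator channel names
#' @return SQL text suitable for [run_sql()]
#' @export
ratio_query <- function(num = "ch1", den = "ch2") {
  path <- system.file("sql", "ratio_timecourse.sql", package = "bactrack")
  sql <- paste(readLines(path), collapse = "\n")
  sql <- gsub(":num", paste0("'", num, "'"), sql, fixed = TRUE)
  gsub(":den", paste0("'", den, "'"), sql, fixed = TRUE)
}

#' Export a query result or table as CSV
#'
#' Writes RFC 4180 CSV with a header row; numeric columns are serialized
#' with round-trip (17 significant digit) precision.
#'
#' @param prj a `bt_project`
#' @param selection a table name, a SELECT query, or a data.frame
#' @param path output file
#' @return invisibly, the number of data rows written
#' @export
export_csv <- function(prj, selection, path) {
  df <- if (is.data.frame(selection)) selection
  else if (selection %in% DBI::dbListTables(prj$db))
    DBI::dbGetQuery(prj$db, paste0("SELECT * FROM ", selection))
  else run_sql(prj, selection)
  esc <- function(x) {
    x[is.na(x)] <- ""
    needs <- grepl('[",\n\r]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  cols <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- NA
      out
    } else as.character(col)
  })
  lines <- c(paste(esc(names(df)), collapse = ","),
             if (nrow(df)) do.call(paste,
               c(lapply(cols, esc), list(sep = ","))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\r\n")
  invisible(nrow(df))
}
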