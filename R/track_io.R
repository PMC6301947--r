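#' Read cell tracks from a delimited file
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`csv`}{The canonical schema: comma-separated with header
#'     `cell_id,frame,t_min,x_um,y_um`. Coordinates are micrometres unless
#'     the file actually holds pixel units, in which case supply
#'     `pixel_size_um` and they are rescaled.}
#'   \item{`mtrackj_points`}{A whitespace-delimited point export with
#'     columns track-id, point-id, x (pixel), y (pixel), frame. Non-numeric
#'     lines (headers, comments) are skipped. Frames are re-based to zero
#'     and times derived from `frame_interval_min`; coordinates are
#'     multiplied by `pixel_size_um`.}
#' }
#'
#' Cells with fewer than 2 points carry no displacement information and are
#' dropped with a warning reporting the count. Projected 2-D tracks
#' systematically underestimate true 3-D path lengths and speeds; no
#' correction is attempted.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"mtrackj_points"`.
#' @param pixel_size_um Micrometres per pixel applied to coordinates
#'   (default 1, i.e. coordinates already in micrometres). Must be > 0.
#' @param frame_interval_min Sampling interval in minutes (default 11).
#' @param label A [condition_label()] to attach.
#' @return A validated [track_set()].
#' @export
read_tracks <- function(path, dialect = c("csv", "mtrackj_points"),
                        pixel_size_um = 1, frame_interval_min = 11,
                        label = condition_label()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0", call. = FALSE)
  }
  if (!is.numeric(frame_interval_min) || frame_interval_min <= 0) {
    stop("frame_interval_min must be > 0", call. = FALSE)
  }
  pts <- switch(dialect,
    csv = .read_csv_dialect(path),
    mtrackj_points = .read_mtrackj_points(path, frame_interval_min)
  )
  pts$x_um <- pts$x_um * pixel_size_um
  pts$y_um <- pts$y_um * pixel_size_um

  counts <- table(pts$cell_id)
  short <- names(counts)[counts < 2]
  if (length(short) > 0) {
    warning(sprintf("dropped %d track(s) with fewer than 2 points: %s",
                    length(short), paste(short, collapse = ", ")),
            call. = FALSE)
    pts <- pts[!(pts$cell_id %in% short), , drop = FALSE]
  }
  .check_monotone_file_frames(pts)
  track_set(pts, frame_interval_min = frame_interval_min, label = label,
            pixel_size_um = pixel_size_um)
}

.read_csv_dialect <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "frame", "t_min", "x_um", "y_um")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("format error: missing required column(s) ",
         paste(sprintf("'%s'", missing_cols), collapse = ", "),
         call. = FALSE)
  }
  raw[required]
}

.read_mtrackj_points <- function(path, frame_interval_min) {
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) < 5) return(NULL)
    num <- suppressWarnings(as.numeric(tok[1:5]))
    if (anyNA(num)) return(NULL)
    num
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(cell_id = character(0), frame = integer(0),
                      t_min = numeric(0), x_um = numeric(0),
                      y_um = numeric(0)))
  }
  m <- do.call(rbind, rows)
  frame <- as.integer(m[, 5]) - min(as.integer(m[, 5]))
  data.frame(
    cell_id = sprintf("track_%d", as.integer(m[, 1])),
    frame = frame,
    t_min = frame * frame_interval_min,
    x_um = m[, 3],
    y_um = m[, 4]
  )
}

# The file itself must list each cell's frames in increasing order *after*
# sorting by frame (duplicates aside); a frame appearing twice is the one
# non-monotone state the sorted representation can still carry.
.check_monotone_file_frames <- function(pts) {
  for (id in unique(pts$cell_id)) {
    fr <- pts$frame[pts$cell_id == id]
    if (anyDuplicated(fr)) {
      stop("non-monotone frames within cell '", id, "'", call. = FALSE)
    }
  }
  invisible(pts)
}

#' Write cell tracks to the canonical CSV schema
#'
#' Writes `cell_id,frame,t_min,x_um,y_um` with coordinates at 6 decimal
#' places, so a write/read round trip reproduces frames exactly and
#' coordinates to 1e-6 um. An empty track set yields a header-only file.
#'
#' @param tracks A [track_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  .assert_track_set(tracks)
  out <- data.frame(
    cell_id = tracks$cell_id,
    frame = tracks$frame,
    t_min = tracks$t_min,
    x_um = sprintf("%.6f", tracks$x_um),
    y_um = sprintf("%.6f", tracks$y_um),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("could not write tracks to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}
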