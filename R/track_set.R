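#' Condition label for a set of tracks
#'
#' Describes the biological condition a set of tracks was recorded under:
#' which tumor it came from, the tumor-level receptor amplification status,
#' and whether the slice was drug treated.
#'
#' @param tumor_id Character identifier of the tumor/slice.
#' @param amplification One of `"amplified"`, `"non_amplified"`, `"unknown"`.
#' @param treatment One of `"control"`, `"drug"`.
#' @return A named list of class `condition_label`.
#' @export
condition_label <- function(tumor_id = "unknown",
                            amplification = c("unknown", "amplified", "non_amplified"),
                            treatment = c("control", "drug")) {
  amplification <- match.arg(amplification)
  treatment <- match.arg(treatment)
  structure(list(tumor_id = as.character(tumor_id),
                 amplification = amplification,
                 treatment = treatment),
            class = "condition_label")
}

#' Construct a validated set of cell tracks
#'
#' A `track_set` is a tibble of time-ordered 2-D centroid positions (one row
#' per cell per frame) carrying the shared sampling interval and condition
#' label as attributes. Positions are in micrometres, time in minutes.
#'
#' Validation enforces the assumptions every downstream metric relies on:
#' uniform sampling (`t_min = frame * frame_interval_min`), strictly
#' increasing frames with no duplicates and no gaps (missing frames are
#' rejected, not interpolated, because interpolation would silently alter
#' instantaneous speeds), finite coordinates, and at least two points per
#' cell (one displacement step).
#'
#' @param points Data frame with columns `cell_id`, `frame`, `t_min`,
#'   `x_um`, `y_um`.
#' @param frame_interval_min Sampling interval in minutes (default 11).
#' @param label A [condition_label()].
#' @param pixel_size_um Pixel size used at conversion, if known (metadata
#'   only; coordinates must already be in micrometres).
#' @return A tibble of class `track_set`, rows sorted by `cell_id`, `frame`.
#' @export
track_set <- function(points, frame_interval_min = 11,
                      label = condition_label(), pixel_size_um = NA_real_) {
  required <- c("cell_id", "frame", "t_min", "x_um", "y_um")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(frame_interval_min) || frame_interval_min <= 0) {
    stop("frame_interval_min must be a positive number", call. = FALSE)
  }
  pts <- tibble::tibble(
    cell_id = as.character(points$cell_id),
    frame = as.integer(points$frame),
    t_min = as.numeric(points$t_min),
    x_um = as.numeric(points$x_um),
    y_um = as.numeric(points$y_um)
  )
  pts <- pts[order(pts$cell_id, pts$frame), , drop = FALSE]
  if (nrow(pts) > 0) {
    if (!all(is.finite(pts$x_um)) || !all(is.finite(pts$y_um))) {
      stop("non-finite coordinates in track table", call. = FALSE)
    }
    if (any(pts$frame < 0)) stop("negative frame index", call. = FALSE)
    for (id in unique(pts$cell_id)) {
      idx <- which(pts$cell_id == id)
      fr <- pts$frame[idx]
      if (length(fr) < 2) {
        stop("track '", id, "' has fewer than 2 points", call. = FALSE)
      }
      if (anyDuplicated(fr)) {
        stop("duplicate or non-monotone frames for cell '", id, "'",
             call. = FALSE)
      }
      if (any(diff(fr) != 1L)) {
        stop("missing frames within track '", id,
             "' (gaps are rejected, not interpolated)", call. = FALSE)
      }
      if (any(abs(pts$t_min[idx] - fr * frame_interval_min) > 1e-6)) {
        stop("t_min inconsistent with frame * frame_interval_min for cell '",
             id, "'", call. = FALSE)
      }
    }
  }
  structure(pts,
            class = c("track_set", class(pts)),
            frame_interval_min = as.numeric(frame_interval_min),
            label = label,
            pixel_size_um = as.numeric(pixel_size_um))
}

#' @export
print.track_set <- function(x, ...) {
  lab <- track_label(x)
  n <- n_tracks(x)
  cat(sprintf("<track_set> %d track(s), %.0f-min interval [%s / %s / %s]\n",
              n, frame_interval(x), lab$tumor_id, lab$amplification,
              lab$treatment))
  NextMethod()
  invisible(x)
}

#' Number of tracks in a track set
#' @param tracks A `track_set`.
#' @return Integer count of distinct cells.
#' @export
n_tracks <- function(tracks) length(unique(tracks$cell_id))

#' Sampling interval of a track set, in minutes
#' @param tracks A `track_set`.
#' @return Numeric scalar (minutes).
#' @export
frame_interval <- function(tracks) attr(tracks, "frame_interval_min")

#' Condition label of a track set
#' @param tracks A `track_set`.
#' @return The [condition_label()] attached at construction.
#' @export
track_label <- function(tracks) attr(tracks, "label")

.assert_track_set <- function(tracks) {
  if (!inherits(tracks, "track_set")) {
    stop("expected a track_set (see track_set() / read_tracks())",
         call. = FALSE)
  }
  invisible(tracks)
}
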