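#' Detect movement peaks (migration bursts) in speed series
#'
#' A movement peak is a maximal run of at least two consecutive steps whose
#' instantaneous speed is strictly greater than `threshold` (default 0
#' um/hr). Isolated single supra-threshold steps are not peaks. The
#' default threshold keeps the strict "above 0 um/hr" rule; a small jitter
#' floor (`threshold > 0`) can be supplied for noisy centroid data where
#' speeds are never exactly zero.
#'
#' The distance traveled within a peak is the area under the speed curve,
#' computed rectangularly (speed x step duration per step), which is
#' identically the sum of the Euclidean step lengths inside the peak.
#'
#' @param series A speed series from [speed_series()] (one or many cells).
#' @param threshold Detection threshold in um/hr, `>= 0`.
#' @return A tibble with one row per peak: `cell_id`, `start_step`,
#'   `end_step` (inclusive step indices), `duration_hr`, `max_speed`
#'   (um/hr) and `distance_um`, ordered by cell then start index.
#' @export
detect_peaks <- function(series, threshold = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("threshold must be a single number >= 0", call. = FALSE)
  }
  dt_hr <- attr(series, "dt_hr")
  if (is.null(dt_hr)) stop("series lacks a dt_hr attribute; use speed_series()",
                           call. = FALSE)
  idx <- split(seq_len(nrow(series)), series$cell_id)
  parts <- lapply(names(idx), function(id) {
    i <- idx[[id]]
    runs <- .supra_runs(series$speed_um_hr[i], threshold)
    if (nrow(runs) == 0) return(NULL)
    data.frame(
      cell_id = id,
      start_step = series$step[i][runs[, 1]],
      end_step = series$step[i][runs[, 2]],
      duration_hr = (runs[, 2] - runs[, 1] + 1) * dt_hr,
      max_speed = vapply(seq_len(nrow(runs)), function(k)
        max(series$speed_um_hr[i][runs[k, 1]:runs[k, 2]]), numeric(1)),
      distance_um = vapply(seq_len(nrow(runs)), function(k)
        sum(series$step_um[i][runs[k, 1]:runs[k, 2]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) {
    return(tibble::tibble(cell_id = character(0), start_step = integer(0),
                          end_step = integer(0), duration_hr = numeric(0),
                          max_speed = numeric(0), distance_um = numeric(0)))
  }
  tibble::as_tibble(do.call(rbind, parts))
}

# Maximal runs of speeds strictly above `thr`, length >= 2, as a two-column
# matrix of local (1-based) start/end indices.
.supra_runs <- function(sp, thr) {
  above <- sp > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  cbind(starts[keep], ends[keep])
}

#' Filter movement peaks by amplitude
#'
#' High-speed peaks are movement peaks whose maximum instantaneous speed is
#' strictly greater than `threshold` (default 20 um/hr), the marker of
#' fast bursting cells.
#'
#' @param peaks A peak table from [detect_peaks()].
#' @param threshold Amplitude threshold in um/hr.
#' @return The subset of `peaks` with `max_speed > threshold`, order kept.
#' @export
high_speed_peaks <- function(peaks, threshold = 20) {
  peaks[peaks$max_speed > threshold, , drop = FALSE]
}

#' Per-cell burst metrics
#'
#' Aggregates movement-peak detection per cell: peak counts, peak rates per
#' hour of imaging (rates are normalized by total imaging duration,
#' `n_steps x dt`), the count and rate of high-speed peaks, and the mean
#' distance traveled per movement (mean per-peak area under the speed
#' curve; 0 for cells with no peaks).
#'
#' @param tracks A [track_set()].
#' @param high_speed_threshold Amplitude threshold in um/hr (default 20).
#' @param peak_epsilon Detection threshold in um/hr (default 0).
#' @return A tibble, one row per cell: `cell_id`, `n_peaks`, `peaks_per_hr`,
#'   `n_high_speed_peaks`, `high_speed_peaks_per_hr`,
#'   `mean_distance_per_movement_um`, `duration_hr`.
#' @export
burst_metrics <- function(tracks, high_speed_threshold = 20,
                          peak_epsilon = 0) {
  .assert_track_set(tracks)
  ser <- speed_series(tracks)
  dt_hr <- attr(ser, "dt_hr")
  peaks <- detect_peaks(ser, threshold = peak_epsilon)
  ids <- sort(unique(tracks$cell_id))
  n_steps <- vapply(split(ser$step, ser$cell_id)[ids], length, integer(1))
  duration_hr <- n_steps * dt_hr
  n_peaks <- integer(length(ids))
  n_high <- integer(length(ids))
  mean_dist <- numeric(length(ids))
  if (nrow(peaks) > 0) {
    by_cell <- split(seq_len(nrow(peaks)), peaks$cell_id)
    for (id in names(by_cell)) {
      j <- match(id, ids)
      rows <- by_cell[[id]]
      n_peaks[j] <- length(rows)
      n_high[j] <- sum(peaks$max_speed[rows] > high_speed_threshold)
      mean_dist[j] <- mean(peaks$distance_um[rows])
    }
  }
  tibble::tibble(
    cell_id = ids,
    n_peaks = n_peaks,
    peaks_per_hr = unname(n_peaks / duration_hr),
    n_high_speed_peaks = n_high,
    high_speed_peaks_per_hr = unname(n_high / duration_hr),
    mean_distance_per_movement_um = mean_dist,
    duration_hr = unname(duration_hr)
  )
}

#' Population speed topography
#'
#' The cells-by-time matrix of instantaneous speed underlying 3-D surface
#' topography maps: one row per cell, one column per step, rows ordered by
#' increasing per-cell standard deviation of instantaneous speed (ties
#' broken lexicographically by `cell_id` for reproducibility). Shorter
#' tracks are padded with `NA`, which every summary here excludes.
#'
#' @param tracks A [track_set()].
#' @return An object of class `topography_matrix`: a list with `speed`
#'   (matrix, um/hr, rownames = cell ids in row order), `cell_id`, `sd`
#'   (row-wise sd of instantaneous speed, non-decreasing) and `time_hr`
#'   (step midpoint times in hours).
#' @export
topography <- function(tracks) {
  .assert_track_set(tracks)
  if (nrow(tracks) == 0) stop("empty track set", call. = FALSE)
  ser <- speed_series(tracks)
  dt_hr <- attr(ser, "dt_hr")
  sp <- split(ser$speed_um_hr, ser$cell_id)
  n_max <- max(vapply(sp, length, integer(1)))
  mat <- t(vapply(sp, function(v) c(v, rep(NA_real_, n_max - length(v))),
                  numeric(n_max)))
  sds <- apply(mat, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) stats::sd(v) else 0
  })
  ord <- order(sds, rownames(mat))
  structure(list(speed = mat[ord, , drop = FALSE],
                 cell_id = rownames(mat)[ord],
                 sd = sds[ord],
                 time_hr = (seq_len(n_max) - 0.5) * dt_hr),
            class = "topography_matrix")
}

#' @export
print.topography_matrix <- function(x, ...) {
  cat(sprintf("<topography_matrix> %d cells x %d steps, sd range [%.2f, %.2f] um/hr\n",
              nrow(x$speed), ncol(x$speed), min(x$sd), max(x$sd)))
  invisible(x)
}
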