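#' Instantaneous speed series for every cell
#'
#' The instantaneous speed of a step is the Euclidean distance between
#' consecutive centroid positions divided by the sampling interval,
#' reported in micrometres per hour. A track of `n` points yields `n - 1`
#' steps.
#'
#' @param tracks A [track_set()].
#' @return A tibble with columns `cell_id`, `step` (1-based step index),
#'   `step_um` (step length) and `speed_um_hr`, carrying the step duration
#'   in hours as attribute `dt_hr`.
#' @export
speed_series <- function(tracks) {
  .assert_track_set(tracks)
  dt_hr <- frame_interval(tracks) / 60
  idx <- split(seq_len(nrow(tracks)), tracks$cell_id)
  parts <- lapply(names(idx), function(id) {
    i <- idx[[id]]
    d <- sqrt(diff(tracks$x_um[i])^2 + diff(tracks$y_um[i])^2)
    data.frame(cell_id = id, step = seq_along(d), step_um = d,
               speed_um_hr = d / dt_hr, stringsAsFactors = FALSE)
  })
  out <- tibble::as_tibble(do.call(rbind, parts))
  attr(out, "dt_hr") <- dt_hr
  out
}

#' Total and net path length per cell
#'
#' Total path length is the sum of Euclidean step lengths; net path length
#' is the displacement, i.e. the straight-line distance from the first to
#' the last recorded position.
#'
#' @param tracks A [track_set()].
#' @return A tibble with columns `cell_id`, `total_path_um`, `net_path_um`.
#' @export
path_lengths <- function(tracks) {
  .assert_track_set(tracks)
  idx <- split(seq_len(nrow(tracks)), tracks$cell_id)
  m <- vapply(idx, function(i) {
    x <- tracks$x_um[i]; y <- tracks$y_um[i]
    c(sum(sqrt(diff(x)^2 + diff(y)^2)),
      sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2))
  }, numeric(2))
  tibble::tibble(cell_id = names(idx),
                 total_path_um = unname(m[1, ]), net_path_um = unname(m[2, ]))
}

#' Per-cell migration metrics
#'
#' Computes, for every cell in the set:
#' \describe{
#'   \item{`total_path_um`, `net_path_um`}{path length and displacement.}
#'   \item{`directionality`}{net / total path, in \[0, 1\]; 1 for a straight
#'     path, 0 for a closed loop. A fully stationary cell (total path 0) is
#'     assigned 0 so it remains part of the population rather than NaN.}
#'   \item{`mean_speed`}{total path over elapsed time (um/hr); with uniform
#'     sampling this equals the arithmetic mean of the instantaneous
#'     speeds.}
#'   \item{`mean_effective_speed`}{mean speed x directionality, the speed at
#'     which the cell effectively traverses tissue.}
#'   \item{`sd_instantaneous_speed`}{sample (n-1) standard deviation of the
#'     instantaneous speed series, the per-cell surrogate of bursting
#'     intensity. A single-step track has no dispersion estimate and is
#'     reported as 0 with a warning.}
#'   \item{`n_steps`}{number of inter-frame steps.}
#' }
#'
#' @param tracks A [track_set()].
#' @return A tibble, one row per cell, ordered by `cell_id`.
#' @export
cell_metrics <- function(tracks) {
  .assert_track_set(tracks)
  dt_hr <- frame_interval(tracks) / 60
  idx <- split(seq_len(nrow(tracks)), tracks$cell_id)
  m <- vapply(idx, function(i) {
    x <- tracks$x_um[i]; y <- tracks$y_um[i]
    d <- sqrt(diff(x)^2 + diff(y)^2)
    total <- sum(d)
    net <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
    dir <- if (total > 0) net / total else 0
    elapsed_hr <- length(d) * dt_hr
    mean_speed <- total / elapsed_hr
    sd_speed <- if (length(d) >= 2) stats::sd(d / dt_hr) else NA_real_
    c(total, net, dir, mean_speed, mean_speed * dir, sd_speed, length(d))
  }, numeric(7))
  single_step <- is.na(m[6, ])
  if (any(single_step)) {
    warning(sprintf(
      "%d track(s) have a single step; sd_instantaneous_speed reported as 0",
      sum(single_step)), call. = FALSE)
    m[6, single_step] <- 0
  }
  n_stationary <- sum(m[1, ] == 0)
  if (n_stationary > 0) {
    message(sprintf("%d stationary cell(s) assigned directionality 0",
                    n_stationary))
  }
  tibble::tibble(
    cell_id = names(idx),
    total_path_um = unname(m[1, ]),
    net_path_um = unname(m[2, ]),
    directionality = unname(m[3, ]),
    mean_speed = unname(m[4, ]),
    mean_effective_speed = unname(m[5, ]),
    sd_instantaneous_speed = unname(m[6, ]),
    n_steps = as.integer(unname(m[7, ]))
  )
}
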