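# Fixture builders and independent oracles shared across test files.

# Build a track_set from a named list of n x 2 coordinate matrices (um).
make_tracks <- function(coords, frame_interval_min = 11) {
  pts <- do.call(rbind, lapply(names(coords), function(id) {
    m <- coords[[id]]
    data.frame(cell_id = id, frame = seq_len(nrow(m)) - 1L,
               t_min = (seq_len(nrow(m)) - 1L) * frame_interval_min,
               x_um = m[, 1], y_um = m[, 2], stringsAsFactors = FALSE)
  }))
  track_set(pts, frame_interval_min = frame_interval_min)
}

# A track realizing a given instantaneous-speed sequence (um/hr) by moving
# along +x; speed_to_track(c(0, 5, 7)) gives a 4-point track.
speed_to_track <- function(speeds, frame_interval_min = 11) {
  dt_hr <- frame_interval_min / 60
  make_tracks(list(c1 = cbind(c(0, cumsum(speeds * dt_hr)), 0)),
              frame_interval_min = frame_interval_min)
}

# Random free-diffusion-like tracks, independent of the package simulator.
random_tracks <- function(n_cells, n_frames = 31, step_sd = 2,
                          zero_prob = 0.3, frame_interval_min = 11) {
  coords <- lapply(seq_len(n_cells), function(i) {
    moving <- stats::runif(n_frames - 1) >= zero_prob
    dx <- stats::rnorm(n_frames - 1, 0, step_sd) * moving
    dy <- stats::rnorm(n_frames - 1, 0, step_sd) * moving
    cbind(c(0, cumsum(dx)), c(0, cumsum(dy)))
  })
  names(coords) <- sprintf("cell_%04d", seq_len(n_cells))
  make_tracks(coords, frame_interval_min = frame_interval_min)
}

# A speed series built directly (no position round trip), for tests that
# exercise strict threshold boundaries.
make_series <- function(speeds, frame_interval_min = 11, cell_id = "c1") {
  dt_hr <- frame_interval_min / 60
  out <- tibble::tibble(cell_id = cell_id, step = seq_along(speeds),
                        step_um = speeds * dt_hr, speed_um_hr = speeds)
  attr(out, "dt_hr") <- dt_hr
  out
}

# Brute-force movement-peak oracle: enumerate every window [i, j] and keep
# those that are supra-threshold throughout, at least 2 long, and maximal.
brute_force_peaks <- function(speeds, threshold = 0) {
  n <- length(speeds)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i + 1) next
      if (!all(speeds[i:j] > threshold)) next
      left_ok <- i == 1 || speeds[i - 1] <= threshold
      right_ok <- j == n || speeds[j + 1] <= threshold
      if (left_ok && right_ok) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Textbook two-group Levene W: one-way ANOVA F on |x - center| deviations.
levene_W_oracle <- function(g1, g2, center = mean) {
  z1 <- abs(g1 - center(g1)); z2 <- abs(g2 - center(g2))
  n1 <- length(z1); n2 <- length(z2); N <- n1 + n2
  zbar <- mean(c(z1, z2))
  between <- n1 * (mean(z1) - zbar)^2 + n2 * (mean(z2) - zbar)^2
  within <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  W <- (N - 2) / 1 * between / within
  p <- stats::pf(W, 1, N - 2, lower.tail = FALSE)
  list(W = W, p = p)
}

# Rank-based AUC of a score for recovering binary labels.
rank_auc <- function(score, is_positive) {
  r <- rank(score)
  np <- sum(is_positive); nn <- sum(!is_positive)
  (sum(r[is_positive]) - np * (np + 1) / 2) / (np * nn)
}

quiet_metrics <- function(tracks) {
  suppressMessages(suppressWarnings(cell_metrics(tracks)))
}

quiet_table <- function(tracks, ...) {
  suppressMessages(suppressWarnings(saltmig:::condition_table(tracks, ...)))
}
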