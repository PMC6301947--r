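#' Fit a log-normal model to a speed distribution
#'
#' Bins the speeds into equal-width bins on the linear scale and fits a
#' scaled log-normal density to the bin counts by nonlinear least squares,
#' reporting the coefficient of determination of the fit over bins. Binned
#' least squares (rather than maximum likelihood) is used because a
#' goodness-of-fit R-squared of the fitted curve is the quantity of
#' interest. Non-positive speeds carry no information about a log-normal
#' and are excluded with a message reporting the count.
#'
#' @param speeds Numeric vector of per-cell mean speeds (um/hr).
#' @param n_bins Number of equal-width bins (default 20). Ignored when
#'   `binning = "fd"`, which picks the bin count by the Freedman-Diaconis
#'   rule.
#' @param binning `"fixed"` (use `n_bins`) or `"fd"`.
#' @return A list of class `lognormal_fit`: `mu`, `sigma` (log-scale
#'   parameters), `amplitude`, `r_squared`, `n_bins`, `n_cells` (speeds
#'   used), `n_excluded`, and the `bins` table (mid, count, fitted).
#' @export
fit_lognormal <- function(speeds, n_bins = 20,
                          binning = c("fixed", "fd")) {
  binning <- match.arg(binning)
  speeds <- speeds[is.finite(speeds)]
  n_excluded <- sum(speeds <= 0)
  if (n_excluded > 0) {
    message(sprintf("excluded %d non-positive speed(s) from log-normal fit",
                    n_excluded))
  }
  x <- speeds[speeds > 0]
  if (length(x) < 20) stop("need at least 20 positive speeds", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("degenerate fit: all speeds identical", call. = FALSE)
  }
  if (binning == "fd") {
    n_bins <- max(5L, grDevices::nclass.FD(x))
  }
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  bw <- diff(breaks)[1]
  start <- list(a = length(x) * bw,
                mu = mean(log(x)),
                sigma = max(stats::sd(log(x)), 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ a * dlnorm(mids, mu, sigma),
                      start = start,
                      lower = c(a = 1e-10, mu = -Inf, sigma = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("log-normal fit failed: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  fitted_counts <- est[["a"]] * stats::dlnorm(mids, est[["mu"]], est[["sigma"]])
  ss_res <- sum((counts - fitted_counts)^2)
  ss_tot <- sum((counts - mean(counts))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(mu = unname(est[["mu"]]), sigma = unname(est[["sigma"]]),
                 amplitude = unname(est[["a"]]), r_squared = r2,
                 n_bins = n_bins, n_cells = length(x),
                 n_excluded = n_excluded,
                 bins = tibble::tibble(mid = mids, count = counts,
                                       fitted = fitted_counts)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit> mu = %.3f, sigma = %.3f, R^2 = %.3f (%d bins, %d cells)\n",
    x$mu, x$sigma, x$r_squared, x$n_bins, x$n_cells))
  invisible(x)
}

#' Spearman rank correlation between two per-cell parameters
#'
#' Midrank-tied Spearman correlation with the large-sample p-value
#' approximation, as appropriate for non-Gaussian per-cell migration
#' parameters.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped); at least 3 complete pairs, neither constant.
#' @return A list of class `correlation_result`: `r`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> Spearman r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Levene's test for equality of variances between two groups
#'
#' Tests whether two cell populations have equal spread in a migration
#' parameter, using absolute deviations from the group center: the
#' classical Levene form centers on the group mean (default); centering on
#' the median gives the Brown-Forsythe variant, more robust to heavy
#' tails. The statistic is the one-way ANOVA F on the absolute deviations,
#' referred to F(1, N - 2).
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @param center `"mean"` (classical Levene) or `"median"`
#'   (Brown-Forsythe).
#' @return A list of class `levene_result`: `W` (the statistic), `p`,
#'   `center`, `n1`, `n2`.
#' @export
levene_test <- function(group1, group2, center = c("mean", "median")) {
  center <- match.arg(center)
  group1 <- group1[is.finite(group1)]
  group2 <- group2[is.finite(group2)]
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  cfun <- if (center == "mean") base::mean else stats::median
  z1 <- abs(group1 - cfun(group1))
  z2 <- abs(group2 - cfun(group2))
  if (sum(z1) == 0 && sum(z2) == 0) {
    stop("Levene statistic undefined: zero within-group deviation in both groups",
         call. = FALSE)
  }
  values <- c(group1, group2)
  grp <- factor(rep(c("g1", "g2"), c(length(group1), length(group2))))
  lt <- car::leveneTest(values, grp, center = cfun)
  structure(list(W = lt[1, "F value"], p = lt[1, "Pr(>F)"], center = center,
                 n1 = length(group1), n2 = length(group2)),
            class = "levene_result")
}

#' @export
print.levene_result <- function(x, ...) {
  cat(sprintf("<levene_result> W = %.3f, p = %.3g (center = %s; n = %d, %d)\n",
              x$W, x$p, x$center, x$n1, x$n2))
  invisible(x)
}

#' Identify the fast, high-variability subpopulation
#'
#' Flags cells whose standard deviation of instantaneous speed lies
#' strictly above a population quantile (default 0.95, so roughly the top
#' 5% of cells — the small subpopulation with frequent high-amplitude
#' bursts).
#'
#' @param metrics Per-cell table containing `cell_id` and
#'   `sd_instantaneous_speed` (see [cell_metrics()]).
#' @param quantile Population quantile defining "fast" (default 0.95).
#' @return A list: `cell_ids` (fast cells), `fast_fraction`, `threshold`
#'   (um/hr).
#' @export
fast_subpopulation <- function(metrics, quantile = 0.95) {
  sds <- metrics$sd_instantaneous_speed
  if (length(sds) < 20) stop("need at least 20 cells", call. = FALSE)
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1) {
    stop("quantile must be in (0, 1)", call. = FALSE)
  }
  thr <- unname(stats::quantile(sds, quantile))
  fast <- metrics$cell_id[sds > thr]
  list(cell_ids = fast, fast_fraction = length(fast) / length(sds),
       threshold = thr)
}

#' Displacement-vs-variability population summary
#'
#' Summarizes one condition's per-cell scatter of displacement (net path,
#' the cell's effective migration) against standard deviation of
#' instantaneous speed (its bursting behavior): the point list, the
#' population centroid (arithmetic means) with per-axis standard
#' deviations, and quadrant counts split at the population medians (the
#' upper-right quadrant holds cells with both efficient migration and
#' high-amplitude bursting).
#'
#' @param metrics Per-cell table with `cell_id`, `net_path_um` and
#'   `sd_instantaneous_speed`.
#' @param medians Optional length-2 numeric `c(displacement, sd)` to use as
#'   the quadrant split (e.g. the control population's medians when
#'   summarizing a treated population); defaults to this table's medians.
#' @return A list of class `population_summary`: `points` (tibble),
#'   `centroid`, `centroid_sd`, `medians`, `quadrant_counts` (named ll,
#'   lr, ul, ur), `n`.
#' @export
scatter_summary <- function(metrics, medians = NULL) {
  if (nrow(metrics) == 0) stop("empty metrics table", call. = FALSE)
  pts <- tibble::tibble(cell_id = metrics$cell_id,
                        displacement_um = metrics$net_path_um,
                        sd_instantaneous_speed = metrics$sd_instantaneous_speed)
  if (is.null(medians)) {
    medians <- c(displacement_um = stats::median(pts$displacement_um),
                 sd_instantaneous_speed = stats::median(pts$sd_instantaneous_speed))
  } else {
    medians <- stats::setNames(as.numeric(medians),
                               c("displacement_um", "sd_instantaneous_speed"))
  }
  hi_x <- pts$displacement_um > medians[1]
  hi_y <- pts$sd_instantaneous_speed > medians[2]
  sd0 <- function(v) if (length(v) >= 2) stats::sd(v) else 0
  structure(list(
    points = pts,
    centroid = c(displacement_um = mean(pts$displacement_um),
                 sd_instantaneous_speed = mean(pts$sd_instantaneous_speed)),
    centroid_sd = c(displacement_um = sd0(pts$displacement_um),
                    sd_instantaneous_speed = sd0(pts$sd_instantaneous_speed)),
    medians = medians,
    quadrant_counts = c(ll = sum(!hi_x & !hi_y), lr = sum(hi_x & !hi_y),
                        ul = sum(!hi_x & hi_y), ur = sum(hi_x & hi_y)),
    n = nrow(pts)), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "<population_summary> n = %d; centroid (%.1f um, %.2f um/hr); ur quadrant %d\n",
    x$n, x$centroid[1], x$centroid[2], x$quadrant_counts["ur"]))
  invisible(x)
}

# Per-cell table combining kinematic and burst metrics for one condition.
condition_table <- function(tracks, high_speed_threshold = 20,
                            peak_epsilon = 0) {
  km <- suppressMessages(suppressWarnings(cell_metrics(tracks)))
  bm <- burst_metrics(tracks, high_speed_threshold = high_speed_threshold,
                      peak_epsilon = peak_epsilon)
  out <- dplyr::inner_join(km, bm, by = "cell_id")
  out$displacement_um <- out$net_path_um
  out
}

#' Compare a control and a drug-treated population
#'
#' For each of five per-cell metrics (`peaks_per_hr`,
#' `high_speed_peaks_per_hr`, `sd_instantaneous_speed`,
#' `mean_distance_per_movement_um`, `displacement_um`) reports group means
#' with SEM, a two-tailed t-test (Welch by default), and the relative
#' change of the drug mean versus control. Variance homogeneity is
#' additionally tested with Levene's test on displacement and on
#' sd of instantaneous speed — the two axes of the population scatter —
#' to quantify drug-induced homogenization of migratory behavior. P-values
#' are reported unadjusted (each metric answers its own question), with a
#' Holm-adjusted column alongside.
#'
#' @param control,drug [track_set()]s for the two arms (>= 3 cells each,
#'   same frame interval).
#' @param high_speed_threshold,peak_epsilon Burst thresholds in um/hr.
#' @param levene_center `"mean"` or `"median"`.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param alpha Significance level used for the `significant` flags.
#' @return A list of class `condition_comparison`: `tests` (tibble over
#'   the five metrics), `levene` (tibble), `control_summary` and
#'   `drug_summary` ([scatter_summary()], the drug one split at control
#'   medians), `n_control`, `n_drug`, `alpha`, `settings`.
#' @export
compare_conditions <- function(control, drug, high_speed_threshold = 20,
                               peak_epsilon = 0,
                               levene_center = c("mean", "median"),
                               var_equal = FALSE, alpha = 0.05) {
  .assert_track_set(control); .assert_track_set(drug)
  levene_center <- match.arg(levene_center)
  if (abs(frame_interval(control) - frame_interval(drug)) > 1e-9) {
    stop("control and drug track sets have different frame intervals",
         call. = FALSE)
  }
  if (n_tracks(control) < 3 || n_tracks(drug) < 3) {
    stop("each condition needs at least 3 cells", call. = FALSE)
  }
  tc <- condition_table(control, high_speed_threshold, peak_epsilon)
  td <- condition_table(drug, high_speed_threshold, peak_epsilon)
  metrics <- c("peaks_per_hr", "high_speed_peaks_per_hr",
               "sd_instantaneous_speed", "mean_distance_per_movement_um",
               "displacement_um")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  rows <- lapply(metrics, function(m) {
    xc <- tc[[m]]; xd <- td[[m]]
    tt <- tryCatch(stats::t.test(xd, xc, var.equal = var_equal),
                   error = function(e) NULL)
    mc <- mean(xc)
    data.frame(metric = m, mean_control = mc, sem_control = sem(xc),
               mean_drug = mean(xd), sem_drug = sem(xd),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               relative_change = if (mc != 0) (mean(xd) - mc) / mc else NA_real_,
               stringsAsFactors = FALSE)
  })
  tests <- tibble::as_tibble(do.call(rbind, rows))
  tests$p_holm <- stats::p.adjust(tests$p, method = "holm")
  tests$significant <- !is.na(tests$p) & tests$p < alpha
  lev <- lapply(c("displacement_um", "sd_instantaneous_speed"), function(m) {
    lt <- tryCatch(levene_test(tc[[m]], td[[m]], center = levene_center),
                   error = function(e) NULL)
    data.frame(metric = m,
               W = if (is.null(lt)) NA_real_ else lt$W,
               p = if (is.null(lt)) NA_real_ else lt$p,
               stringsAsFactors = FALSE)
  })
  levene <- tibble::as_tibble(do.call(rbind, lev))
  levene$significant <- !is.na(levene$p) & levene$p < alpha
  ctrl_sum <- scatter_summary(tc)
  drug_sum <- scatter_summary(td, medians = ctrl_sum$medians)
  structure(list(tests = tests, levene = levene,
                 control_summary = ctrl_sum, drug_summary = drug_sum,
                 n_control = nrow(tc), n_drug = nrow(td), alpha = alpha,
                 settings = list(high_speed_threshold = high_speed_threshold,
                                 peak_epsilon = peak_epsilon,
                                 levene_center = levene_center,
                                 var_equal = var_equal)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> n = %d control vs %d drug\n",
              x$n_control, x$n_drug))
  sig <- x$tests$metric[x$tests$significant]
  cat("  metrics changed at alpha:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  lsig <- x$levene$metric[x$levene$significant]
  cat("  variance changed (Levene):",
      if (length(lsig)) paste(lsig, collapse = ", ") else "none", "\n")
  invisible(x)
}
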