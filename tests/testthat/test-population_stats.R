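test_that("spearman correlation matches hand-ranked oracles and monotone limits", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$r, 1)
  expect_equal(spearman_cor(x, -sqrt(x))$r, -1)
  # hand-ranked: d = (-1, 1, -1, 1, 0), r = 1 - 6 * 4 / (5 * 24) = 0.8
  expect_equal(spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$r, 0.8)
  expect_error(spearman_cor(x, rep(1, 10)), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")

  # invariance under strictly monotone transforms
  set.seed(701)
  a <- rnorm(50); b <- rnorm(50)
  r0 <- spearman_cor(a, b)$r
  expect_equal(spearman_cor(exp(a), b)$r, r0)
  expect_equal(spearman_cor(a, 3 * b - 10)$r, r0)
})

test_that("Levene test matches the textbook W formula and its invariances", {
  g1 <- c(1, 2, 3, 4); g2 <- c(-2, 0, 4, 6)
  got <- levene_test(g1, g2)
  want <- levene_W_oracle(g1, g2, mean)
  expect_equal(got$W, want$W, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  expect_equal(c(got$n1, got$n2), c(4, 4))

  got_med <- levene_test(g1, g2, center = "median")
  want_med <- levene_W_oracle(g1, g2, stats::median)
  expect_equal(got_med$W, want_med$W, tolerance = 1e-9)

  # identical groups: W = 0, p = 1
  same <- levene_test(g1, g1)
  expect_equal(same$W, 0)
  expect_equal(same$p, 1)

  # no within-group spread anywhere: undefined
  expect_error(levene_test(c(1, 1), c(2, 2)), "undefined")

  # invariant under shift, and under common rescaling
  set.seed(702)
  for (rep in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), sd = 2)
    w <- levene_test(a, b)$W
    expect_equal(levene_test(a + 7, b + 7)$W, w, tolerance = 1e-9)
    expect_equal(levene_test(a * 3.5, b * 3.5)$W, w, tolerance = 1e-9)
    expect_equal(levene_test(a, b)$W, levene_W_oracle(a, b, mean)$W,
                 tolerance = 1e-9)
  }
})

test_that("Levene test detects a doubled standard deviation", {
  set.seed(703)
  rejections <- vapply(1:60, function(i) {
    levene_test(rnorm(150), rnorm(150, sd = 2))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})

test_that("log-normal fit recovers known parameters and flags misspecification", {
  set.seed(704)
  x <- rlnorm(4000, meanlog = 2, sdlog = 0.5)
  fit <- fit_lognormal(x)
  expect_equal(fit$mu, 2, tolerance = 0.1)
  expect_equal(fit$sigma, 0.5, tolerance = 0.1)
  expect_gt(fit$r_squared, 0.9)
  expect_equal(fit$n_bins, 20)

  u <- runif(4000, 1, 2)
  fit_u <- fit_lognormal(u)
  expect_lt(fit_u$r_squared, fit$r_squared)

  expect_error(fit_lognormal(rep(3, 100)), "identical")
  expect_error(fit_lognormal(rlnorm(10)), "at least 20")
  expect_message(fit_lognormal(c(rep(0, 5), x)), "excluded 5")
})

test_that("fast subpopulation calls the top tail of speed variability", {
  set.seed(705)
  metrics <- tibble::tibble(cell_id = sprintf("c%03d", 1:100),
                            sd_instantaneous_speed = runif(100))
  fs <- fast_subpopulation(metrics, quantile = 0.95)
  expect_equal(fs$fast_fraction, 0.05, tolerance = 0.011)
  expect_true(all(metrics$sd_instantaneous_speed[
    metrics$cell_id %in% fs$cell_ids] > fs$threshold))

  # all-equal variability: nothing strictly above the quantile
  flat <- tibble::tibble(cell_id = sprintf("c%03d", 1:50),
                         sd_instantaneous_speed = rep(2, 50))
  expect_equal(fast_subpopulation(flat)$fast_fraction, 0)

  # well-separated simulated mixture, 10% fast, threshold at 0.90
  slow_cfg <- sim_config(180, 0, saltmig:::.preset_slow(),
                         saltmig:::.preset_fast(),
                         scenario = "amp_control", seed = 7051)
  fast_cfg <- sim_config(20, 1, saltmig:::.preset_slow(),
                         saltmig:::.preset_fast(),
                         scenario = "amp_control", seed = 7052)
  tab <- rbind(cbind(quiet_table(simulate_population(slow_cfg)$tracks),
                     truth = "slow"),
               cbind(quiet_table(simulate_population(fast_cfg)$tracks),
                     truth = "fast"))
  tab$cell_id <- sprintf("m%03d", seq_len(nrow(tab)))
  fs2 <- fast_subpopulation(tab, quantile = 0.90)
  called <- tab$cell_id %in% fs2$cell_ids
  truth <- tab$truth == "fast"
  jaccard <- sum(called & truth) / sum(called | truth)
  expect_gt(jaccard, 0.8)
})

test_that("scatter summary reports centroid, spread and quadrants", {
  one <- tibble::tibble(cell_id = "c1", net_path_um = 5,
                        sd_instantaneous_speed = 2)
  s1 <- scatter_summary(one)
  expect_equal(unname(s1$centroid), c(5, 2))
  expect_equal(unname(s1$centroid_sd), c(0, 0))

  cross <- tibble::tibble(cell_id = paste0("c", 1:4),
                          net_path_um = c(0, 10, 5, 5),
                          sd_instantaneous_speed = c(3, 3, 0, 6))
  s4 <- scatter_summary(cross)
  expect_equal(unname(s4$centroid), c(5, 3))
  expect_equal(sum(s4$quadrant_counts), 4)

  # centroid is the column means: remove and re-add a point, unchanged
  set.seed(706)
  tab <- tibble::tibble(cell_id = paste0("c", 1:30),
                        net_path_um = rlnorm(30, 2),
                        sd_instantaneous_speed = rlnorm(30, 1))
  expect_equal(scatter_summary(tab)$centroid,
               scatter_summary(tab[c(2:30, 1), ])$centroid)
  expect_equal(unname(scatter_summary(tab)$centroid),
               c(mean(tab$net_path_um), mean(tab$sd_instantaneous_speed)))

  # amplified populations dominate non-amplified on both axes
  amp <- quiet_table(simulate_population(preset("amp_control", seed = 71))$tracks)
  non <- quiet_table(simulate_population(preset("nonamp_control", seed = 72))$tracks)
  expect_true(all(scatter_summary(amp)$centroid > scatter_summary(non)$centroid))
})

test_that("comparing a condition with itself yields a null report", {
  set.seed(707)
  sim <- simulate_population(preset("amp_control", seed = 707))
  cmp <- compare_conditions(sim$tracks, sim$tracks)
  expect_equal(cmp$tests$relative_change, rep(0, 5))
  expect_true(all(cmp$tests$p > 0.999))
  expect_false(any(cmp$tests$significant))
  expect_equal(cmp$levene$W, c(0, 0))
  expect_equal(cmp$levene$p, c(1, 1))

  small <- track_set(sim$tracks[sim$tracks$cell_id %in%
                                  unique(sim$tracks$cell_id)[1:2], ])
  expect_error(compare_conditions(small, sim$tracks), "at least 3")
})

test_that("speed variability correlates with effective migration in bursty populations", {
  tab <- quiet_table(simulate_population(preset("amp_control", seed = 708))$tracks)
  r <- spearman_cor(tab$sd_instantaneous_speed, tab$mean_effective_speed)$r
  expect_gt(r, 0.5)
})
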