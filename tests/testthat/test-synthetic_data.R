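test_that("simulation is deterministic given seed and config", {
  cfg <- preset("amp_control", seed = 801)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(as.data.frame(a$tracks), as.data.frame(b$tracks))
  expect_identical(a$truth$cells, b$truth$cells)
  c_ <- simulate_population(preset("amp_control", seed = 802))
  expect_false(identical(a$tracks$x_um, c_$tracks$x_um))
})

test_that("degenerate phenotypes behave as configured", {
  still <- phenotype_params(p_burst = 0, burst_duration_mean_frames = 2,
                            burst_speed_mu = log(10), burst_speed_sigma = 0.3)
  set.seed(803)
  tr <- simulate_track(still, n_frames = 20)
  expect_true(all(tr$points$x_um == 0 & tr$points$y_um == 0))
  expect_true(all(tr$states == "pause"))

  # pause jitter alone produces no high-speed peaks
  jitter <- phenotype_params(p_burst = 0, burst_duration_mean_frames = 2,
                             burst_speed_mu = log(10), burst_speed_sigma = 0.3,
                             pause_speed_scale = 2)
  set.seed(804)
  total_hs <- 0
  for (i in 1:50) {
    ts <- track_set(simulate_track(jitter, n_frames = 61,
                                   cell_id = "c")$points)
    total_hs <- total_hs + burst_metrics(ts)$n_high_speed_peaks
  }
  expect_equal(total_hs, 0)

  # extreme persistence with a single long burst: directionality near 1
  persistent <- phenotype_params(p_burst = 1, burst_duration_mean_frames = 60,
                                 burst_speed_mu = log(20),
                                 burst_speed_sigma = 0.1,
                                 persistence_kappa = 200)
  set.seed(805)
  dirs <- vapply(1:20, function(i) {
    quiet_metrics(track_set(simulate_track(persistent,
                                           n_frames = 61,
                                           cell_id = "c")$points))$directionality
  }, numeric(1))
  expect_gt(mean(dirs), 0.95)
})

test_that("presets mirror the pooled experimental group sizes", {
  expect_equal(preset("amp_control")$n_cells, 152L)
  expect_equal(preset("amp_drug")$n_cells, 129L)
  expect_equal(preset("nonamp_control")$n_cells, 162L)
  expect_equal(preset("nonamp_drug")$n_cells, 163L)
  expect_equal(preset("nonamp_drug")$drug_effect, c(1, 1))
  expect_equal(preset("amp_drug")$drug_effect, c(0.5, 0.7))
  expect_equal(preset("amp_control")$fraction_fast, 0.20)
  expect_equal(preset("nonamp_control")$fraction_fast, 0.05)
  expect_equal(preset("amp_control")$n_frames, 61L)
  expect_equal(preset("amp_control")$frame_interval_min, 11)
  expect_error(preset("whatever"))
})

test_that("the drug effect is selective: slow-cell tracks are identical in law", {
  base <- preset("amp_control", seed = 806)
  drug <- preset("amp_drug", seed = 806)
  drug$n_cells <- base$n_cells  # equal sizes so per-cell streams align
  a <- simulate_population(base)
  b <- simulate_population(sim_config(
    n_cells = base$n_cells, fraction_fast = drug$fraction_fast,
    slow_params = drug$slow_params, fast_params = drug$fast_params,
    drug_effect = drug$drug_effect, scenario = "amp_drug",
    seed = 806))
  slow_ids <- a$truth$cells$cell_id[a$truth$cells$phenotype == "slow"]
  expect_identical(a$truth$cells$phenotype, b$truth$cells$phenotype)
  expect_equal(
    as.data.frame(a$tracks[a$tracks$cell_id %in% slow_ids, ]),
    as.data.frame(b$tracks[b$tracks$cell_id %in% slow_ids, ]),
    ignore_attr = TRUE)
  fast_ids <- setdiff(a$truth$cells$cell_id, slow_ids)
  expect_false(isTRUE(all.equal(
    as.data.frame(a$tracks[a$tracks$cell_id %in% fast_ids, ]),
    as.data.frame(b$tracks[b$tracks$cell_id %in% fast_ids, ]),
    check.attributes = FALSE)))
})

test_that("halving the burst entry rate halves the peak rate in the rare-burst regime", {
  # for a phenotype whose pauses dominate the cycle, peak rate ~ p_burst;
  # long tracks keep end-of-track burst truncation negligible
  rare <- phenotype_params(p_burst = 0.02, burst_duration_mean_frames = 2.5,
                           burst_speed_mu = log(10), burst_speed_sigma = 0.3,
                           persistence_kappa = 4)
  mk_cfg <- function(drug, seed) sim_config(
    n_cells = 300, fraction_fast = 1, slow_params = rare, fast_params = rare,
    drug_effect = drug, scenario = if (drug[1] == 1) "amp_control" else "amp_drug",
    n_frames = 301, seed = seed)
  ctrl <- simulate_population(mk_cfg(c(1, 1), 807))
  half <- simulate_population(mk_cfg(c(0.5, 1), 808))
  r_ctrl <- mean(burst_metrics(ctrl$tracks)$peaks_per_hr)
  r_half <- mean(burst_metrics(half$tracks)$peaks_per_hr)
  expect_equal(r_half / r_ctrl, 0.5, tolerance = 0.15)
})

test_that("detected peak rates track the analytic semi-Markov expectation", {
  sim <- simulate_population(preset("amp_control", seed = 809))
  bm <- burst_metrics(sim$tracks)
  expected <- vapply(seq_len(nrow(sim$truth$cells)), function(i) {
    row <- sim$truth$cells[i, ]
    expected_peaks_per_hr(phenotype_params(
      p_burst = row$p_burst,
      burst_duration_mean_frames = row$burst_duration_mean_frames,
      burst_speed_mu = row$burst_speed_mu,
      burst_speed_sigma = row$burst_speed_sigma))
  }, numeric(1))
  expect_equal(mean(bm$peaks_per_hr), mean(expected), tolerance = 0.2)
})

test_that("fast and slow phenotypes are separable by speed variability", {
  sim <- simulate_population(preset("amp_control", seed = 810))
  m <- quiet_metrics(sim$tracks)
  is_fast <- sim$truth$cells$phenotype[match(m$cell_id,
                                             sim$truth$cells$cell_id)] == "fast"
  expect_gt(rank_auc(m$sd_instantaneous_speed, is_fast), 0.9)
})

test_that("a null mixture shows no spurious drug effect", {
  # fraction_fast 0 with active drug multipliers: control and drug arms are
  # exchangeable, so Levene rejections stay near the nominal rate
  slow <- saltmig:::.preset_slow(); fast <- saltmig:::.preset_fast()
  set.seed(811)
  seeds <- sample.int(1e6, 2 * 60)
  ps <- vapply(1:60, function(i) {
    a <- simulate_population(sim_config(50, 0, slow, fast,
                                        drug_effect = c(0.5, 0.7),
                                        scenario = "amp_control",
                                        seed = seeds[2 * i - 1]))
    b <- simulate_population(sim_config(50, 0, slow, fast,
                                        drug_effect = c(0.5, 0.7),
                                        scenario = "amp_drug",
                                        seed = seeds[2 * i]))
    levene_test(quiet_metrics(a$tracks)$net_path_um,
                quiet_metrics(b$tracks)$net_path_um)$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps < 0.5), 0.25)  # p-values spread over the unit interval
})
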