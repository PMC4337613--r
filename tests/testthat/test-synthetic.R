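test_that("make_trace produces the requested geometry", {
  tr <- make_trace(30)
  expect_s3_class(tr, "neurite_trace")
  expect_equal(tr$vertices[1, ], c(0, 0, 0))
  expect_equal(tr$vertices[nrow(tr$vertices), ], c(30000, 0, 0))
  expect_equal(trace_length(tr), 30000)

  # curved trace: polyline arc length matches the requested length
  trc <- make_trace(10, curvature = 0.05)
  expect_equal(trace_length(trc), 10000, tolerance = 1e-3)
  # and it genuinely curves away from the x axis
  expect_gt(max(abs(trc$vertices[, 2])), 100)

  expect_error(make_trace(0), class = "mpskel_invalid_argument")
  expect_error(make_trace(-5), class = "mpskel_invalid_argument")
})

test_that("simulate_lattice realizes the configured Poisson localization budget", {
  tr <- straight30
  locs <- simulate_lattice(tr, lattice_config(seed = 1))
  # floor(30000/190) + 1 ring sites; mean 30 locs each; background is
  # a fraction 0.10 of the total, so E[n] = 158 * 30 / 0.9
  expect_equal(attr(locs, "n_rings"), 158)
  expected <- 158 * 30 / (1 - 0.10)
  expect_lt(abs(nrow(locs) - expected), 3 * sqrt(expected))
  # ground-truth labels partition the table
  expect_true(all(locs$truth_ring >= -1))
  expect_equal(sum(locs$truth_ring >= 0) + sum(locs$truth_ring == -1),
               nrow(locs))
})

test_that("noiseless lattice is an exact comb at the period plus one phase", {
  tr <- straight30
  locs <- simulate_lattice(tr, noiseless_cfg(seed = 4))
  s <- locs$x_nm # straight trace along +x
  resid <- s %% 190
  expect_lt(max(resid) - min(resid), 1e-6)
  expect_equal(sort(unique(round((s - min(s)) / 190))),
               seq(0, round((max(s) - min(s)) / 190)))
})

test_that("generators are pure functions of their seed", {
  tr <- straight30
  cfg <- lattice_config(seed = 7)
  expect_identical(simulate_lattice(tr, cfg), simulate_lattice(tr, cfg))
  expect_identical(simulate_irregular(tr, cfg), simulate_irregular(tr, cfg))
  lcfg <- live_series_config(n_frames = 600, lattice = cfg)
  expect_identical(simulate_live_series(tr, lcfg),
                   simulate_live_series(tr, lcfg))
  fcfg <- frap_sim_config(0.5, 60, noise_sd = 0.02, seed = 3)
  expect_identical(simulate_frap(fcfg), simulate_frap(fcfg))
  pcfg <- polarity_image_config(seed = 5)
  expect_identical(simulate_polarity_image(pcfg),
                   simulate_polarity_image(pcfg))
})

test_that("generators reject invalid configurations", {
  expect_error(lattice_config(period_nm = 0), class = "mpskel_invalid_argument")
  expect_error(lattice_config(background_fraction = 1),
               class = "mpskel_invalid_argument")
  expect_error(simulate_lattice(make_trace(0.3), lattice_config()),
               class = "mpskel_invalid_argument")
  expect_error(simulate_live_series(straight30,
                 live_series_config(n_frames = 1)),
               class = "mpskel_invalid_argument")
  expect_error(frap_sim_config(1.2, 60), class = "mpskel_invalid_argument")
  expect_error(frap_sim_config(0.5, 60, bleach_depth = 0),
               class = "mpskel_invalid_argument")
  expect_error(polarity_image_config(axon_rows = 1:60, dendrite_rows = 50:80),
               class = "mpskel_invalid_argument")
})

test_that("lattice and irregular clouds share the same marginal density", {
  tr <- straight30
  n_lat <- sapply(1:25, function(i)
    nrow(simulate_lattice(tr, lattice_config(seed = i))))
  n_irr <- sapply(1:25, function(i)
    nrow(simulate_irregular(tr, lattice_config(seed = 1000 + i))))
  expect_gt(t.test(n_lat, n_irr)$p.value, 0.01)
})

test_that("irregular clouds score near zero periodicity", {
  amps <- sapply(1:10, function(i) {
    locs <- simulate_irregular(straight30, lattice_config(seed = i))
    lattice_amplitude(locs)$amplitude
  })
  expect_lte(median(amps), 0.1)
})

test_that("simulated FRAP traces match the closed-form model exactly", {
  cfg <- frap_sim_config(mobile_fraction = 0.6, recovery_halftime_s = 45,
                         bleach_depth = 0.8, acq_bleach_rate_per_s = 0.002)
  tr <- simulate_frap(cfg)
  t <- tr$t_s
  B <- exp(-0.002 * (t + cfg$pre_bleach_s))
  expected <- B
  post <- t >= 0
  expected[post] <- B[post] *
    (0.2 + 0.8 * 0.6 * (1 - 2^(-t[post] / 45)))
  expect_lt(max(abs(tr$roi - expected)), 1e-9)
  expect_lt(max(abs(tr$reference - B)), 1e-9)

  # full-bleach, fully-mobile trace passes through 0.5 at the half-time
  tr2 <- simulate_frap(frap_sim_config(1, 60, bleach_depth = 1))
  expect_equal(recovery_fraction(tr2, 60), 0.5)
  # immobile: post-bleach trace flat at 1 - bleach_depth
  tr3 <- simulate_frap(frap_sim_config(0, 60, bleach_depth = 0.9))
  expect_true(all(abs(tr3$roi[tr3$t_s >= 0] - 0.1) < 1e-12))
})

test_that("live series with zero drift keeps the lattice static across windows", {
  ls <- simulate_live_series(straight30, live_series_config(
    n_frames = 24000, phase_drift_nm_per_s = 0,
    lattice = lattice_config(seed = 3)))
  expect_true(all(ls$frame >= 1 & ls$frame <= 24000))
  shifts <- phase_shift_table(ls, straight30)
  expect_lte(max(abs(shifts$peak_lag_nm)), 10) # one 10 nm bin
})

test_that("imposed drift shows up as the predicted window phase shift", {
  # 1 nm/s over 400 s: window centers (50, 350) s are 300 s apart
  ls <- simulate_live_series(straight30, live_series_config(
    n_frames = 24000, frame_rate_hz = 60, phase_drift_nm_per_s = 1,
    lattice = lattice_config(seed = 3)))
  tws <- split_time_windows(ls, n_windows = 4)
  cc <- window_cross_correlation(tws$windows[[1]], tws$windows[[4]],
                                 straight30, max_lag_nm = 600)
  expect_lt(abs(cc$peak_lag_nm - 300), 20)
})

test_that("polarity images honor configured intensities and masks", {
  sim <- simulate_polarity_image(polarity_image_config(
    axon_intensity = 200, dendrite_intensity = 100,
    background_intensity = 5, poisson_noise = FALSE))
  expect_equal(masked_mean(sim$image, sim$masks$axon), 200)
  expect_equal(masked_mean(sim$image, sim$masks$dendrite), 100)
  expect_equal(masked_mean(sim$image, sim$masks$background), 5)
  expect_equal(sum(sim$masks$axon), 1e4)
  expect_equal(sum(sim$masks$dendrite), 1e4)
  # no-noise, no-background ratio is exact by construction
  ir <- intensity_ratio(sim$image, sim$masks, background_subtract = FALSE)
  expect_equal(ir$ratio, 2)

  # background-only configuration: both compartments at background level
  bg <- simulate_polarity_image(polarity_image_config(
    axon_intensity = 7, dendrite_intensity = 7, background_intensity = 7,
    poisson_noise = FALSE))
  expect_equal(masked_mean(bg$image, bg$masks$axon),
               masked_mean(bg$image, bg$masks$background))
})
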