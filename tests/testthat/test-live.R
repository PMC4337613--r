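test_that("time windows partition frames with the remainder up front", {
  locs <- localization_table(data.frame(
    x_nm = runif(500, 0, 1000), y_nm = 0, frame = sample(24000, 500, TRUE)))
  tws <- split_time_windows(locs, n_windows = 4, n_frames = 24000)
  expect_equal(tws$frame_end - tws$frame_start + 1L, rep(6000L, 4))
  expect_equal(sum(sapply(tws$windows, nrow)), nrow(locs))

  tws2 <- split_time_windows(locs, n_windows = 3, n_frames = 10)
  expect_equal(tws2$frame_end - tws2$frame_start + 1L, c(4L, 3L, 3L))
  expect_equal(tws2$frame_start, c(1L, 5L, 8L))

  expect_error(split_time_windows(locs, n_windows = 5, n_frames = 2),
               class = "mpskel_invalid_argument")
  # every localization lands in exactly one window
  ids <- sort(unlist(lapply(tws$windows, function(w) w$id)))
  expect_equal(ids, sort(locs$id))
})

test_that("window-vs-itself cross-correlation reduces to the autocorrelation", {
  ls <- simulate_live_series(straight30, live_series_config(
    n_frames = 6000, lattice = lattice_config(seed = 4)))
  tws <- split_time_windows(ls, n_windows = 2)
  w <- tws$windows[[1]]
  cc <- window_cross_correlation(w, w, straight30, max_lag_nm = 800)
  proj <- project_onto_trace(w, straight30)
  ac <- autocorrelation(density_profile(proj$s, 10, range_nm = c(0, 30000)),
                        max_lag_nm = 800)
  nonneg <- cc$lags_nm >= 0
  expect_lt(max(abs(cc$cc[nonneg] - ac$ac)), 1e-10)
  expect_equal(cc$peak_lag_nm, 0)
  expect_equal(max(cc$cc), 1, tolerance = 1e-9)
})

test_that("phase shifts are antisymmetric under window exchange", {
  ls <- simulate_live_series(straight30, live_series_config(
    n_frames = 24000, phase_drift_nm_per_s = 0.5,
    lattice = lattice_config(seed = 5)))
  tws <- split_time_windows(ls, n_windows = 4)
  ab <- window_cross_correlation(tws$windows[[1]], tws$windows[[4]],
                                 straight30, max_lag_nm = 600)
  ba <- window_cross_correlation(tws$windows[[4]], tws$windows[[1]],
                                 straight30, max_lag_nm = 600)
  expect_lte(abs(ab$peak_lag_nm + ba$peak_lag_nm), 10)
})

test_that("per-window spectra agree for static and purely translated lattices", {
  for (drift in c(0, 1)) {
    ls <- simulate_live_series(straight30, live_series_config(
      n_frames = 12000, phase_drift_nm_per_s = drift,
      lattice = lattice_config(seed = 6)))
    tws <- split_time_windows(ls, n_windows = 4)
    sp <- window_spectra(tws, straight30)
    expect_false(any(sp$low_confidence))
    expect_lte(diff(range(sp$dominant_period_nm)), 5)
  }
})

test_that("degenerate windows are flagged, not fatal, in window_spectra", {
  # all localizations in the first half of the acquisition
  locs <- simulate_lattice(straight30, lattice_config(seed = 7))
  locs$frame <- sample(1:100, nrow(locs), replace = TRUE)
  tws <- split_time_windows(locs, n_windows = 2, n_frames = 1000)
  expect_equal(nrow(tws$windows[[2]]), 0L)
  sp <- window_spectra(tws, straight30)
  expect_true(is.na(sp$dominant_period_nm[2]))
  expect_true(sp$low_confidence[2])
  expect_false(is.na(sp$dominant_period_nm[1]))
  expect_error(window_cross_correlation(tws$windows[[1]], tws$windows[[2]],
                                        straight30),
               class = "mpskel_invalid_argument")
})
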