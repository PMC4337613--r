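test_that("projection assigns arc-length coordinates and filters by lateral distance", {
  tr <- neurite_trace(rbind(c(0, 0, 0), c(1000, 0, 0), c(1000, 1000, 0)))
  locs <- localization_table(data.frame(
    x_nm = c(1000, 500, 1000, 500),
    y_nm = c(0, 100, 600, 500),
    z_nm = 0, frame = 1))
  proj <- project_onto_trace(locs, tr, max_lateral_nm = 400)
  # point exactly on vertex 2 -> s = cumulative arc length there
  expect_equal(proj$s[proj$row == 1], 1000)
  expect_equal(proj$lateral[proj$row == 1], 0)
  expect_equal(proj$s[proj$row == 2], 500)
  expect_equal(proj$lateral[proj$row == 2], 100)
  expect_equal(proj$s[proj$row == 3], 1600)
  # 4th point is > 400 nm from the polyline -> excluded
  expect_false(4 %in% proj$row)
  expect_equal(attr(proj, "n_excluded"), 1L)
  expect_equal(nrow(proj) + attr(proj, "n_excluded"), attr(proj, "n_input"))
})

test_that("synthetic lattice projects almost entirely within the acceptance radius", {
  locs <- simulate_lattice(straight30, lattice_config(seed = 8))
  proj <- project_onto_trace(locs, straight30, max_lateral_nm = 400)
  # ring radius 80 + precision 10 and background padded to 110 nm laterally:
  # geometrically everything lies within 400 nm of the axis
  expect_gte(nrow(proj) / nrow(locs), 0.999)
})

test_that("density profiles bin with half-open edges and conserve counts", {
  prof <- density_profile(c(5, 15, 25), 10, range_nm = c(0, 30))
  expect_equal(prof$counts, c(1, 1, 1))
  expect_equal(density_profile(c(0, 10, 20), 10, range_nm = c(0, 30))$counts,
               c(1, 1, 1)) # values on left edges belong to their bin
  expect_equal(sum(density_profile(numeric(0), 10, range_nm = c(0, 100))$counts), 0)
  s <- runif(5000, 0, 30000)
  prof2 <- density_profile(s, 10, range_nm = c(0, 30000))
  expect_equal(sum(prof2$counts), 5000)
  expect_error(density_profile(1:10, bin_size_nm = 0),
               class = "mpskel_invalid_argument")
})

test_that("uniform positions give a flat profile (chi-square uniformity)", {
  set.seed(42)
  s <- runif(5000, 0, 10000)
  prof <- density_profile(s, 100, range_nm = c(0, 10000))
  expect_gt(chisq.test(prof$counts)$p.value, 0.001)
})

test_that("FFT autocorrelation equals the direct double-loop estimator", {
  set.seed(11)
  for (counts in list(rpois(200, 5),
                      5 + 3 * cos(2 * pi * (1:150) / 19) + rnorm(150))) {
    prof <- structure(list(counts = as.numeric(counts), bin_size_nm = 10,
                           s0 = 0), class = "density_profile")
    a_fft <- autocorrelation(prof, max_lag_nm = 500)
    a_dir <- autocorrelation(prof, max_lag_nm = 500, method = "direct")
    expect_lt(max(abs(a_fft$ac - a_dir$ac)), 1e-10)
  }
})

test_that("autocorrelation is unit-normalized at lag zero and bounded for noise", {
  set.seed(12)
  prof <- density_profile(runif(30000, 0, 30000), 10, range_nm = c(0, 30000))
  ac <- autocorrelation(prof, max_lag_nm = 1000)
  expect_equal(ac$ac[1], 1, tolerance = 1e-12)
  # white-noise bound: |ac| <= 4/sqrt(N) for at least 99% of nonzero lags
  N <- length(prof$counts)
  frac_ok <- mean(abs(ac$ac[-1]) <= 4 / sqrt(N))
  expect_gte(frac_ok, 0.99)
})

test_that("a periodic profile yields a cosine-like autocorrelation peaking at its period", {
  s_bins <- 1:3000
  prof <- structure(list(counts = 10 + 8 * cos(2 * pi * s_bins * 10 / 190),
                         bin_size_nm = 10, s0 = 0), class = "density_profile")
  ac <- autocorrelation(prof, max_lag_nm = 1000)
  expect_equal(ac$first_peak_lag_nm, 190)
  expect_gt(ac$ac[20], 0.95) # lag 190 nm
  expect_error(autocorrelation(structure(
    list(counts = rep(3, 500), bin_size_nm = 10, s0 = 0),
    class = "density_profile")), class = "mpskel_degenerate_input")
})

test_that("amplitude of an ideal cosine autocorrelation is 2; flat curves score 0", {
  lags <- seq(0, 600, 10)
  ideal <- structure(list(lags_nm = lags, ac = cos(2 * pi * lags / 190),
                          bin_size_nm = 10, amplitude = NA_real_,
                          first_peak_lag_nm = NA_real_),
                     class = "autocorr_result")
  amp <- autocorr_amplitude(ideal)
  expect_equal(amp$first_peak_lag_nm, 190)
  # valleys are quantized to the 10 nm lag grid, costing ~1% of the score
  expect_equal(amp$amplitude, 2, tolerance = 0.01)

  flat <- ideal
  flat$ac <- c(1, rep(0, length(lags) - 1))
  expect_equal(autocorr_amplitude(flat)$amplitude, 0)

  short <- ideal
  short$lags_nm <- lags[lags <= 300]
  short$ac <- flat$ac[lags <= 300]
  expect_error(autocorr_amplitude(short), class = "mpskel_invalid_argument")
})

test_that("dominant period recovers the generator ground truth", {
  locs <- simulate_lattice(straight30, noiseless_cfg(seed = 2))
  proj <- project_onto_trace(locs, straight30)
  prof <- density_profile(proj$s, 10, range_nm = c(0, 30000))
  sp <- dominant_period(prof)
  expect_equal(sp$dominant_period_nm, 190, tolerance = 2 / 190)
  expect_false(sp$low_confidence)
})

test_that("with two superposed combs the stronger period wins", {
  s_bins <- (1:3000) * 10
  counts <- 20 + 10 * cos(2 * pi * s_bins / 190) + 3 * cos(2 * pi * s_bins / 150)
  prof <- structure(list(counts = counts, bin_size_nm = 10, s0 = 0),
                    class = "density_profile")
  sp <- dominant_period(prof)
  expect_equal(sp$dominant_period_nm, 190, tolerance = 2 / 190)
})

test_that("white-noise profiles are flagged low-confidence", {
  set.seed(21)
  flags <- replicate(10, {
    prof <- structure(list(counts = rnorm(3000), bin_size_nm = 10, s0 = 0),
                      class = "density_profile")
    dominant_period(prof)$low_confidence
  })
  expect_gte(mean(flags), 0.8)
  expect_error(dominant_period(structure(
    list(counts = rep(0, 500), bin_size_nm = 10, s0 = 0),
    class = "density_profile")), class = "mpskel_degenerate_input")
})

test_that("curve averaging is idempotent, linear, and reduces variance", {
  ac <- lattice_amplitude(simulate_lattice(straight30, lattice_config(seed = 3)))
  avg5 <- average_autocorrelation(rep(list(ac), 5))
  expect_equal(avg5$ac, ac$ac)
  expect_equal(avg5$amplitude, ac$amplitude)

  neg <- ac; neg$ac <- -ac$ac
  zero <- average_autocorrelation(list(ac, neg))
  expect_true(all(abs(zero$ac) < 1e-12))

  acs <- lapply(1:12, function(i)
    lattice_amplitude(simulate_lattice(straight30, lattice_config(seed = i))))
  single <- vapply(acs, function(a) a$amplitude, numeric(1))
  grp <- vapply(list(1:4, 5:8, 9:12), function(ix)
    average_autocorrelation(acs[ix])$amplitude, numeric(1))
  expect_lt(sd(grp) / sd(single), 1.5) # averaged curves do not inflate spread
})

test_that("mixed bin sizes cannot be averaged", {
  prof1 <- density_profile(runif(500, 0, 5000), 10, range_nm = c(0, 5000))
  prof2 <- density_profile(runif(500, 0, 5000), 20, range_nm = c(0, 5000))
  expect_error(average_autocorrelation(list(autocorrelation(prof1, 500),
                                            autocorrelation(prof2, 500))),
               class = "mpskel_invalid_argument")
})

test_that("periodicity is invariant to translation and count rescaling", {
  locs <- simulate_lattice(straight30, lattice_config(seed = 5))
  proj <- project_onto_trace(locs, straight30)
  prof <- density_profile(proj$s, 10)
  shifted <- density_profile(proj$s + 373, 10)
  ac1 <- autocorrelation(prof); ac2 <- autocorrelation(shifted)
  expect_equal(ac2$first_peak_lag_nm, ac1$first_peak_lag_nm, tolerance = 10 / 190)
  expect_equal(ac2$amplitude, ac1$amplitude, tolerance = 0.05)
  expect_equal(dominant_period(shifted)$dominant_period_nm,
               dominant_period(prof)$dominant_period_nm, tolerance = 1 / 190)

  scaled <- prof; scaled$counts <- prof$counts * 7.5
  ac3 <- autocorrelation(scaled)
  expect_equal(ac3$ac, ac1$ac, tolerance = 1e-12)
  expect_equal(dominant_period(scaled)$dominant_period_nm,
               dominant_period(prof)$dominant_period_nm, tolerance = 1e-9)
})

test_that("subsampling to the full count reproduces the reference exactly", {
  locs <- simulate_lattice(straight30, lattice_config(seed = 6))
  n <- nrow(locs)
  tab <- subsample_robustness(locs, straight30, target_counts = n, n_reps = 3)
  ref <- lattice_amplitude(locs)$amplitude
  expect_equal(tab$mean_amplitude[tab$target_count == n], ref)
  expect_equal(tab$sd_amplitude[tab$target_count == n], 0)
  # reproducible under a fixed seed
  t1 <- subsample_robustness(locs, straight30, c(n, 2000), n_reps = 5, seed = 2)
  t2 <- subsample_robustness(locs, straight30, c(n, 2000), n_reps = 5, seed = 2)
  expect_identical(t1, t2)
  expect_error(subsample_robustness(locs, straight30, n + 1),
               class = "mpskel_invalid_argument")
})

test_that("periodicity_vs_distance tracks the imposed distal occupancy decay", {
  # single exact segment equals the whole-trace amplitude
  locs <- simulate_lattice(straight30, lattice_config(seed = 7))
  one <- periodicity_vs_distance(locs, straight30, segment_length_um = 30)
  expect_equal(nrow(one), 1)
  expect_equal(one$amplitude, lattice_amplitude(locs)$amplitude)

  # short decay: amplitude decreasing along the axon (Spearman over seeds)
  rhos <- sapply(1:10, function(i) {
    l <- simulate_lattice(straight30,
      lattice_config(density_decay_length_um = 10, seed = i))
    tab <- periodicity_vs_distance(l, straight30, segment_length_um = 5)
    cor(tab$center_um, tab$amplitude, method = "spearman", use = "complete.obs")
  })
  expect_lt(median(rhos), 0)

  expect_error(periodicity_vs_distance(locs, straight30, segment_length_um = 31),
               class = "mpskel_invalid_argument")
})

test_that("increasing ring jitter monotonically degrades the periodicity score", {
  jitters <- c(0, 20, 40, 80)
  med_amp <- sapply(jitters, function(j) {
    amps <- sapply(1:8, function(i)
      lattice_amplitude(simulate_lattice(straight30,
        lattice_config(ring_jitter_nm = j, seed = i)))$amplitude)
    median(amps)
  })
  expect_true(all(diff(med_amp) < 0))
})
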