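#' Configuration for the periodic-lattice localization generator
#'
#' Describes the ground-truth membrane periodic skeleton emulated by
#' [simulate_lattice()]: rings of label positions spaced `period_nm` apart
#' along a neurite, imaged with a given localization precision, labeling
#' density, uniform background, and an optional exponential decay of ring
#' occupancy toward the distal end (as seen in developing axons, where
#' localization density falls off distally).
#'
#' @param period_nm ring spacing along the axis (default 190 nm, the
#'   spectrin-tetramer length scale of the axonal lattice).
#' @param ring_jitter_nm Gaussian sd of each ring's axial position about its
#'   ideal lattice site (default 10).
#' @param loc_precision_nm per-localization Gaussian sd applied
#'   independently in x, y and z (default 10, a conventional SMLM lateral
#'   precision).
#' @param locs_per_ring mean localizations per ring; realized counts are
#'   Poisson (default 30).
#' @param neurite_radius_nm radius of the ring circle around the axis
#'   (default 80).
#' @param background_fraction expected fraction of all localizations placed
#'   uniformly in the bounding volume (default 0.10; must be < 1).
#' @param density_decay_length_um e-folding length of ring occupancy with
#'   arc length; `Inf` (default) means uniform occupancy.
#' @param seed integer RNG seed.
#' @return a list of class `lattice_config`.
#' @export
lattice_config <- function(period_nm = 190, ring_jitter_nm = 10,
                           loc_precision_nm = 10, locs_per_ring = 30,
                           neurite_radius_nm = 80, background_fraction = 0.10,
                           density_decay_length_um = Inf, seed = 1L) {
  check_scalar(period_nm, "period_nm", positive = TRUE)
  check_scalar(ring_jitter_nm, "ring_jitter_nm", nonneg = TRUE)
  check_scalar(loc_precision_nm, "loc_precision_nm", nonneg = TRUE)
  check_scalar(locs_per_ring, "locs_per_ring", positive = TRUE)
  check_scalar(neurite_radius_nm, "neurite_radius_nm", positive = TRUE)
  check_scalar(background_fraction, "background_fraction", nonneg = TRUE)
  if (background_fraction >= 1)
    stop_invalid("'background_fraction' must be < 1")
  check_scalar(density_decay_length_um, "density_decay_length_um", positive = TRUE)
  structure(list(
    period_nm = period_nm, ring_jitter_nm = ring_jitter_nm,
    loc_precision_nm = loc_precision_nm, locs_per_ring = locs_per_ring,
    neurite_radius_nm = neurite_radius_nm,
    background_fraction = background_fraction,
    density_decay_length_um = density_decay_length_um,
    seed = as.integer(seed)
  ), class = "lattice_config")
}

# Ring occupancy at arc length s (nm): exponential decay toward the distal
# end, e-folding length in um, Inf = uniform.
ring_occupancy <- function(s_nm, decay_um) {
  if (is.infinite(decay_um)) rep(1, length(s_nm)) else exp(-(s_nm / 1000) / decay_um)
}

# Background bounding box: the trace's bounding box expanded laterally so a
# straight trace does not yield a zero-volume box.
background_box <- function(trace, cfg) {
  pad <- cfg$neurite_radius_nm + 3 * cfg$loc_precision_nm
  lo <- apply(trace$vertices, 2, min) - pad
  hi <- apply(trace$vertices, 2, max) + pad
  rbind(lo, hi)
}

# Shared machinery: place n_k localizations on a ring of radius r in the
# plane normal to the trace at axial positions s (already jittered/drifted),
# then blur each coordinate with the localization precision.
place_on_rings <- function(trace, s, cfg) {
  n <- length(s)
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  s <- pmin(pmax(s, 0), trace_length(trace))
  at <- trace_point_at(trace, s)
  basis <- normal_basis(at$tangent)
  theta <- stats::runif(n, 0, 2 * pi)
  r <- cfg$neurite_radius_nm
  pos <- at$point +
    r * cos(theta) * basis$n1 +
    r * sin(theta) * basis$n2
  if (cfg$loc_precision_nm > 0)
    pos <- pos + matrix(stats::rnorm(3 * n, sd = cfg$loc_precision_nm), ncol = 3)
  pos
}

draw_background <- function(trace, cfg, n_struct) {
  f <- cfg$background_fraction
  if (f <= 0 || n_struct == 0L) return(matrix(numeric(0), ncol = 3))
  n_bg <- stats::rpois(1, n_struct * f / (1 - f))
  if (n_bg == 0L) return(matrix(numeric(0), ncol = 3))
  box <- background_box(trace, cfg)
  cbind(stats::runif(n_bg, box[1, 1], box[2, 1]),
        stats::runif(n_bg, box[1, 2], box[2, 2]),
        stats::runif(n_bg, box[1, 3], box[2, 3]))
}

assemble_table <- function(struct_pos, ring_idx, bg_pos, frames = NULL) {
  pos <- rbind(struct_pos, bg_pos)
  n <- nrow(pos)
  truth <- c(ring_idx, rep(-1L, nrow(bg_pos)))
  if (is.null(frames)) frames <- rep(1L, n)
  localization_table(data.frame(
    id = seq_len(n), frame = frames,
    x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
    truth_ring = as.integer(truth)
  ))
}

# Draw ring sites and per-ring localization counts for a lattice; returns
# per-localization axial position and ring index.
draw_lattice_axial <- function(trace, cfg) {
  L <- trace_length(trace)
  phase <- stats::runif(1, 0, cfg$period_nm)
  centers <- seq(phase, L, by = cfg$period_nm)
  occ <- ring_occupancy(centers, cfg$density_decay_length_um)
  counts <- stats::rpois(length(centers), cfg$locs_per_ring * occ)
  ring_idx <- rep(seq_along(centers) - 1L, counts)
  s <- rep(centers, counts)
  if (cfg$ring_jitter_nm > 0) {
    # jitter is a property of the ring, common to all its localizations
    jit <- stats::rnorm(length(centers), sd = cfg$ring_jitter_nm)
    s <- s + rep(jit, counts)
  }
  list(s = s, ring = ring_idx, phase = phase, n_rings = length(centers))
}

#' Simulate localizations from a periodic ring lattice on a neurite
#'
#' Ring centers sit at `phase + k * period_nm` along the trace (phase drawn
#' uniformly in one period), each axially jittered by `ring_jitter_nm`.
#' Each ring contributes `Poisson(locs_per_ring * occupancy(s))`
#' localizations placed on a circle of radius `neurite_radius_nm` in the
#' plane normal to the axis, then blurred by the localization precision.
#' Background localizations are uniform over the (laterally padded)
#' bounding box of the trace. Every localization records its ground-truth
#' ring index (`truth_ring`; -1 for background).
#'
#' @param trace a [neurite_trace()] with arc length >= 2 periods.
#' @param cfg a [lattice_config()].
#' @return a [localization_table()] with attributes `phase_nm` (realized
#'   lattice phase) and `n_rings`.
#' @export
#' @examples
#' locs <- simulate_lattice(make_trace(30), lattice_config(seed = 1))
simulate_lattice <- function(trace, cfg = lattice_config()) {
  stopifnot(inherits(trace, "neurite_trace"), inherits(cfg, "lattice_config"))
  if (trace_length(trace) < 2 * cfg$period_nm)
    stop_invalid("trace must be at least two periods long")
  with_seed(cfg$seed, {
    ax <- draw_lattice_axial(trace, cfg)
    struct_pos <- place_on_rings(trace, ax$s, cfg)
    bg_pos <- draw_background(trace, cfg, nrow(struct_pos))
    out <- assemble_table(struct_pos, ax$ring, bg_pos)
    attr(out, "phase_nm") <- ax$phase
    attr(out, "n_rings") <- ax$n_rings
    out
  })
}

#' Simulate an irregular (non-periodic) localization cloud
#'
#' Negative control for periodicity scoring, emulating the largely
#' irregular spectrin distribution of wild-type dendrites. The marginal
#' localization density along the neurite matches [simulate_lattice()] for
#' the same config (including any distal decay), but axial positions are
#' drawn from the continuous occupancy density with no ring structure, so
#' the expected autocorrelation amplitude is ~0. Structural localizations
#' carry `truth_ring = 0`, background -1.
#'
#' @inheritParams simulate_lattice
#' @return a [localization_table()].
#' @export
simulate_irregular <- function(trace, cfg = lattice_config()) {
  stopifnot(inherits(trace, "neurite_trace"), inherits(cfg, "lattice_config"))
  L <- trace_length(trace)
  if (L < 2 * cfg$period_nm)
    stop_invalid("trace must be at least two periods long")
  with_seed(cfg$seed, {
    # same expected structural count as the lattice: sum over ring sites
    phase <- stats::runif(1, 0, cfg$period_nm)
    centers <- seq(phase, L, by = cfg$period_nm)
    occ <- ring_occupancy(centers, cfg$density_decay_length_um)
    n_struct <- stats::rpois(1, cfg$locs_per_ring * sum(occ))
    s <- sample_axial_density(n_struct, L, cfg$density_decay_length_um)
    struct_pos <- place_on_rings(trace, s, cfg)
    bg_pos <- draw_background(trace, cfg, n_struct)
    assemble_table(struct_pos, rep(0L, n_struct), bg_pos)
  })
}

# Inverse-CDF sampling from density proportional to exp(-s/decay) on [0, L].
sample_axial_density <- function(n, L_nm, decay_um) {
  if (n == 0L) return(numeric(0))
  if (is.infinite(decay_um)) return(stats::runif(n, 0, L_nm))
  lam <- 1 / (decay_um * 1000) # 1/nm
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-lam * L_nm))) / lam
}

#' Configuration for a live-cell localization stream
#'
#' @param n_frames total camera frames (>= 2).
#' @param frame_rate_hz camera frame rate (default 60, a typical STORM
#'   acquisition rate).
#' @param phase_drift_nm_per_s imposed uniform translation of the lattice
#'   along the axis (default 0 = static lattice).
#' @param lattice a [lattice_config()] describing the underlying structure.
#' @return a list of class `live_series_config`.
#' @export
live_series_config <- function(n_frames = 24000L, frame_rate_hz = 60,
                               phase_drift_nm_per_s = 0,
                               lattice = lattice_config()) {
  if (!is.numeric(n_frames) || n_frames < 1)
    stop_invalid("'n_frames' must be >= 1")
  check_scalar(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  check_scalar(phase_drift_nm_per_s, "phase_drift_nm_per_s")
  stopifnot(inherits(lattice, "lattice_config"))
  structure(list(
    n_frames = as.integer(n_frames), frame_rate_hz = frame_rate_hz,
    phase_drift_nm_per_s = phase_drift_nm_per_s, lattice = lattice
  ), class = "live_series_config")
}

#' Simulate a frame-stamped live-cell localization stream
#'
#' Localizations are drawn as in [simulate_lattice()], each stamped with a
#' frame drawn uniformly over `[1, n_frames]`. At frame `f` the whole
#' lattice is translated along the axis by
#' `phase_drift_nm_per_s * (f - 1) / frame_rate_hz`, so zero drift
#' reproduces the static lattice marginally. Background localizations get
#' uniform frame stamps and no drift (they are unstructured).
#'
#' @param trace a [neurite_trace()].
#' @param cfg a [live_series_config()].
#' @return a [localization_table()].
#' @export
simulate_live_series <- function(trace, cfg) {
  stopifnot(inherits(trace, "neurite_trace"), inherits(cfg, "live_series_config"))
  if (cfg$n_frames < 2)
    stop_invalid("'n_frames' must be >= 2 for a live series")
  lat <- cfg$lattice
  if (trace_length(trace) < 2 * lat$period_nm)
    stop_invalid("trace must be at least two periods long")
  with_seed(lat$seed, {
    ax <- draw_lattice_axial(trace, lat)
    n <- length(ax$s)
    frames <- sample.int(cfg$n_frames, n, replace = TRUE)
    t_s <- (frames - 1) / cfg$frame_rate_hz
    s <- ax$s + cfg$phase_drift_nm_per_s * t_s
    struct_pos <- place_on_rings(trace, s, lat)
    bg_pos <- draw_background(trace, lat, n)
    bg_frames <- sample.int(cfg$n_frames, nrow(bg_pos), replace = TRUE)
    assemble_table(struct_pos, ax$ring, bg_pos,
                   frames = c(frames, bg_frames))
  })
}

#' Configuration for a simulated FRAP experiment
#'
#' The simulated bleached-ROI intensity follows
#' `I(t) = B(t) * [(1 - bleach_depth) + bleach_depth * mobile_fraction *
#' (1 - 2^(-t / halftime))]` for time `t >= 0` after the bleach, and
#' `I(t) = B(t)` before it, where `B(t) = exp(-acq_bleach_rate * (t + pre_bleach_s))`
#' is the acquisition-photobleaching envelope (also emitted as the
#' reference trace). Gaussian noise is added last. Time origin is the
#' bleach event; pre-bleach samples have negative times.
#'
#' @param mobile_fraction fraction of fluorescence that recovers (0-1).
#' @param recovery_halftime_s half-time of the single-exponential recovery.
#' @param bleach_depth fraction of ROI intensity removed by the bleach
#'   (default 0.9).
#' @param acq_bleach_rate_per_s exponential acquisition-photobleaching rate
#'   applied to ROI and reference alike (default 0).
#' @param noise_sd additive Gaussian noise sd relative to the pre-bleach
#'   intensity (default 0).
#' @param pre_bleach_s,post_bleach_s,sample_interval_s trace timing;
#'   defaults 10 s pre-bleach, 600 s post-bleach, 1 s sampling (1 Hz
#'   acquisition).
#' @param seed integer RNG seed (used only when `noise_sd > 0`).
#' @return a list of class `frap_sim_config`.
#' @export
frap_sim_config <- function(mobile_fraction, recovery_halftime_s,
                            bleach_depth = 0.9, acq_bleach_rate_per_s = 0,
                            noise_sd = 0, pre_bleach_s = 10,
                            post_bleach_s = 600, sample_interval_s = 1,
                            seed = 1L) {
  check_scalar(mobile_fraction, "mobile_fraction", nonneg = TRUE)
  if (mobile_fraction > 1) stop_invalid("'mobile_fraction' must be <= 1")
  check_scalar(recovery_halftime_s, "recovery_halftime_s", positive = TRUE)
  check_scalar(bleach_depth, "bleach_depth", positive = TRUE)
  if (bleach_depth > 1) stop_invalid("'bleach_depth' must be <= 1")
  check_scalar(acq_bleach_rate_per_s, "acq_bleach_rate_per_s", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(pre_bleach_s, "pre_bleach_s", positive = TRUE)
  check_scalar(post_bleach_s, "post_bleach_s", positive = TRUE)
  check_scalar(sample_interval_s, "sample_interval_s", positive = TRUE)
  if (pre_bleach_s < 2 * sample_interval_s)
    stop_invalid("need at least 2 pre-bleach samples")
  structure(list(
    mobile_fraction = mobile_fraction,
    recovery_halftime_s = recovery_halftime_s,
    bleach_depth = bleach_depth,
    acq_bleach_rate_per_s = acq_bleach_rate_per_s,
    noise_sd = noise_sd, pre_bleach_s = pre_bleach_s,
    post_bleach_s = post_bleach_s, sample_interval_s = sample_interval_s,
    seed = as.integer(seed)
  ), class = "frap_sim_config")
}

#' FRAP presets for the two expression regimes
#'
#' `"high"` emulates the high-expression regime where most labeled spectrin
#' is freely diffusing: mobile fraction 0.75 with a half-time of
#' `300 / log2(27)` s (~63.1 s), constructed so the noiseless
#' bleach-corrected recovery fraction at 5 min is exactly 75%.
#' `"low"` emulates the low-expression regime where spectrin is
#' incorporated into the stable lattice: mobile fraction 0 (recovery
#' essentially undetectable).
#'
#' @param which `"high"` or `"low"`.
#' @param ... overrides passed on to [frap_sim_config()] (e.g.
#'   `acq_bleach_rate_per_s`, `noise_sd`, `seed`).
#' @return a `frap_sim_config`.
#' @export
frap_preset <- function(which = c("high", "low"), ...) {
  which <- match.arg(which)
  halftime <- 300 / log2(27)
  args <- list(...)
  base <- list(
    mobile_fraction = if (which == "high") 0.75 else 0,
    recovery_halftime_s = halftime,
    bleach_depth = 0.9
  )
  do.call(frap_sim_config, utils::modifyList(base, args))
}

#' Simulate a FRAP trace
#'
#' @param cfg a [frap_sim_config()].
#' @return a [frap_trace()] data frame with columns `t_s`, `roi`,
#'   `reference`; the bleach occurs at t = 0.
#' @export
simulate_frap <- function(cfg) {
  stopifnot(inherits(cfg, "frap_sim_config"))
  t <- seq(-cfg$pre_bleach_s, cfg$post_bleach_s, by = cfg$sample_interval_s)
  B <- exp(-cfg$acq_bleach_rate_per_s * (t + cfg$pre_bleach_s))
  post <- t >= 0
  rec <- (1 - cfg$bleach_depth) +
    cfg$bleach_depth * cfg$mobile_fraction *
      (1 - 2^(-(t[post]) / cfg$recovery_halftime_s))
  roi <- B
  roi[post] <- B[post] * rec
  reference <- B
  if (cfg$noise_sd > 0) {
    with_seed(cfg$seed, {
      roi <- roi + stats::rnorm(length(t), sd = cfg$noise_sd)
      reference <- reference + stats::rnorm(length(t), sd = cfg$noise_sd)
    })
  }
  frap_trace(data.frame(t_s = t, roi = roi, reference = reference),
             t_bleach_s = 0)
}

#' Configuration for a two-compartment polarity image
#'
#' A single-channel intensity image with one horizontal axon stripe and one
#' dendrite stripe over a uniform background, plus matching boolean masks,
#' emulating conventional-fluorescence images used to quantify
#' axon/dendrite intensity polarity.
#'
#' @param axon_intensity,dendrite_intensity,background_intensity mean
#'   counts/pixel in each region (>= 0).
#' @param poisson_noise apply Poisson noise per pixel?
#' @param image_shape_px c(rows, cols), default c(200, 200).
#' @param pixel_size_nm pixel pitch (default 100).
#' @param axon_rows,dendrite_rows integer row ranges of the two stripes;
#'   must not overlap. Defaults give 10^4 pixels per stripe.
#' @param seed RNG seed (used when `poisson_noise`).
#' @return a list of class `polarity_image_config`.
#' @export
polarity_image_config <- function(axon_intensity = 210,
                                  dendrite_intensity = 110,
                                  background_intensity = 10,
                                  poisson_noise = TRUE,
                                  image_shape_px = c(200L, 200L),
                                  pixel_size_nm = 100,
                                  axon_rows = 41:90,
                                  dendrite_rows = 111:160,
                                  seed = 1L) {
  check_scalar(axon_intensity, "axon_intensity", nonneg = TRUE)
  check_scalar(dendrite_intensity, "dendrite_intensity", nonneg = TRUE)
  check_scalar(background_intensity, "background_intensity", nonneg = TRUE)
  check_scalar(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  if (length(image_shape_px) != 2L || any(image_shape_px < 1))
    stop_invalid("'image_shape_px' must be c(rows, cols)")
  if (length(intersect(axon_rows, dendrite_rows)) > 0)
    stop_invalid("axon and dendrite stripes must not overlap")
  if (max(axon_rows, dendrite_rows) > image_shape_px[1] ||
      min(axon_rows, dendrite_rows) < 1)
    stop_invalid("stripes must fit inside the image")
  structure(list(
    axon_intensity = axon_intensity,
    dendrite_intensity = dendrite_intensity,
    background_intensity = background_intensity,
    poisson_noise = isTRUE(poisson_noise),
    image_shape_px = as.integer(image_shape_px),
    pixel_size_nm = pixel_size_nm,
    axon_rows = as.integer(axon_rows),
    dendrite_rows = as.integer(dendrite_rows),
    seed = as.integer(seed)
  ), class = "polarity_image_config")
}

#' Polarity image presets for the two genotypes
#'
#' `"wild-type"`: ~twofold axonal enrichment of spectrin — axon 210,
#' dendrite 110 over background 10 counts/px, so the background-subtracted
#' axon/dendrite signal ratio is exactly 2.0. `"ankyrin-b-ko"`: dendritic
#' spectrin raised to axonal levels (axon = dendrite = 210), ratio 1.0.
#'
#' @param which `"wild-type"` or `"ankyrin-b-ko"`.
#' @param ... overrides passed to [polarity_image_config()].
#' @return a `polarity_image_config`.
#' @export
polarity_preset <- function(which = c("wild-type", "ankyrin-b-ko"), ...) {
  which <- match.arg(which)
  base <- list(axon_intensity = 210,
               dendrite_intensity = if (which == "wild-type") 110 else 210,
               background_intensity = 10)
  do.call(polarity_image_config, utils::modifyList(base, list(...)))
}

#' Simulate a two-compartment polarity image with masks
#'
#' @param cfg a [polarity_image_config()].
#' @return a list with elements `image` (an `mps_image`) and `masks` (a
#'   [compartment_masks()] with axon, dendrite and background masks).
#'   Without Poisson noise, masked means equal the configured intensities
#'   exactly.
#' @export
simulate_polarity_image <- function(cfg) {
  stopifnot(inherits(cfg, "polarity_image_config"))
  ny <- cfg$image_shape_px[1]; nx <- cfg$image_shape_px[2]
  img <- matrix(cfg$background_intensity, nrow = ny, ncol = nx)
  img[cfg$axon_rows, ] <- cfg$axon_intensity
  img[cfg$dendrite_rows, ] <- cfg$dendrite_intensity
  if (cfg$poisson_noise) {
    img <- with_seed(cfg$seed,
      matrix(stats::rpois(ny * nx, lambda = img), nrow = ny, ncol = nx))
  }
  axon <- matrix(FALSE, ny, nx); axon[cfg$axon_rows, ] <- TRUE
  dend <- matrix(FALSE, ny, nx); dend[cfg$dendrite_rows, ] <- TRUE
  bg <- !(axon | dend)
  list(
    image = mps_image(img, pixel_size_nm = cfg$pixel_size_nm),
    masks = compartment_masks(axon = axon, dendrite = dend, background = bg)
  )
}
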