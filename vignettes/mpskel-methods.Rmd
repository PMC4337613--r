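---
title: "Methods: quantifying the periodic membrane skeleton from localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the periodic membrane skeleton from localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpskel)
```

## The measurement problem

The axonal membrane periodic skeleton (MPS) is a quasi-one-dimensional
lattice: actin rings wrap the axon circumference and repeat along the shaft
with a ~190 nm spacing set by the length of the spectrin tetramers that
connect them. SMLM resolves this spacing, but a reconstructed localization
cloud is not yet a measurement. `mpskel` turns localization tables into the
quantities this field actually reports: a periodicity score, a period
estimate, their robustness to localization density, live-cell stability
summaries, FRAP turnover fractions, and axon/dendrite intensity polarity.

All coordinates are nanometers and all times seconds internally; a few
config fields that are naturally micrometer-scale (trace lengths, decay
lengths, segment lengths) accept µm and convert on ingest.

## From point cloud to 1D profile

A neurite trace is an ordered 3D polyline. Each localization is assigned
the arc-length coordinate `s` of its nearest point on the polyline
(`project_onto_trace()`); localizations farther than `max_lateral_nm`
(default 400 nm, comfortably above the ~80 nm neurite radius plus
localization error) are treated as off-neurite and excluded. Binned counts
at `bin_size_nm = 10` form the density profile ρ(s). The bin width is a
design choice, not a measured value: ~1/19 of the expected period keeps
peak-location quantization at or below 10 nm (≈5 % of the period) while
leaving ~30 counts per occupied bin at typical labeling densities. Bins are
half-open `[edge, edge + bin)`.

## Periodicity scoring

**Autocorrelation.** We use the mean-subtracted, variance-normalized,
biased (fixed-N denominator) estimator

```
AC(l) = Σ_{s} (ρ(s) − ρ̄)(ρ(s + l) − ρ̄) / (N · var ρ),
```

computed via FFT, with a direct O(N²) implementation of the *same*
estimator retained (`method = "direct"`) as a cross-check; tests require
agreement to 1e−10. This estimator guarantees `AC(0) = 1` and boundedness;
plotted periodicity curves in the literature are unit-normalized but the
estimator behind them is typically unstated, so we fix one and document it.
The **amplitude** score is the value at the first peak minus the mean of
the two flanking valleys: the peak is the maximum of AC over a 130–260 nm
search band (a generous window around the ~190 nm period; configurable),
valley 1 is the minimum on `(0, peak)` and valley 2 the minimum on
`(peak, 2·peak)`. Equal maxima break toward the smallest lag so results
are deterministic. An ideal cosine scores 2; white noise scores ~0; the
default synthetic lattice scores ≈0.8.

**Dominant period.** The profile is mean-subtracted, Hann-windowed,
zero-padded to ≥4× its length, and the power maximum is located in a
100–400 nm period band, refined by quadratic interpolation of the three
samples around the peak. These FFT details are chosen to give ≤2 nm period
resolution on a 30 µm profile; none of them is a measured quantity. A
result is flagged `low_confidence` when the peak lies at a band edge or
its power is below 30× the median in-band power. That multiplier was
calibrated on the generators: structureless profiles (white noise,
irregular clouds) show peak/median ratios below ~15 — the extreme-value
ceiling for ~10³ correlated spectral samples — while default lattices sit
at 600–1200, so 30× separates the regimes by more than an order of
magnitude on either side in log space.

**Degenerate inputs** (zero-variance or empty profiles) raise a typed
condition (`mpskel_degenerate_input`) rather than returning NaN, so batch
pipelines can skip-and-log; `window_spectra()` demonstrates the pattern by
flagging empty windows instead of failing.

**Averaging and robustness.** `average_autocorrelation()` takes the
pointwise mean over the shared lag range and re-scores the averaged curve,
mirroring how multi-segment curves are reported. `subsample_robustness()`
removes localizations at random (without replacement) down to target
counts and re-scores; because the amplitude is variance-normalized, halving
the count costs only a few percent of the score — the in-silico control
that distal amplitude loss is not a density artifact.
`periodicity_vs_distance()` tiles the trace into consecutive half-open
segments (default 5 µm), proximal to distal; partial trailing segments are
dropped, low-count segments are flagged rather than removed.

## The synthetic generators

The generators are first-class, tested code: they define the ground truth
every analysis is validated against.

**Lattice** (`simulate_lattice()`): ring sites at `phase + k·period` with
the phase uniform in one period (random by default so bin edges are never
accidentally aligned; fix the seed for reproducibility). Each ring's axial
position is jittered once (sd `ring_jitter_nm = 10` — lattice disorder is
a ring property, shared by all of that ring's localizations), contributes
`Poisson(30 × occupancy)` localizations on a circle of radius 80 nm in the
normal plane, and every coordinate is blurred by the localization
precision (sd 10 nm per axis, a conventional SMLM precision; the defaults
for jitter, labeling density and precision are field conventions, not
published measurements, and are all exposed in `lattice_config()`).
Occupancy decays as `exp(−s/decay_length)` toward the distal end
(`Inf` = uniform); the exponential form is a modeling choice — published
data show distal decay but no functional form. Background localizations
(10 % of the total in expectation) are uniform over the trace's bounding
box; since a straight trace has a degenerate box, it is padded laterally by
the neurite radius plus 3 precision sd. Rings are circles rather than
filled annuli because only the axial marginal enters the 1D analyses.

**Irregular control** (`simulate_irregular()`): identical count process and
marginal axial density (including decay), but positions drawn from the
continuous occupancy density — no ring comb. Its amplitude is ≈0.06, an
order of magnitude below the lattice, which is what makes the score a
discriminator.

**Live series** (`simulate_live_series()`): lattice localizations stamped
with uniform frames; at frame `f` the lattice is translated by
`drift × (f−1)/frame_rate`. Drift 0 reproduces the static lattice
marginally.

**FRAP** (`simulate_frap()`): the bleached-ROI intensity is
`B(t)·[(1−d) + d·M·(1 − 2^(−t/τ½))]` after the bleach and `B(t)` before,
with `B(t)` the acquisition-photobleaching envelope, also emitted as the
reference trace; noise is added last. Time zero is the bleach event, so
"recovery at 300 s" needs no clock bookkeeping. The **high-expression
preset** uses `M = 0.75`, `d = 0.9`, and `τ½ = 300/log2(27) ≈ 63.1 s`,
chosen so the noiseless corrected recovery fraction at 5 min is exactly
75 % — i.e. the preset is constructed to pass through the published
operating point of the freely-diffusing regime, with `τ½ ≪ 300 s` as the
only kinetic commitment. The **low-expression preset** (`M = 0`) emulates
lattice-incorporated spectrin, whose recovery is essentially undetectable.

**Polarity images** (`simulate_polarity_image()`): one axon and one
dendrite stripe (10⁴ px each by default) over uniform background, with
matching boolean masks and optional Poisson noise. The wild-type preset
(axon 210, dendrite 110, background 10 counts/px) makes the
background-subtracted signal ratio exactly 2.0 — the published ~twofold
axonal enrichment; the ankyrin-B-knockout preset sets dendrite = axon
(ratio 1.0). Intensities are absolute counts; the *presets* are defined
through the subtracted ratio because that is the quantity reported.

Every generator is a pure function of its config including the seed.
Pipelines derive per-stage seeds with `derive_seed()` (counter-based, so
inserting a stage never perturbs earlier stages' streams).

What the generators deliberately do **not** emulate: fluorophore blinking
and camera image formation (localizations are drawn directly), the
alternating two-color spectrin/actin ring phasing, stage drift,
axon-vs-dendrite classification, and spatially resolved FRAP. Passing
tests therefore certify the analysis chain above the localization level;
they say nothing about upstream single-molecule fitting.

## Live-cell stability analysis

`split_time_windows()` partitions frames into equal contiguous windows
(remainder to the earliest windows) — frame-based rather than wall-clock
based, so no acquisition metadata is needed; wall-clock windows map to
frames via the frame rate. Per-window spectra use the same
`dominant_period()` machinery on a shared bin grid. The phase shift
between windows is the peak lag of the Pearson-normalized
cross-correlation of their profiles, with the same fixed-N denominator as
the autocorrelation so the self-case reduces to it exactly; ties break
toward the smallest |lag|, and a positive shift means the later pattern
sits at larger arc length. Two caveats are inherent and documented rather
than patched: (i) the peak is ambiguous modulo one period, so replicate
summaries use medians; (ii) drift smears the lattice *within* a window by
`drift × window_duration`, so stability experiments should keep windows
short enough that this smear stays below ~one period — the packaged drift
analyses use a 200 s acquisition in four 50 s windows for drifts up to
2 nm/s. The live analysis correlates 1D profiles rather than rendered 2D
images; for a quasi-1D lattice both carry the same axial phase
information, though they are not numerically identical.

## FRAP analysis

`bleach_correct()` implements the standard multiplicative ratio method —
`corrected(t) = roi(t) · mean(ref_pre) / ref(t)` — which removes any
common multiplicative envelope exactly; with a constant reference it is
the identity. The pre-bleach baseline is the mean over all pre-bleach
samples (≥2 required; a single-sample baseline is too noise-sensitive).
`recovery_fraction()` is the corrected intensity relative to that
baseline, linearly interpolated at requested times; this is the raw
ratio-to-prebleach definition, not a bleach-depth-normalized one, and the
simulation presets are constructed consistently with it.
`fit_recovery()` fits `R(t) = R0 + A(1 − 2^(−t/τ½))` by
Levenberg–Marquardt with box constraints and recovers the mobile fraction
as `A/(1 − R0)`, since `R0` estimates the immobile floor `1 − d`. A
single-exponential, half-time-parameterized model matches how recovery
times are reported in this literature; reaction–diffusion FRAP models are
out of scope.

## Polarity analysis

Masks are inputs (the dendrite marker staining used to identify
compartments is upstream of this package); the simulator ships matching
masks with its images. Background subtraction defaults to on whenever a
background mask exists, off otherwise — both conventions occur in
published work, so the mode used is part of the result. The ratio is
invariant to detector gain, and (with a background mask) to constant
offsets; the delta-method variance of the ratio estimator is verified
against Monte-Carlo in the tests.

## Problem sizes and runtime

The validation suite and the demonstration pipeline run on 30 µm axons
(~5,000 localizations, 3,000 bins), 50-seed Monte-Carlo batches for the
stochastic claims (period recovery, lattice-vs-irregular discrimination,
FRAP parameter recovery, polarity scatter), 20 seeds for live-cell
stability, and 100 subsampling replicates — sizes at which every
individual analysis is effectively instantaneous and full batches complete
in seconds on one CPU, while Monte-Carlo medians are stable to well within
the tolerances asserted.

## Known limitations

- Periodicity is scored on binned density profiles; a pair-correlation
  approach on raw distances would avoid binning but is not what the
  displayed histograms correspond to, and is not implemented. The choice
  is recorded in results metadata by construction (bin size travels with
  every profile).
- Absolute amplitude values depend on labeling density, jitter and
  precision; they are comparable within a configuration, not across
  instruments. Published amplitude axes are unit-less and are not used as
  quantitative anchors here.
- Phase shifts beyond one period are not unwrapped.
- The curvature argument of `make_trace()` produces planar constant-
  curvature arcs; torsion and wiggle are not modeled. Projection handles
  arbitrary polylines regardless.
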