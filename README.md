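# mpskel

Quantification of the periodic membrane skeleton (MPS) of neurons from
single-molecule localization microscopy (SMLM/STORM) data.

Axons carry a sub-membrane lattice in which actin rings, connected by
spectrin tetramers, repeat along the shaft with a spacing of ~190 nm. The
questions practitioners ask of SMLM data about this structure are
quantitative: *is* a neurite segment periodic, *how* periodic, at what
period, does the score depend trivially on localization density, is the
lattice static in live cells, how fast do its components turn over, and how
polarized is spectrin between axons and dendrites? `mpskel` implements this
analysis chain for localization tables (one row per detected molecule, x/y/z
in nm plus a camera-frame stamp), together with ground-truth simulators so
every stage can be validated against known truth.

## The statistics at the core

Localizations are projected onto a neurite trace (a 3D polyline), giving
each molecule an arc-length coordinate *s*; binned counts form the 1D
density profile ρ(s). Two periodicity summaries are computed from ρ:

- **Autocorrelation amplitude.** With the biased, variance-normalized
  estimator `AC(l) = Σ_s (ρ(s) − ρ̄)(ρ(s+l) − ρ̄) / (N·var ρ)` (so
  `AC(0) = 1`), the score is the value at the first peak (searched in a
  130–260 nm band) minus the mean of the two flanking valleys. An ideal
  cosine scores 2; an unstructured profile scores ~0.
- **Dominant period.** The mean-subtracted, Hann-windowed, zero-padded FFT
  power spectrum is searched in a 100–400 nm period band; the peak is
  refined by quadratic interpolation.

Around these sit: curve averaging across segments, subsampling robustness
(randomly removing localizations and re-scoring), periodicity versus
distance along the axon, time-windowed live-cell analysis (per-window
spectra and cross-correlation phase shifts), FRAP bleach correction
(`corrected = roi · ref̄_pre / ref`) with recovery fractions and a
single-exponential fit, and axon/dendrite intensity ratios from masked
images.

## Worked example

```r
library(mpskel)

trace <- make_trace(30)                     # 30 um straight axon
locs  <- simulate_lattice(trace, lattice_config(seed = 42))
proj  <- project_onto_trace(locs, trace)
prof  <- density_profile(proj$s, bin_size_nm = 10, range_nm = c(0, 30000))
autocorrelation(prof)
#> <autocorr_result> lags 0..1000 nm @ 10 nm; amplitude 0.787, first peak 190 nm
dominant_period(prof)
#> <spectrum_result> dominant period 190.0 nm

# negative control: same density, no ring structure
irr <- simulate_irregular(trace, lattice_config(seed = 42))
autocorrelation(density_profile(project_onto_trace(irr, trace)$s, 10,
                                range_nm = c(0, 30000)))$amplitude
#> 0.060

# FRAP, high-expression preset (mobile spectrin pool)
frap <- simulate_frap(frap_preset("high", acq_bleach_rate_per_s = 0.001))
recovery_fraction(frap, 300)
#> 0.75

# axon/dendrite polarity, wild-type preset
sim <- simulate_polarity_image(polarity_preset("wild-type", seed = 42))
intensity_ratio(sim$image, sim$masks)$ratio
#> 1.998
```

The first-peak lag and dominant period recover the generator's 190 nm ring
spacing; the amplitude of the periodic lattice (0.79) is an order of
magnitude above the irregular control (0.06); the high-expression FRAP
preset recovers 75% of its fluorescence five minutes after the bleach; and
the wild-type polarity preset shows the twofold axonal enrichment of
spectrin.

`run_full_demo(seed = 1, out_dir = "demo")` runs every stage end to end and
writes a JSON report; `run_development_course()` simulates cohorts with
increasing lattice extent and scores periodicity per axonal segment.

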