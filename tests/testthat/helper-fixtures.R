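# Shared fixtures: a 30 um straight axon trace and small analysis helpers.
straight30 <- make_trace(30)

# Project -> bin -> autocorrelate with the package defaults on a fixed grid.
lattice_amplitude <- function(locs, trace = straight30, bin = 10) {
  proj <- project_onto_trace(locs, trace)
  prof <- density_profile(proj$s, bin, range_nm = c(0, trace_length(trace)))
  autocorrelation(prof)
}

# A noiseless comb config: rings are delta-like, no background.
noiseless_cfg <- function(seed = 1L) {
  lattice_config(ring_jitter_nm = 0, loc_precision_nm = 0,
                 background_fraction = 0, seed = seed)
}
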