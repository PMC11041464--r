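# Small shared generators for the tests.

# Two-channel pair with constant mixing a, unit spectra, fixed seed.
const_pair <- function(a, duration, seed, fs = 500) {
  generate_eeg_pair(synth_config(duration = duration, fs = fs,
                                 mixing_mean = a, drift_amplitude = 0,
                                 seed = seed))
}

# Per-second Coh(beta) of a pair without the front-end filter (the MSC
# is invariant to common filtering; skipping it keeps tests fast).
pair_coh_series <- function(pair, dsp = dsp_params()) {
  fragment_coh_series(pair$ch1, pair$ch2, dsp)
}
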