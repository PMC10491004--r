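# Example simulation scenarios for `holophase simulate`.
# Lengths in micrometres; carrier offsets in spectral bins (u0 - P, v0 - Q);
# C is the spherical-wavefront curvature (omit it for a telecentric system).
scenarios:
  - name: demo
    X: 256
    "Y": 256
    delta_xy: 5.86
    wavelength: 0.532
    offset_bins_x: 60
    offset_bins_y: 70
    C: 65000
    pattern: wedding_cake
    height: 0.9
    rng_seed: 11
  - name: demo_telecentric
    X: 256
    "Y": 256
    delta_xy: 5.86
    wavelength: 0.532
    offset_bins_x: 60
    offset_bins_y: 45
    pattern: blobs
    height: 1.2
    noise_sd: 0.02
    rng_seed: 12
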