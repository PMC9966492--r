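# Example run configuration for the embolrheo drivers. Every entry is
# optional: built-in defaults are the published Sisko constants, DMSO
# thermal properties and the default catheter + AVM geometry.
seed: 1

# run_generate(): synthetic flow curves
curves:
  - polymer: onyx18
    temperature: 37
    noise_sd: 0.05
  - polymer: squid12
    temperature: 37
    noise_sd: 0.05
    bump_amplitude: 0.3
    bump_center: 1.0

# run_sweep(): racemose diameter sweep at 37 degC
polymers: [onyx18, squid12]
diameters_mm: [0.5, 0.75, 0.9, 1.0, 1.25, 1.5, 1.75, 1.9, 2.0]
temperature: 37

# run_thermal(): catheter warm-up profile
polymer: squid12
lumen_diameter_m: 1.0e-3
length_m: 1.0
inflow_m3_s: 1.0e-8
inlet_temperature_C: 20
body_temperature_C: 37
n_points: 200
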