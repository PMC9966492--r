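# the four published (polymer x temperature) Sisko parameter sets
published_params <- function() {
  list(onyx18_20 = embolic_sisko_params("onyx18", 20),
       onyx18_37 = embolic_sisko_params("onyx18", 37),
       squid12_20 = embolic_sisko_params("squid12", 20),
       squid12_37 = embolic_sisko_params("squid12", 37))
}

# noiseless curve from a parameter set on a log-spaced grid
noiseless_curve <- function(params, shear_range = c(0.1, 10), n_points = 30) {
  generate_curve(synthetic_rheometry_config(
    params, n_points = n_points, shear_range = shear_range, noise_sd = 0))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
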