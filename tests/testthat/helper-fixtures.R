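# shared fixtures: small deterministic specs and a noise model with known SD
# (used when curves are generated at zero noise but peak amplitudes are
# expressed in SD units through peak_force_scale)

known_noise <- function(sd, baseline = 0) {
  structure(list(baseline = baseline, sd = sd, method = "known"),
            class = "noise_model")
}

zero_noise_spec <- function(rupture_mean = 40, peaks = numeric(0),
                            peak_force_scale = 2) {
  curve_spec(rupture_mean = rupture_mean, rupture_sd = 0,
             peak_amplitudes_sd_units = peaks,
             peak_force_scale = peak_force_scale, noise_sd = 0)
}

analyze_curve <- function(curve, noise = estimate_noise(curve), ...) {
  rup <- detect_rupture(curve, noise)
  detect_prerupture_peaks(curve, rup, noise, ...)
}
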