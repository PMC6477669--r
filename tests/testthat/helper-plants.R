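# Shared fixtures: the packaged parameter rows and small curve builders.

control_params <- function() yeoh_params(0.0002, 0.0090, 0.0080,
                                         label = "60-20-10-10 (1.96 mm/s)")

all_parameter_rows <- function() {
  tab <- surrogate_parameter_table()
  lapply(seq_len(nrow(tab)), function(i)
    yeoh_params(tab$c1_MPa[i], tab$c2_MPa[i], tab$c3_MPa[i],
                label = sprintf("%s (%s)", tab$surrogate[i],
                                tab$rate_label[i])))
}

# Noise-free curve on the given plant over a stretch range.
plant_curve <- function(params, n = 50, lam_min = 0.55, lam_max = 1) {
  lam <- seq(lam_min, lam_max, length.out = n)
  stress_stretch_curve(lam, yeoh_uniaxial_stress(lam, params),
                       label = params$label)
}

# Analytic loop with prescribed branch force functions of displacement.
analytic_loop <- function(f_load, f_unload, d_max = 9, n = 101) {
  d <- seq(0, d_max, length.out = n)
  hysteresis_loop(
    loading = data.frame(displacement_mm = d, force_N = f_load(d)),
    unloading = data.frame(displacement_mm = rev(d), force_N = f_unload(rev(d))))
}
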