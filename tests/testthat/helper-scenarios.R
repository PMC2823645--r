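# Small scenario builders shared across test files.

tiny_panel <- function(fc = c(G1 = 0.301, G2 = -0.5), n = 4, noise = 0,
                       seed = 3, ...) {
  expression_scenario(n_per_group = n, true_log10_fc = fc,
                      noise_sd = noise, seed = seed, ...)
}

# one-point ladder at 1e-16 M: the equivalence point of a baseline -16 gene
point_design <- function(conc = 1e-16) {
  ladder_design(start_conc = conc, dilution_factor = 10, n_points = 1)
}
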