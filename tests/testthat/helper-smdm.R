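# Shared fixtures: small, fast objects rebuilt in code for every run.

fast_settings <- function(sigma_loc = 0.02, seed = 1L, capture_radius = 0.8) {
  acquisition_settings(dt = 1e-3, sigma_loc = sigma_loc,
                       field_width = 6.4, field_height = 6.4,
                       capture_radius = capture_radius, seed = seed)
}

uniform_field <- function(D = 7, shape = c(16L, 16L), bound_fraction = 0) {
  make_filament_field(shape, n_filaments = 0L, D_bound = D, D_free = D,
                      bound_fraction = bound_fraction, seed = 1L)
}

two_region_field <- function(seed = 3L) {
  make_filament_field(c(16L, 16L), n_filaments = 8L, D_bound = 1.5,
                      D_free = 7, bound_fraction = 0.6, seed = seed)
}

# Rayleigh displacement magnitudes at diffusivity D (the model's own
# sampling identity: r = s * sqrt(-2 log U))
rayleigh_r <- function(n, D, dt = 1e-3, sigma_loc = 0) {
  s <- sqrt(2 * D * dt + 2 * sigma_loc^2)
  s * sqrt(-2 * log(runif(n)))
}

vimentin_fasta <- system.file("extdata", "vimentin_P08670_synthetic.fasta",
                              package = "smdmtools")
gfap_fasta <- system.file("extdata", "gfap_P14136_synthetic.fasta",
                          package = "smdmtools")
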