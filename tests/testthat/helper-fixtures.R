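# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

flat_spectrum <- function(value, kind = "reflectance",
                          wl = seq(350, 2500, by = 1)) {
  new_spectrum(wl, rep(value, length(wl)), kind)
}

# Random positive reflectance covering 350-2500 nm at 1 nm: iid uniform in
# [lo, hi], so every band resolves to an independent positive value.
random_reflectance <- function(seed, lo = 0.05, hi = 0.95) {
  withr::with_seed(seed, {
    wl <- seq(350, 2500, by = 1)
    new_spectrum(wl, runif(length(wl), lo, hi), "reflectance")
  })
}

# Sum of Gaussian peaks on the fluorescence grid.
gaussian_fluorescence <- function(amplitudes, centers, widths,
                                  wl = seq(360, 800, by = 0.5),
                                  baseline = 0) {
  v <- rep(baseline, length(wl))
  for (i in seq_along(amplitudes)) {
    v <- v + amplitudes[i] * exp(-(wl - centers[i])^2 / (2 * widths[i]^2))
  }
  new_spectrum(wl, v, "fluorescence")
}

# A small labeled sample set built directly from the generator.
small_dataset <- function(n = 24, seed = 42, ...) {
  generate_dataset(synthetic_config(n_samples = n, seed = seed, ...))
}
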