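# Shared fixtures: all data are generated in code at test time.

tiny_pulse <- function() pulse_spec(200e6, 0.9)

tiny_acq <- function(n = 512, noise_sd = 0.05, jitter = 4) {
  acquisition_spec(n_samples = n, film_echo_delay = round(0.6 * n),
                   scatterer_delay_offset = round(0.15 * n),
                   delay_jitter = jitter, noise_sd = noise_sd)
}

# two cell-like classes at acoustic-contrast ratio 2 (the separable study
# condition: small anucleate cells vs larger nucleated cells)
tiny_classes <- function(contrast_ratio = 2) {
  list(RBC = scatterer_spec(6.57, "cell", acoustic_contrast = 1,
                            diameter_sd_um = 0.66),
       PNT1A = scatterer_spec(10.10, "cell",
                              acoustic_contrast = contrast_ratio,
                              diameter_sd_um = 0.88))
}

tiny_set <- function(n_per_class = 6, n = 512, seed = 1, noise_sd = 0.05,
                     contrast_ratio = 2) {
  generate_labeled_dataset(tiny_classes(contrast_ratio), n_per_class,
                           tiny_acq(n, noise_sd), tiny_pulse(), seed = seed,
                           positive_label = "PNT1A")
}

# spectral peak frequency measured on a zero-padded FFT (Hz)
peak_frequency <- function(x, sample_rate, nfft = 16384) {
  xz <- c(x, rep(0, nfft - length(x)))
  mag <- Mod(stats::fft(xz))[seq_len(nfft / 2 + 1)]
  (which.max(mag) - 1) / nfft * sample_rate
}

# brute-force O(N^2) DFT magnitude oracle, right half
dft_oracle <- function(x) {
  n <- length(x)
  f <- 0:(n %/% 2)
  E <- exp(-2i * pi * outer(f, 0:(n - 1)) / n)
  Mod(as.vector(E %*% x))
}
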