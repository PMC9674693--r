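# The forward model: monocycle pulse, single-recording synthesis, and the
# labeled dataset generator.

test_that("monocycle pulse peaks at the center frequency and is zero-mean bipolar", {
  pw <- make_monocycle_pulse(pulse_spec(200e6, 0.9), 10e9)
  expect_equal(mean(pw), 0, tolerance = 1e-12)
  expect_true(min(pw) < 0 && max(pw) > 0)          # bipolar
  pk <- peak_frequency(pw, 10e9)
  expect_gte(pk, 180e6)
  expect_lte(pk, 220e6)
})

test_that("zero amplitude scale yields an all-zero pulse", {
  pw <- make_monocycle_pulse(pulse_spec(200e6, 0.9), 10e9, amplitude = 0)
  expect_true(all(pw == 0))
})

test_that("pulse spectral peak bin agrees with a brute-force DFT scan", {
  pw <- make_monocycle_pulse(pulse_spec(100e6, 0.9), 10e9)
  nfft <- 2048
  xz <- c(pw, rep(0, nfft - length(pw)))
  fast_bin <- which.max(fft_spectrum(xz)$magnitudes)
  brute_bin <- which.max(dft_oracle(xz))
  expect_identical(fast_bin, brute_bin)
  expect_equal((fast_bin - 1) / nfft * 10e9, 100e6, tolerance = 0.1 * 100e6)
})

test_that("sampling below the Nyquist margin is rejected", {
  expect_error(make_monocycle_pulse(pulse_spec(200e6), 500e6), "Nyquist")
})

test_that("pulse and scatterer specs validate their fields", {
  expect_error(pulse_spec(-1), "center_frequency")
  expect_error(pulse_spec(200e6, 2.5), "fractional_bandwidth")
  expect_error(scatterer_spec(0), "diameter")
  expect_error(scatterer_spec(5, diameter_sd_um = -1), "diameter_sd")
  expect_error(acquisition_spec(n_samples = 512, film_echo_delay = 600),
               "film_echo_delay")
  expect_error(acquisition_spec(noise_sd = -0.1), "noise_sd")
})

test_that("zero contrast and zero noise reduce to the pure film echo", {
  acq <- tiny_acq(512, noise_sd = 0)
  e <- synthesize_echo(scatterer_spec(10, acoustic_contrast = 0), acq,
                       tiny_pulse(), seed = 1)
  pw <- make_monocycle_pulse(tiny_pulse(), acq$sample_rate)
  film <- echotype:::add_centered(numeric(512), pw, acq$film_echo_delay)
  expect_identical(e$samples, film)
  expect_identical(e$samples, e$clean_samples)
})

test_that("synthesis is bit-identical under the same seed", {
  acq <- tiny_acq(512)
  e1 <- synthesize_echo(scatterer_spec(8), acq, tiny_pulse(), seed = 33)
  e2 <- synthesize_echo(scatterer_spec(8), acq, tiny_pulse(), seed = 33)
  expect_identical(e1$samples, e2$samples)
})

test_that("scatterer-echo energy increases strictly with diameter", {
  acq <- tiny_acq(1024, noise_sd = 0)
  energies <- sapply(c(4, 6, 8, 10, 12, 15), function(d) {
    e <- synthesize_echo(scatterer_spec(d), acq, tiny_pulse(), seed = 1)
    win <- e$scatterer_delay + (-60:60)
    sum(e$clean_samples[win]^2)
  })
  expect_true(all(diff(energies) > 0))
})

test_that("the scatterer echo stays below the film reflection", {
  acq <- tiny_acq(512, noise_sd = 0)
  e <- synthesize_echo(scatterer_spec(12, acoustic_contrast = 2), acq,
                       tiny_pulse(), seed = 1)
  win <- e$scatterer_delay + (-40:40)
  expect_lt(max(abs(e$clean_samples[win])), acq$film_echo_amplitude)
  expect_error(
    synthesize_echo(scatterer_spec(10, acoustic_contrast = 100), acq,
                    tiny_pulse(), seed = 1),
    "film reflection")
})

test_that("a scatterer delay outside the recording is rejected", {
  acq <- tiny_acq(512)
  expect_error(
    synthesize_echo(scatterer_spec(8), acq, tiny_pulse(), jitter = 10000),
    "outside")
})

test_that("additive noise variance matches noise_sd^2 within 5%", {
  acq <- tiny_acq(2048, noise_sd = 0.3)
  resid <- unlist(lapply(1:50, function(i) {
    e <- synthesize_echo(scatterer_spec(8), acq, tiny_pulse(), seed = i)
    e$samples - e$clean_samples
  }))
  expect_gte(length(resid), 1e5)
  expect_equal(stats::var(resid), 0.3^2, tolerance = 0.05)
})

test_that("the generator yields exactly n_per_class signals per class", {
  set <- tiny_set(n_per_class = 5)
  expect_equal(nrow(set$signals), 10)
  expect_equal(as.vector(table(set$labels)), c(5, 5))
  expect_true(all(c("id", "label", "material", "diameter_um") %in%
                  names(set$meta)))
  expect_true(all(set$meta$diameter_um > 0))
})

test_that("the generator is deterministic: same seed, identical datasets on disk", {
  d1 <- file.path(tempdir(), "echoset1"); d2 <- file.path(tempdir(), "echoset2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  s1 <- generate_labeled_dataset(tiny_classes(), 3, tiny_acq(256), tiny_pulse(),
                                 seed = 7, dir = d1)
  s2 <- generate_labeled_dataset(tiny_classes(), 3, tiny_acq(256), tiny_pulse(),
                                 seed = 7, dir = d2)
  expect_identical(s1$signals, s2$signals)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  for (f in list.files(d1, pattern = "txt$"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("degenerate class configurations are rejected", {
  expect_error(generate_labeled_dataset(list(A = scatterer_spec(5)), 3,
                                        tiny_acq(), tiny_pulse()),
               "at least 2 classes")
  cls <- list(scatterer_spec(5), scatterer_spec(10))
  names(cls) <- c("A", "A")
  expect_error(generate_labeled_dataset(cls, 3, tiny_acq(), tiny_pulse()),
               "duplicate")
})

test_that("at contrast ratio 2 a scatterer-window energy threshold separates classes", {
  set <- tiny_set(n_per_class = 30, n = 1024, seed = 5, contrast_ratio = 2)
  acq <- tiny_acq(1024)
  win <- (acq$film_echo_delay - acq$scatterer_delay_offset) + (-80:80)
  energy <- rowSums(set$signals[, win]^2)
  y <- labels01(set)
  acc <- max(sapply(stats::quantile(energy, seq(0.1, 0.9, 0.02)),
                    function(thr) mean((energy >= thr) == y)))
  expect_gte(acc, 0.9)
})
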