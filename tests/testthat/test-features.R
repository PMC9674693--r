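# Spectrum / spectrogram featurization against closed forms and a brute-force
# DFT oracle, plus frequency-resolution reduction.

test_that("fft_spectrum matches closed forms for constant and cosine inputs", {
  n <- 64
  sp <- fft_spectrum(rep(2.5, n))
  expect_equal(sp$magnitudes[1], n * 2.5)
  expect_lt(max(sp$magnitudes[-1]), 1e-9)

  k <- 7
  x <- cos(2 * pi * k * (0:(n - 1)) / n)
  sp <- fft_spectrum(x)
  expect_equal(sp$magnitudes[k + 1], n / 2, tolerance = 1e-10)
  expect_lt(max(sp$magnitudes[-(k + 1)]), 1e-9)
})

test_that("fft_spectrum agrees with the O(N^2) DFT oracle on random signals", {
  set.seed(99)
  worst <- 0
  for (n in c(16, 100, 256, 1000)) {
    for (r in 1:13) {
      x <- rnorm(n)
      fast <- fft_spectrum(x)$magnitudes
      brute <- dft_oracle(x)
      expect_length(fast, n %/% 2 + 1)
      worst <- max(worst, max(abs(fast - brute)) / max(brute))
    }
  }
  expect_lt(worst, 1e-8)    # 52 random signals
})

test_that("the full transform of a real signal is conjugate-symmetric before halving", {
  set.seed(7)
  for (n in c(32, 101)) {
    x <- rnorm(n)
    mag <- Mod(stats::fft(x))
    expect_equal(mag[2:n], rev(mag[2:n]), tolerance = 1e-10)
  }
})

test_that("fft_spectrum rejects degenerate input", {
  expect_error(fft_spectrum(1), "at least 2")
  expect_error(fft_spectrum(c(1, NA, 2)), "finite")
})

test_that("spectrogram frame count follows floor((N-l)/d) + 1", {
  sg <- stft_spectrogram(rnorm(160), stft_spec(32, 16))
  expect_equal(ncol(sg$values), 9)    # nine half-overlapping segments
  expect_equal(nrow(sg$values), 17)
  for (n in c(64, 100, 250, 512)) for (l in c(16, 32)) for (d in c(8, 16)) {
    sg <- stft_spectrogram(rnorm(n), stft_spec(l, d))
    expect_equal(ncol(sg$values), (n - l) %/% d + 1)
    expect_equal(nrow(sg$values), l %/% 2 + 1)
  }
})

test_that("nine-segment preset reproduces l=32, d=16 at N=160", {
  spec <- nine_segment_stft(160)
  expect_equal(spec$window_length, 32L)
  expect_equal(spec$step, 16L)
  sg <- stft_spectrogram(rnorm(160), spec)
  expect_equal(ncol(sg$values), 9)
})

test_that("each spectrogram column is the squared-magnitude FFT of its Hamming frame", {
  set.seed(3)
  x <- rnorm(256)
  spec <- stft_spec(32, 16)
  sg <- stft_spectrogram(x, spec)
  w <- echotype:::hamming_window(32)
  for (m in seq_len(ncol(sg$values))) {
    frame <- x[(m - 1) * 16 + 1:32] * w
    expect_equal(sg$values[, m], fft_spectrum(frame)$magnitudes^2,
                 tolerance = 1e-10)
  }
  expect_true(all(sg$values >= 0))
})

test_that("a zero signal yields an all-zero spectrogram and l > N is rejected", {
  sg <- stft_spectrogram(numeric(64), stft_spec(32, 16))
  expect_true(all(sg$values == 0))
  expect_error(stft_spectrogram(rnorm(16), stft_spec(32, 16)), "exceeds")
})

test_that("resolution reduction hits the requested bin count", {
  sp <- fft_spectrum(rnorm(10000))
  expect_length(sp$magnitudes, 5001)
  red <- reduce_resolution(sp, 513)
  expect_length(red$magnitudes, 513)
  expect_true(all(red$magnitudes %in% sp$magnitudes))   # pure subsampling
  # identity when target equals source
  expect_identical(reduce_resolution(sp, 5001), sp)
  expect_error(reduce_resolution(sp, 6000), "must be in")
})

test_that("bin-averaging a constant spectrum returns the same constant", {
  sp <- fft_spectrum(rep(1, 100))
  sp$magnitudes <- rep(3.5, length(sp$magnitudes))
  red <- reduce_resolution(sp, 10, method = "bin_average")
  expect_equal(red$magnitudes, rep(3.5, 10))
})

test_that("spectrogram resolution reduction acts on the frequency axis only", {
  sg <- stft_spectrogram(rnorm(256), stft_spec(32, 16))
  red <- reduce_resolution(sg, 9)
  expect_equal(dim(red$values), c(9, ncol(sg$values)))
  expect_true(all(red$values >= 0))
})

test_that("representation_features returns consistent shapes for all three views", {
  set <- tiny_set(n_per_class = 3, n = 160)
  fw <- representation_features(set$signals, "waveform")
  fs <- representation_features(set$signals, "spectrum")
  fg <- representation_features(set$signals, "spectrogram")
  expect_equal(dim(fw$x), c(6, 160))
  expect_equal(dim(fs$x), c(6, 81))
  expect_equal(dim(fg$x), c(6, 17, 9))
  # per-example max normalization
  expect_equal(unname(apply(abs(fw$x), 1, max)), rep(1, 6))
  expect_equal(unname(apply(abs(fg$x), 1, max)), rep(1, 6))
})
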