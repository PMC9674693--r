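# Signal representations fed to the classifiers: the waveform itself, the
# magnitude frequency spectrum (right half of the FFT), and the spectrogram
# (squared-magnitude short-time Fourier transform over Hamming-windowed
# sliding frames), plus frequency-resolution reduction by decimation or
# bin-averaging.

#' Magnitude frequency spectrum of a real signal
#'
#' Computes `|X(f)|` for `f = 0..floor(N/2)`: the transform of a real signal
#' is conjugate-symmetric, so only the right half is kept.
#'
#' @param samples finite numeric vector, length >= 2
#' @param sample_rate optional sampling rate in Hz; sets the bin spacing
#'   metadata
#' @return object of class `echo_spectrum`: `magnitudes` (length
#'   `floor(N/2)+1`) and `bin_spacing`
#' @export
fft_spectrum <- function(samples, sample_rate = NULL) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples")
  if (!all(is.finite(samples))) stop("non-finite samples")
  mag <- Mod(stats::fft(samples))[seq_len(n %/% 2 + 1)]
  structure(list(magnitudes = mag,
                 bin_spacing = if (is.null(sample_rate)) NA_real_ else sample_rate / n),
            class = "echo_spectrum")
}

# Hamming taper, periodic-symmetric form w(j) = 0.54 - 0.46 cos(2*pi*j/(l-1))
hamming_window <- function(l) {
  stopifnot(l >= 2)
  0.54 - 0.46 * cos(2 * pi * (0:(l - 1)) / (l - 1))
}

#' Short-time Fourier transform specification
#'
#' The study's grid-searched values are a window of `l = 32` samples moving in
#' steps of `d = 16` (50% overlap) with a Hamming taper and squared-magnitude
#' output. `nine_segment_stft()` derives `(l, d)` from the signal length so
#' that the signal splits into nine half-overlapping segments, an
#' alternative convention for describing the same transform.
#'
#' @param window_length window size l in samples
#' @param step hop size d in samples, `0 < d <= l`
#' @return object of class `stft_spec`
#' @export
stft_spec <- function(window_length = 32L, step = 16L) {
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (window_length < 2) stop("window_length must be >= 2")
  if (step < 1 || step > window_length) stop("need 0 < step <= window_length")
  structure(list(window_length = window_length, step = step), class = "stft_spec")
}

#' @rdname stft_spec
#' @param n_samples signal length from which to derive the window
#' @export
nine_segment_stft <- function(n_samples) {
  # nine frames at 50% overlap: N = l + 8 * (l/2) = 5l
  l <- 2L * as.integer(ceiling(n_samples / 10))
  stft_spec(window_length = l, step = l %/% 2L)
}

#' Spectrogram: squared-magnitude STFT over sliding Hamming windows
#'
#' Frame `m` covers samples `(m-1)*d + 1 .. (m-1)*d + l`; trailing samples
#' that do not fill a frame are dropped, giving `floor((N - l)/d) + 1`
#' columns. Rows are the `floor(l/2)+1` non-negative frequency bins.
#'
#' @param samples finite numeric vector, length >= window_length
#' @param spec an [stft_spec()]
#' @return object of class `echo_spectrogram` with non-negative matrix
#'   `values` (rows = frequency bins, columns = time windows)
#' @export
stft_spectrogram <- function(samples, spec = stft_spec()) {
  stopifnot(inherits(spec, "stft_spec"))
  n <- length(samples)
  l <- spec$window_length; d <- spec$step
  if (l > n) stop("window_length (", l, ") exceeds signal length (", n, ")")
  if (!all(is.finite(samples))) stop("non-finite samples")
  w <- hamming_window(l)
  m <- (n - l) %/% d + 1L
  nb <- l %/% 2L + 1L
  out <- matrix(0, nb, m)
  for (j in seq_len(m)) {
    fr <- samples[(j - 1L) * d + seq_len(l)] * w
    out[, j] <- Mod(stats::fft(fr))[seq_len(nb)]^2
  }
  structure(list(values = out, window_length = l, step = d),
            class = "echo_spectrogram")
}

#' Reduce the frequency resolution of a spectrum or spectrogram
#'
#' Decimation keeps `target_bins` evenly spaced frequency bins (the study's
#' "subsampling"); bin-averaging pools contiguous groups of bins, which is
#' less lossy for spiky spectra. The time axis of a spectrogram is untouched.
#'
#' @param rep an `echo_spectrum` or `echo_spectrogram`
#' @param target_bins number of frequency bins to keep, `1 <= target_bins <=
#'   current bins`
#' @param method "decimate" (default) or "bin_average"
#' @return same class as the input, with `target_bins` frequency bins
#' @export
reduce_resolution <- function(rep, target_bins,
                              method = c("decimate", "bin_average")) {
  method <- match.arg(method)
  is_spec <- inherits(rep, "echo_spectrum")
  if (!is_spec && !inherits(rep, "echo_spectrogram"))
    stop("rep must be an echo_spectrum or echo_spectrogram")
  nb <- if (is_spec) length(rep$magnitudes) else nrow(rep$values)
  target_bins <- as.integer(target_bins)
  if (target_bins < 1 || target_bins > nb)
    stop("target_bins (", target_bins, ") must be in 1..", nb)
  if (target_bins == nb) return(rep)
  if (method == "decimate") {
    idx <- round(seq(1, nb, length.out = target_bins))
    if (is_spec) rep$magnitudes <- rep$magnitudes[idx]
    else rep$values <- rep$values[idx, , drop = FALSE]
  } else {
    grp <- ceiling(seq_len(nb) / (nb / target_bins))
    if (is_spec) rep$magnitudes <- as.numeric(tapply(rep$magnitudes, grp, mean))
    else rep$values <- apply(rep$values, 2, function(col) tapply(col, grp, mean))
  }
  rep
}

#' Featurize a matrix of signals under one representation
#'
#' Applies the chosen transform per signal and (optionally) per-example
#' maximum-absolute normalization, the scale presented to all classifiers.
#'
#' @param signals numeric matrix, one signal per row
#' @param representation "waveform", "spectrum" or "spectrogram"
#' @param stft an [stft_spec()] (spectrogram only)
#' @param resolution optional frequency-bin count passed to
#'   [reduce_resolution()]
#' @param method resolution-reduction method
#' @param normalize divide each example by its max |value|
#' @return list with `kind` ("1d" or "2d") and `x`: a matrix `n x d` for 1d,
#'   an array `n x bins x frames` for 2d
#' @export
representation_features <- function(signals,
                                    representation = c("waveform", "spectrum",
                                                       "spectrogram"),
                                    stft = stft_spec(), resolution = NULL,
                                    method = "decimate", normalize = TRUE) {
  representation <- match.arg(representation)
  signals <- as.matrix(signals)
  n <- nrow(signals)
  if (representation == "waveform") {
    x <- signals
    if (!is.null(resolution)) {
      if (resolution > ncol(x)) stop("resolution exceeds waveform length")
      x <- x[, round(seq(1, ncol(x), length.out = resolution)), drop = FALSE]
    }
    if (normalize) x <- normalize_rows(x)
    return(list(kind = "1d", x = x, representation = representation))
  }
  if (representation == "spectrum") {
    first <- fft_spectrum(signals[1, ])
    if (!is.null(resolution)) first <- reduce_resolution(first, resolution, method)
    x <- matrix(0, n, length(first$magnitudes))
    x[1, ] <- first$magnitudes
    if (n > 1) for (i in 2:n) {
      sp <- fft_spectrum(signals[i, ])
      if (!is.null(resolution)) sp <- reduce_resolution(sp, resolution, method)
      x[i, ] <- sp$magnitudes
    }
    if (normalize) x <- normalize_rows(x)
    return(list(kind = "1d", x = x, representation = representation))
  }
  first <- stft_spectrogram(signals[1, ], stft)
  if (!is.null(resolution)) first <- reduce_resolution(first, resolution, method)
  x <- array(0, c(n, nrow(first$values), ncol(first$values)))
  x[1, , ] <- first$values
  if (n > 1) for (i in 2:n) {
    sg <- stft_spectrogram(signals[i, ], stft)
    if (!is.null(resolution)) sg <- reduce_resolution(sg, resolution, method)
    x[i, , ] <- sg$values
  }
  if (normalize) {
    mx <- apply(abs(x), 1, max)
    mx[mx == 0] <- 1
    x <- x / mx              # recycles over the first dimension
  }
  list(kind = "2d", x = x, representation = representation)
}

#' Write a spectrogram to delimited text for inspection
#' @param sg an `echo_spectrogram`
#' @param path destination path (tab-separated, rows = frequency bins)
#' @export
write_spectrogram <- function(sg, path) {
  stopifnot(inherits(sg, "echo_spectrogram"))
  utils::write.table(sg$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
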