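# Parametric forward model for pulse-echo recordings of a single trapped
# micron-sized object resting on an acoustically transparent film. Each
# recording contains one dominant film reflection and one small scatterer echo
# whose amplitude and spectral content depend on the object's diameter and
# material, plus additive Gaussian noise. The model deliberately stops short of
# physical acoustics (no wave propagation or scattering theory): its purpose is
# to produce labeled datasets with the qualitative structure of the real
# recordings, so the downstream pipeline can be exercised and tested.

#' Excitation pulse specification
#'
#' A monocycle bipolar pulse: a single sinusoid cycle under a Gaussian
#' envelope. The -6 dB bandwidth is `fractional_bandwidth * center_frequency`.
#'
#' @param center_frequency pulse center frequency in Hz
#' @param fractional_bandwidth -6 dB bandwidth as a fraction of the center
#'   frequency, in (0, 2)
#' @param polarity only "bipolar" is supported
#' @return object of class `pulse_spec`
#' @export
pulse_spec <- function(center_frequency = 200e6, fractional_bandwidth = 0.9,
                       polarity = "bipolar") {
  if (!is.numeric(center_frequency) || center_frequency <= 0)
    stop("center_frequency must be > 0")
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("fractional_bandwidth must be in (0, 2)")
  polarity <- match.arg(polarity, "bipolar")
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 polarity = polarity), class = "pulse_spec")
}

#' Scatterer (trapped object) specification
#'
#' @param diameter_um mean object diameter in micrometers
#' @param material categorical material label (e.g. "cell", "polystyrene")
#' @param acoustic_contrast dimensionless echo amplitude factor relative to a
#'   reference object of the same size
#' @param diameter_sd_um population standard deviation of the diameter
#' @param spectral_exponent exponent of the diameter-dependent low-pass
#'   spectral shaping of the scatterer echo; materials may differ here
#' @return object of class `scatterer_spec`
#' @export
scatterer_spec <- function(diameter_um, material = "cell",
                           acoustic_contrast = 1, diameter_sd_um = 0,
                           spectral_exponent = 2) {
  if (!is.numeric(diameter_um) || diameter_um <= 0) stop("diameter_um must be > 0")
  if (diameter_sd_um < 0) stop("diameter_sd_um must be >= 0")
  if (acoustic_contrast < 0) stop("acoustic_contrast must be >= 0")
  structure(list(diameter_um = diameter_um, material = as.character(material),
                 acoustic_contrast = acoustic_contrast,
                 diameter_sd_um = diameter_sd_um,
                 spectral_exponent = spectral_exponent),
            class = "scatterer_spec")
}

#' Acquisition specification
#'
#' @param sample_rate oscilloscope sampling rate in Hz (bookkeeping metadata
#'   for the frequency axis; 10 GHz by default)
#' @param n_samples recording length N in samples
#' @param film_echo_amplitude peak amplitude of the film reflection
#'   (relative units; the dominant component of every recording)
#' @param film_echo_delay sample index (1-based) of the film echo center
#' @param scatterer_delay_offset samples by which the object echo precedes the
#'   film echo
#' @param delay_jitter maximum per-signal jitter (samples) of the object echo
#'   position, emulating trapping-position variability
#' @param noise_sd standard deviation of additive Gaussian noise, in the same
#'   relative units as `film_echo_amplitude`
#' @return object of class `acquisition_spec`
#' @export
acquisition_spec <- function(sample_rate = 10e9, n_samples = 10000,
                             film_echo_amplitude = 1,
                             film_echo_delay = round(0.6 * n_samples),
                             scatterer_delay_offset = round(0.15 * n_samples),
                             delay_jitter = 16, noise_sd = 0.05) {
  if (n_samples <= 0) stop("n_samples must be > 0")
  if (film_echo_delay < 1 || film_echo_delay > n_samples)
    stop("film_echo_delay must lie inside the recording")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (delay_jitter < 0) stop("delay_jitter must be >= 0")
  structure(list(sample_rate = sample_rate, n_samples = as.integer(n_samples),
                 film_echo_amplitude = film_echo_amplitude,
                 film_echo_delay = as.integer(film_echo_delay),
                 scatterer_delay_offset = as.integer(scatterer_delay_offset),
                 delay_jitter = as.integer(delay_jitter),
                 noise_sd = noise_sd), class = "acquisition_spec")
}

#' Generate a monocycle bipolar pulse waveform
#'
#' A sinusoid at the center frequency under a Gaussian envelope whose width is
#' set by the fractional bandwidth; the resulting waveform is zero-mean,
#' bipolar, and its magnitude-spectrum peak sits at the center frequency.
#'
#' @param pulse a [pulse_spec()]
#' @param sample_rate sampling rate in Hz; must be at least 4x the center
#'   frequency
#' @param amplitude peak amplitude scale
#' @return numeric vector (odd length, centered on the pulse)
#' @export
make_monocycle_pulse <- function(pulse, sample_rate, amplitude = 1) {
  stopifnot(inherits(pulse, "pulse_spec"))
  fc <- pulse$center_frequency
  if (sample_rate < 4 * fc)
    stop(sprintf(paste0("sample_rate (%.3g Hz) violates the Nyquist margin: ",
                        "at least 4 x center_frequency (%.3g Hz) required"),
                 sample_rate, 4 * fc))
  # -6 dB half width of a Gaussian magnitude envelope: sigma_f * sqrt(2 ln 2)
  sigma_f <- pulse$fractional_bandwidth * fc / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half_dur <- max(0.5 / fc, 4 * sigma_t)
  nh <- ceiling(half_dur * sample_rate)
  t <- (-nh:nh) / sample_rate
  p <- sin(2 * pi * fc * t) * exp(-t^2 / (2 * sigma_t^2))
  p <- p - mean(p)                     # enforce exact zero mean
  mx <- max(abs(p))
  if (mx > 0) p <- p / mx
  p * amplitude
}

# add waveform w centered at index `center` of a length-n vector, clipping at
# the boundaries
add_centered <- function(x, w, center) {
  half <- (length(w) - 1L) %/% 2L
  lo <- center - half; hi <- center + half
  src <- seq_along(w)
  keep <- lo:hi >= 1L & lo:hi <= length(x)
  idx <- (lo:hi)[keep]
  x[idx] <- x[idx] + w[src[keep]]
  x
}

# diameter- and material-dependent shaping of the scatterer echo: the pulse is
# low-pass filtered with a Gaussian-family response whose cutoff decreases with
# diameter (larger objects return relatively more low-frequency energy)
shape_scatterer_pulse <- function(p, fc, sample_rate, diameter_um,
                                  spectral_exponent, d_ref_um) {
  np <- length(p)
  f <- (seq_len(np) - 1) / np * sample_rate
  f <- pmin(f, sample_rate - f)        # two-sided |frequency| axis
  f_cut <- 2 * fc * d_ref_um / diameter_um
  H <- exp(-0.5 * (f / f_cut)^spectral_exponent)
  Re(stats::fft(stats::fft(p) * H, inverse = TRUE)) / np
}

#' Synthesize one backscattered recording
#'
#' The noise-free reference is the film reflection (the excitation pulse scaled
#' by `film_echo_amplitude` at `film_echo_delay`) plus the object echo placed
#' `scatterer_delay_offset` samples earlier (shifted by `jitter`). The object
#' echo amplitude is `acoustic_contrast * scatter_amp * (d / d_ref_um)^gamma`
#' and its spectrum is low-pass shaped with a cutoff decreasing in diameter.
#' The recorded samples add i.i.d. Gaussian noise of standard deviation
#' `noise_sd` (drawn from the current RNG state unless `seed` is given).
#'
#' @param scatterer a [scatterer_spec()]
#' @param acq an [acquisition_spec()]
#' @param pulse a [pulse_spec()]
#' @param diameter_um realized diameter; defaults to the scatterer mean
#' @param jitter per-signal shift (samples) of the object echo position
#' @param d_ref_um reference diameter of the amplitude law
#' @param gamma exponent of the amplitude-vs-diameter power law
#' @param scatter_amp echo amplitude of the reference object at unit contrast
#' @param seed optional seed (local to this call) for the noise draw
#' @return object of class `echo_signal` with `samples`, `clean_samples`,
#'   `diameter_um`
#' @export
synthesize_echo <- function(scatterer, acq, pulse,
                            diameter_um = scatterer$diameter_um, jitter = 0,
                            d_ref_um = 10, gamma = 1.5, scatter_amp = 0.25,
                            seed = NULL) {
  stopifnot(inherits(scatterer, "scatterer_spec"),
            inherits(acq, "acquisition_spec"), inherits(pulse, "pulse_spec"))
  if (diameter_um <= 0) stop("diameter_um must be > 0")
  n <- acq$n_samples
  delay_sc <- acq$film_echo_delay - acq$scatterer_delay_offset + as.integer(jitter)
  if (delay_sc < 1 || delay_sc > n)
    stop("scatterer echo delay (", delay_sc, ") falls outside the recording")
  p <- make_monocycle_pulse(pulse, acq$sample_rate)
  clean <- add_centered(numeric(n), acq$film_echo_amplitude * p,
                        acq$film_echo_delay)
  amp <- scatterer$acoustic_contrast * scatter_amp * (diameter_um / d_ref_um)^gamma
  if (amp > 0) {
    ps <- shape_scatterer_pulse(p, pulse$center_frequency, acq$sample_rate,
                                diameter_um, scatterer$spectral_exponent,
                                d_ref_um)
    if (amp * max(abs(ps)) >= acq$film_echo_amplitude * max(abs(p)))
      stop("scatterer echo would not be smaller than the film reflection; ",
           "reduce acoustic_contrast or scatter_amp")
    clean <- add_centered(clean, amp * ps, delay_sc)
  }
  samples <- with_local_seed(seed,
    clean + stats::rnorm(n, 0, acq$noise_sd))
  structure(list(samples = samples, clean_samples = clean,
                 diameter_um = diameter_um,
                 scatterer_delay = delay_sc, label = NULL),
            class = "echo_signal")
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_per_class` recordings per class. Per-signal diameters come from a
#' normal distribution truncated at zero; per-signal echo positions are
#' jittered uniformly in `[-delay_jitter, delay_jitter]`. Realized diameters
#' are recorded in the metadata for audit. Deterministic under `seed`.
#'
#' @param classes named list of [scatterer_spec()]; names are class labels
#' @param n_per_class recordings per class (the study scale is 77)
#' @param acq an [acquisition_spec()]
#' @param pulse a [pulse_spec()]
#' @param seed integer seed
#' @param dir optional directory: write per-signal text files and a manifest
#' @param positive_label class mapped to 1 downstream
#' @param ... forwarded to [synthesize_echo()] (`d_ref_um`, `gamma`,
#'   `scatter_amp`)
#' @return a [signal_set()] carrying clean reference signals; when `dir` is
#'   given the manifest path is attached as attribute `manifest`
#' @export
generate_labeled_dataset <- function(classes, n_per_class, acq, pulse,
                                     seed = 1L, dir = NULL,
                                     positive_label = NULL, ...) {
  if (length(classes) < 2) stop("at least 2 classes required")
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop("classes must be a named list")
  if (anyDuplicated(names(classes))) stop("duplicate class labels")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  for (cl in classes) stopifnot(inherits(cl, "scatterer_spec"))

  with_local_seed(seed, {
    n_tot <- n_per_class * length(classes)
    sig <- matrix(0, n_tot, acq$n_samples)
    cln <- matrix(0, n_tot, acq$n_samples)
    meta <- vector("list", n_tot)
    r <- 0L
    for (lab in names(classes)) {
      sc <- classes[[lab]]
      for (i in seq_len(n_per_class)) {
        r <- r + 1L
        d <- stats::rnorm(1, sc$diameter_um, sc$diameter_sd_um)
        while (d <= 0) d <- stats::rnorm(1, sc$diameter_um, sc$diameter_sd_um)
        j <- if (acq$delay_jitter > 0)
          sample.int(2L * acq$delay_jitter + 1L, 1L) - acq$delay_jitter - 1L
        else 0L
        e <- synthesize_echo(sc, acq, pulse, diameter_um = d, jitter = j, ...)
        sig[r, ] <- e$samples
        cln[r, ] <- e$clean_samples
        meta[[r]] <- data.frame(id = sprintf("%s_%03d", lab, i), label = lab,
                                material = sc$material, diameter_um = d,
                                jitter = j, seed = seed)
      }
    }
    meta <- do.call(rbind, meta)
    set <- signal_set(sig, meta$label, ids = meta$id, meta = meta,
                      positive_label = positive_label, clean = cln)
    if (!is.null(dir)) {
      manifest <- write_dataset(set, dir)
      attr(set, "manifest") <- manifest
    }
    set
  })
}
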