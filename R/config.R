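# Configuration loading and validation for the command-line workflows. The
# defaults are the study's best hyperparameter settings; a config file only
# needs to state deviations from them.

config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "echotype-out",
    simulate = list(
      n_per_class = 77L,
      classes = list(
        RBC = list(diameter_um = 6.57, diameter_sd_um = 0.66,
                   material = "cell", acoustic_contrast = 1,
                   spectral_exponent = 2),
        PNT1A = list(diameter_um = 10.10, diameter_sd_um = 0.88,
                     material = "cell", acoustic_contrast = 2,
                     spectral_exponent = 2)),
      positive_label = "PNT1A"),
    pulse = list(center_frequency = 200e6, fractional_bandwidth = 0.9),
    acquisition = list(sample_rate = 10e9, n_samples = 10000L,
                       film_echo_amplitude = 1, film_echo_delay = 6000L,
                       scatterer_delay_offset = 1500L, delay_jitter = 16L,
                       noise_sd = 0.05),
    noise = list(sigma_n = 0.1, copies_per_signal = 10L),
    autoencoder = list(latent_dim = 1250L),
    ae_train = list(epochs = 200L, learning_rate = 0.01, batch_size = 12L,
                    loss = "mae"),
    classifier = list(epochs = 50L, learning_rate = 0.001, batch_size = 15L),
    features = list(stft_window = 32L, stft_step = 16L,
                    resolution = NULL, resolution_method = "decimate"),
    evaluation = list(k = 3L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults) && !(path == "simulate.classes"))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[key] <- user[key]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("config error: ", msg)
  chk(cfg$simulate$n_per_class >= 1, "simulate.n_per_class must be >= 1")
  chk(length(cfg$simulate$classes) >= 2, "simulate.classes needs >= 2 classes")
  chk(cfg$ae_train$epochs >= 1, "ae_train.epochs must be >= 1")
  chk(cfg$ae_train$learning_rate > 0, "ae_train.learning_rate must be > 0")
  chk(cfg$classifier$epochs >= 1, "classifier.epochs must be >= 1")
  chk(cfg$classifier$learning_rate > 0, "classifier.learning_rate must be > 0")
  chk(cfg$noise$sigma_n >= 0, "noise.sigma_n must be >= 0")
  chk(cfg$noise$copies_per_signal >= 0, "noise.copies_per_signal must be >= 0")
  chk(cfg$acquisition$n_samples > 0, "acquisition.n_samples must be > 0")
  chk(cfg$evaluation$k >= 2, "evaluation.k must be >= 2")
  chk(cfg$features$stft_window >= 2, "features.stft_window must be >= 2")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON; JSON is a YAML subset) configuration, fills every
#' omitted key from the documented defaults — the study's best
#' hyperparameters — validates the result and rejects unknown keys. An empty
#' or missing file yields the all-defaults configuration.
#'
#' @param path config file path, or `NULL` for pure defaults
#' @return validated configuration list of class `run_config`
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) stop("config must be a mapping")
      cfg <- merge_config(cfg, user)
    }
  }
  structure(validate_config(cfg), class = "run_config")
}

#' Write a resolved configuration snapshot
#' @param cfg a `run_config`
#' @param path destination YAML path
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# build domain objects from a config
config_pulse <- function(cfg)
  pulse_spec(cfg$pulse$center_frequency, cfg$pulse$fractional_bandwidth)

config_acquisition <- function(cfg)
  acquisition_spec(cfg$acquisition$sample_rate, cfg$acquisition$n_samples,
                   cfg$acquisition$film_echo_amplitude,
                   cfg$acquisition$film_echo_delay,
                   cfg$acquisition$scatterer_delay_offset,
                   cfg$acquisition$delay_jitter, cfg$acquisition$noise_sd)

config_classes <- function(cfg) {
  lapply(cfg$simulate$classes, function(cl)
    scatterer_spec(cl$diameter_um, cl$material, cl$acoustic_contrast,
                   cl$diameter_sd_um, cl$spectral_exponent))
}

config_opts <- function(cfg) {
  n <- cfg$acquisition$n_samples
  npad <- as.integer(ceiling(n / 8) * 8)
  latent <- cfg$autoencoder$latent_dim
  list(noise = noise_spec(cfg$noise$sigma_n, cfg$noise$copies_per_signal),
       ae_spec = autoencoder_spec(n, latent_dim = latent),
       ae_train = ae_train_spec(cfg$ae_train$epochs, cfg$ae_train$learning_rate,
                                cfg$ae_train$batch_size, cfg$ae_train$loss),
       tspec = classifier_train_spec(cfg$classifier$epochs,
                                     cfg$classifier$learning_rate,
                                     cfg$classifier$batch_size,
                                     seed = cfg$seed),
       stft = stft_spec(cfg$features$stft_window, cfg$features$stft_step),
       resolution = cfg$features$resolution,
       resolution_method = cfg$features$resolution_method)
}
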