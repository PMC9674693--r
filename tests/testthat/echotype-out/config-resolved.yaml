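seed: 1
output_dir: echotype-out
simulate:
  n_per_class: 77
  classes:
    RBC:
      diameter_um: 6.57
      diameter_sd_um: 0.66
      material: cell
      acoustic_contrast: 1.0
      spectral_exponent: 2.0
    PNT1A:
      diameter_um: 10.1
      diameter_sd_um: 0.88
      material: cell
      acoustic_contrast: 2.0
      spectral_exponent: 2.0
  positive_label: PNT1A
pulse:
  center_frequency: 2.0e+08
  fractional_bandwidth: 0.9
acquisition:
  sample_rate: 1.0e+10
  n_samples: 10000
  film_echo_amplitude: 1.0
  film_echo_delay: 6000
  scatterer_delay_offset: 1500
  delay_jitter: 16
  noise_sd: 0.05
noise:
  sigma_n: 0.1
  copies_per_signal: 10
autoencoder:
  latent_dim: 1250
ae_train:
  epochs: 200
  learning_rate: 0.01
  batch_size: 12
  loss: mae
classifier:
  epochs: 50
  learning_rate: 0.001
  batch_size: 15
features:
  stft_window: 32
  stft_step: 16
  resolution: ~
  resolution_method: decimate
evaluation:
  k: 3
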