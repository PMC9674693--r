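# echotype

Automated cell-type classification from label-free, high-frequency ultrasound
backscatter.

Acoustic tweezers operating above 100 MHz can trap a single micron-sized
object — a red blood cell (RBC, ~6.6 µm), a prostate epithelial cell (PNT1A,
~10 µm), a polystyrene microsphere — and record the ultrasound it scatters
back. Each recording is a 1D trace dominated by the reflection from the Mylar
film supporting the object; the object's own echo is a tiny wavelet arriving
slightly earlier, buried in that reflection and in noise. `echotype` replaces
manual integrated-backscatter post-processing with an automated pipeline for
researchers working with such single-cell acoustic sensing data:

1. **Denoising** — a 1D convolutional denoising autoencoder
   (6 dilated conv layers + 3 max-pools + 2 dense layers encoding to a latent
   vector *Z*, |Z| = 1250 by default; 7 dilated conv layers + 3 upsamplings
   decoding back), trained to reconstruct X from a Gaussian-corrupted
   X̃ = X + n, n ~ N(0, σₙ²), with MAE loss and Adam.
2. **Augmentation** — ten noisy replicas per training signal (σₙ = 0.1
   relative to the per-signal amplitude), an 11× training set.
3. **Representations** — the waveform itself; the magnitude spectrum
   X̂(f) = Σₙ X̂(n)·e^(−i2πfn/N) (right half, ⌊N/2⌋+1 bins); the spectrogram
   (squared-magnitude STFT over Hamming windows, l = 32, d = 16).
4. **Classifiers** — dilated 1D/2D CNNs (7 conv layers, kernel 3, batch norm,
   dropout 0.2, 4 max-pools, 3 dense layers, sigmoid output, binary
   cross-entropy) against linear-SVM, ridge-logistic and 5×100-unit MLP
   baselines.
5. **Evaluation** — stratified 3-fold cross-validation reporting
   A = (|T*∩T|+|(T*∪T)ᶜ|)/|U|, P = |T*∩T|/|T|, R = |T*∩T|/|T*|,
   F₁ = 2PR/(P+R) per fold with mean and sample SD; a Raw/DN/DN+ denoising
   ablation; and a frequency-resolution sweep.

Because raw recordings from such instruments are rarely shareable, the
package also ships a parametric forward model that synthesizes labeled
datasets with the same structure (film reflection + diameter- and
material-dependent object echo + noise), so the entire pipeline is testable
end to end. The neural networks run on a self-contained im2col/BLAS engine
with Rcpp hot loops — no deep-learning framework required.

## Worked example

Synthesize a two-class dataset (77 recordings per class, mimicking the
RBC-vs-PNT1A contrast), then run the denoise → augment → spectrum → 1D-CNN
pipeline under 3-fold cross-validation:

```r
library(echotype)

classes <- list(
  RBC   = scatterer_spec(6.57,  "cell", acoustic_contrast = 1, diameter_sd_um = 0.66),
  PNT1A = scatterer_spec(10.10, "cell", acoustic_contrast = 2, diameter_sd_um = 0.88))
acq <- acquisition_spec(n_samples = 512, film_echo_delay = 300,
                        scatterer_delay_offset = 80, delay_jitter = 4,
                        noise_sd = 0.05)
set <- generate_labeled_dataset(classes, 77, acq, pulse_spec(), seed = 42,
                                positive_label = "PNT1A")

report <- run_cv_experiment(
  set, representation = "spectrum", model_family = "cnn", mode = "DN+",
  k = 3, seed = 42,
  opts = list(noise    = noise_spec(sigma_n = 0.1, copies_per_signal = 10),
              ae_spec  = autoencoder_spec(512, latent_dim = 64),
              ae_train = ae_train_spec(epochs = 80, learning_rate = 0.003),
              tspec    = classifier_train_spec(epochs = 6)))
print(report)
```

```
<experiment_report> spectrum / cnn / DN+, 3-fold (seed 42)
  1-Fold  A 1.00  F1 1.00  P 1.00  R 1.00
  2-Fold  A 1.00  F1 1.00  P 1.00  R 1.00
  3-Fold  A 1.00  F1 1.00  P 1.00  R 1.00
  Avg.    A 1.00  F1 1.00  P 1.00  R 1.00
  S.D.    A 0.00  F1 0.00  P 0.00  R 0.00
```

Each `*-Fold` row is the held-out fold's accuracy, F1, precision and recall
for detecting the positive class (PNT1A); `Avg.`/`S.D.` are the mean and
sample standard deviation across the three folds. At an acoustic-contrast
ratio of 2 the synthetic classes are cleanly separable, so near-perfect
scores are the expected outcome — the informative checks are the ablation
(`run_ablation()`), the permuted-label control (chance accuracy), and the
resolution sweep (`run_resolution_sweep()`).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/echotype.R simulate --config cfg.yaml --out runs/demo
Rscript inst/cli/echotype.R run --out runs/demo --representation spectrum --model cnn
Rscript inst/cli/echotype.R ablate --out runs/demo
```

Defaults (an empty config) are the protocol's best settings: autoencoder
ε = 200, ρ = 0.01, batch 12, |Z| = 1250, σₙ = 0.1; classifiers ρ = 0.001,
batch 15, ε = 50.

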