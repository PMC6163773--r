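# aharTL

Audio-based human activity recognition with transfer-learning data
augmentation for imbalanced corpora.

Everyday activities — brewing coffee, showering, washing dishes — have
characteristic sound, and a microphone plus a generative classifier can
recognize them. The practical obstacle is imbalance: real corpora routinely
pair a 400-clip class with a 15-clip class, and models of the data-poor
classes are under-trained. `aharTL` implements a feature-space
transfer-learning remedy around a conventional HMM recognizer:

1. **Multidomain frame features.** 30 ms Hamming frames at 10 ms hop,
   512-point FFT; per frame, MFCCs with velocities (26 dims), MPEG-7
   spectrum centroid/spread/flatness descriptors (30 dims at 16 kHz), and
   perceptual wavelet-packet features over Bark bands via a 3-level Haar
   transform (22 dims) — usable singly or concatenated, normalized by
   training-fold statistics: `F' = (F − μ)/σ`.
2. **Statistical proximity.** Each class's frames are modeled by a
   16-component diagonal GMM; the distance between classes is the
   symmetrized Monte Carlo Kullback–Leibler divergence
   `KL(M‖N) + KL(N‖M)`, each direction estimated as
   `(1/ω) Σ log[p_M(x_i)/p_N(x_i)]` with `ω = 2000` draws `x_i ~ M`. For
   every data-poor class `C_l`, the closest data-richer class `C_d` is its
   donor.
3. **Reservoir-network transfer.** An echo state network
   `x(k) = tanh(W_in u(k) + W_res x(k−1))`, `y(k) = W_out' x(k)` learns a
   MIMO map from donor frames to the limited class's feature space; only
   the readout is trained, by ridge regression
   `W_out = (X'X + εI)⁻¹X'D`, with hyperparameters (spectral radius,
   reservoir size, input scaling) chosen by exhaustive search on held-out
   reconstruction error. Donor training clips pushed through the learned
   map become synthetic limited-class training material.
4. **Recognition.** Either class-specific left–right HMMs with GMM
   emissions (Baum–Welch), or a universal ergodic HMM trained on all
   classes with per-class MAP adaptation of emission weights and means
   (relevance factor 16). Clips are scored by length-normalized forward
   log-likelihood; four system variants (cHMM, cHMM-TL, uHMM, uHMM-TL) are
   compared under stratified cross-validation with confusion-matrix
   reporting and a programmatic no-leakage audit.

A deterministic synthetic-corpus generator (band-limited noise + harmonic
stacks with realistic per-clip variability and strong class imbalance)
makes every stage testable without any external data.

## Worked example

```r
library(aharTL)

# an imbalanced 8-class corpus (199 clips, 2 s each), generated in memory
corpus <- generate_corpus(default_test_recipes(duration_s = 2), seed = 42)
feats  <- lapply(corpus$clips, extract_features, feature_set = "mfcc")

cfg <- experiment_config(systems = c("chmm", "chmm_tl"),
                         repetitions = 1, seed = 1)
rep <- run_experiment(feats, cfg)
rep
#> <evaluation_report>
#>   chmm     average recognition rate 83.4%
#>   chmm_tl  average recognition rate 86.1%

rep$pairings[[1]]$pairings$use_oven
#> <transfer_pairing: use_oven <- cooking (divergence 62.633)>
```

The report says: with plain class-specific HMMs the unweighted mean of
per-class recalls is 83.4%; after the transfer module augments the
data-poor classes (e.g. `use_oven`, whose statistically closest
data-richer class here is `cooking`), the same recognizer reaches 86.1%.
`rep$confusion$chmm_tl` holds the row-normalized confusion matrix (%), and
`report_files(rep, "results/")` writes confusion matrices, predictions and
a config echo to disk.

Lower-level entry points mirror the pipeline stages: `extract_features()`,
`fit_gmm()` / `symmetrized_divergence()` / `closest_class()`,
`learn_transfer()` / `apply_transfer()` / `augment_class()`,
`train_class_hmm()` / `train_universal_hmm()` / `adapt_universal()` /
`classify()`. A thin command-line front end lives at `inst/cli/ahar`
(`synth`, `extract`, `pair`, `augment`, `train`, `classify`, `run`
subcommands; `run` also accepts a YAML config file).

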