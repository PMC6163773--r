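#' Recipe for one synthetic activity class
#'
#' Activity-like audio is emulated as band-limited noise plus an optional
#' harmonic stack, under slow random amplitude modulation. Per-clip jitter
#' of gain, band edges and fundamental gives the within-class variability
#' a recognizer must generalize over.
#'
#' @param class_id Class label.
#' @param n_clips Number of clips to generate.
#' @param duration_s Clip duration in seconds.
#' @param noise_band `c(lo, hi)` band-pass edges in Hz for the noise bed.
#' @param noise_gain Linear gain of the noise bed.
#' @param f0 Fundamental of the harmonic stack in Hz, or `NULL` for none.
#' @param n_harmonics Number of harmonics.
#' @param harmonic_gain Linear gain of the harmonic stack.
#' @param am_rate Amplitude-modulation rate in Hz.
#' @param am_depth Modulation depth in `[0, 1)`.
#' @param gain_jitter_db Per-clip overall gain jitter, +/- dB.
#' @param f0_jitter Per-clip relative jitter of `f0`.
#' @param band_jitter Per-clip relative jitter of the noise band edges.
#' @param noise_floor Broadband background-noise floor relative to signal
#'   RMS (linear; jittered by +/- 50% per clip), emulating heterogeneous
#'   recording hardware and rooms.
#' @return A `class_recipe`.
#' @export
class_recipe <- function(class_id, n_clips, duration_s = 10,
                         noise_band = c(200, 4000), noise_gain = 1,
                         f0 = NULL, n_harmonics = 4L, harmonic_gain = 0.5,
                         am_rate = 1, am_depth = 0.3,
                         gain_jitter_db = 6, f0_jitter = 0.12,
                         band_jitter = 0.25, noise_floor = 0.1) {
  nyq <- CANONICAL_RATE / 2
  if (any(noise_band <= 0) || any(noise_band >= nyq) ||
      noise_band[1] >= noise_band[2]) {
    stop("noise_band must satisfy 0 < lo < hi < Nyquist (", nyq, " Hz)")
  }
  if (!is.null(f0) && f0 * n_harmonics >= nyq) {
    stop("harmonic stack exceeds Nyquist: f0 * n_harmonics must be < ", nyq)
  }
  if (n_clips < 0) stop("n_clips must be >= 0")
  structure(
    list(class_id = class_id, n_clips = as.integer(n_clips),
         duration_s = duration_s, noise_band = noise_band,
         noise_gain = noise_gain, f0 = f0, n_harmonics = as.integer(n_harmonics),
         harmonic_gain = harmonic_gain, am_rate = am_rate, am_depth = am_depth,
         gain_jitter_db = gain_jitter_db, f0_jitter = f0_jitter,
         band_jitter = band_jitter, noise_floor = noise_floor),
    class = "class_recipe"
  )
}

# Band-pass filter a signal in the frequency domain (brick wall with a
# raised-cosine skirt one bin wide per 100 Hz of edge).
fft_bandpass <- function(x, lo, hi, sr = CANONICAL_RATE) {
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * sr / n
  af <- abs(f)
  skirt <- pmax(20, 0.05 * (hi - lo))
  gain <- pmin(1, pmax(0, (af - (lo - skirt)) / skirt)) *
    pmin(1, pmax(0, ((hi + skirt) - af) / skirt))
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# Render one clip from a recipe under already-set RNG state.
render_clip <- function(recipe, sr = CANONICAL_RATE) {
  n <- round(recipe$duration_s * sr)
  t <- (seq_len(n) - 1) / sr
  bj <- 1 + stats::runif(2, -recipe$band_jitter, recipe$band_jitter)
  lo <- max(10, recipe$noise_band[1] * bj[1])
  hi <- min(sr / 2 - 10, recipe$noise_band[2] * bj[2])
  if (lo >= hi) { lo <- recipe$noise_band[1]; hi <- recipe$noise_band[2] }
  x <- recipe$noise_gain * fft_bandpass(stats::rnorm(n), lo, hi, sr)
  if (!is.null(recipe$f0)) {
    f0 <- recipe$f0 * (1 + stats::runif(1, -recipe$f0_jitter, recipe$f0_jitter))
    stack <- 0
    for (h in seq_len(recipe$n_harmonics)) {
      stack <- stack + sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi)) / h
    }
    x <- x + recipe$harmonic_gain * stack / 2
  }
  am <- 1 + recipe$am_depth * sin(2 * pi * recipe$am_rate * t +
                                    stats::runif(1, 0, 2 * pi))
  x <- x * am
  floor_lvl <- recipe$noise_floor * stats::runif(1, 0.5, 1.5)
  x <- x + floor_lvl * stats::sd(x) * stats::rnorm(n)
  x <- x * 10^(stats::runif(1, -recipe$gain_jitter_db, recipe$gain_jitter_db) / 20)
  x <- x / max(1e-12, stats::sd(x)) * 0.1          # nominal RMS
  peak <- max(abs(x))
  if (peak > 0.99) x <- x * 0.99 / peak            # no clipping
  x
}

#' Generate a synthetic labeled corpus
#'
#' Deterministic given `seed`. Returns in-memory clips plus a manifest;
#' optionally writes 16-bit WAV files and a tab-separated manifest to
#' `dir`.
#'
#' @param recipes List of [class_recipe()] objects (at least 2).
#' @param seed Integer seed.
#' @param dir Output directory for WAVs + `manifest.tsv`, or `NULL` to
#'   keep everything in memory.
#' @return List with `clips` (list of [audio_clip()]; absent when `dir`
#'   is given), `manifest` (data frame: clip_id, path, label, recipe
#'   index, clip seed index).
#' @export
generate_corpus <- function(recipes, seed = 1L, dir = NULL) {
  if (length(recipes) < 2) stop("need at least 2 recipes")
  local_seed(seed)
  clips <- list()
  rows <- list()
  k <- 0L
  for (ri in seq_along(recipes)) {
    r <- recipes[[ri]]
    if (r$n_clips == 0L) next
    for (ci in seq_len(r$n_clips)) {
      k <- k + 1L
      id <- sprintf("%s_%03d", r$class_id, ci)
      x <- render_clip(r)
      path <- if (is.null(dir)) NA_character_ else
        file.path(dir, paste0(id, ".wav"))
      clips[[k]] <- audio_clip(x, CANONICAL_RATE, label = r$class_id,
                               clip_id = id)
      rows[[k]] <- data.frame(clip_id = id, path = path, label = r$class_id,
                              recipe = ri, index = ci,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(clips)) {
      write_wav(clips[[i]]$samples, CANONICAL_RATE, manifest$path[i])
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    return(list(manifest = manifest, dir = dir))
  }
  list(clips = clips, manifest = manifest)
}

#' Linked donor/limited class pair with known ground truth
#'
#' The limited class is defined as a stated signal-level transformation of
#' independent draws from the donor process, so the true feature-space
#' relationship is known and learnable.
#'
#' @param donor_recipe A [class_recipe()] for the donor class.
#' @param limited_id Label for the limited class.
#' @param transform `"identity"`, `"tilt"` (affine spectral tilt with
#'   slope `magnitude` across the band, in linear gain per Nyquist), or
#'   `"shift"` (spectral shift upward by `magnitude` Hz).
#' @param magnitude Transformation strength.
#' @return A `linked_class_pair`.
#' @export
linked_class_pair <- function(donor_recipe, limited_id = "limited",
                              transform = c("identity", "tilt", "shift"),
                              magnitude = 0) {
  transform <- match.arg(transform)
  structure(
    list(donor = donor_recipe, limited_id = limited_id,
         transform = transform, magnitude = magnitude),
    class = "linked_class_pair"
  )
}

apply_signal_transform <- function(x, transform, magnitude,
                                   sr = CANONICAL_RATE) {
  if (transform == "identity" || magnitude == 0) return(x)
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  f <- c(seq(0, half), seq(-ceiling(n / 2) + 1, -1)) * sr / n
  if (transform == "tilt") {
    gain <- pmax(0.05, 1 + magnitude * (abs(f) / (sr / 2) - 0.5))
    X <- X * gain
  } else {                                  # spectral shift by +magnitude Hz
    bins <- round(magnitude / (sr / n))
    pos <- X[seq_len(half + 1)]
    shifted <- c(rep(0 + 0i, bins), pos)[seq_len(half + 1)]
    X <- c(shifted, Conj(rev(shifted[2:(n - half)])))
    X <- X[seq_len(n)]
  }
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  peak <- max(abs(y))
  if (peak > 0.99) y <- y * 0.99 / peak
  y
}

#' Generate a donor/limited corpus subset from a linked pair
#'
#' Donor clips are fresh draws from the donor recipe; limited clips are
#' the stated transformation applied to further *independent* donor-process
#' draws.
#'
#' @param pair A [linked_class_pair()].
#' @param n_donor,n_limited Clip counts.
#' @param seed Integer seed.
#' @return List with `donor` and `limited` (lists of [audio_clip()]), and
#'   `truth` (the pair definition).
#' @export
generate_linked_pair <- function(pair, n_donor = 20L, n_limited = 5L,
                                 seed = 1L) {
  local_seed(seed)
  donor <- lapply(seq_len(n_donor), function(i) {
    audio_clip(render_clip(pair$donor), CANONICAL_RATE,
               label = pair$donor$class_id,
               clip_id = sprintf("%s_%03d", pair$donor$class_id, i))
  })
  limited <- lapply(seq_len(n_limited), function(i) {
    x <- render_clip(pair$donor)
    audio_clip(apply_signal_transform(x, pair$transform, pair$magnitude),
               CANONICAL_RATE, label = pair$limited_id,
               clip_id = sprintf("%s_%03d", pair$limited_id, i))
  })
  list(donor = donor, limited = limited, truth = pair)
}

#' Sample labeled sequences from known left-right HMM generators
#'
#' Builds `n_classes` random left-right HMM generators with Gaussian
#' emissions whose state means are `separation` apart between classes,
#' samples labeled sequences from them, and returns the generators for
#' parameter-recovery tests.
#'
#' @param n_classes Number of classes.
#' @param n_states States per generator.
#' @param separation Distance scale between class mean layouts.
#' @param n_seq Sequences per class.
#' @param len Frames per sequence.
#' @param dim Feature dimensionality.
#' @param emission_sd Emission standard deviation.
#' @param seed Integer seed.
#' @return List with `sequences` (labeled [feature_seq()] list) and
#'   `generators` (list of `activity_hmm`).
#' @export
generate_hmm_dataset <- function(n_classes = 4L, n_states = 3L,
                                 separation = 4, n_seq = 20L, len = 50L,
                                 dim = 2L, emission_sd = 0.7, seed = 1L) {
  stopifnot(separation > 0)
  local_seed(seed)
  gens <- lapply(seq_len(n_classes), function(ci) {
    base <- stats::rnorm(dim) * separation
    em <- lapply(seq_len(n_states), function(s) {
      list(weights = 1,
           means = matrix(base + stats::rnorm(dim, sd = separation / 4), 1),
           variances = matrix(rep(emission_sd^2, dim), 1))
    })
    A <- diag(0.85, n_states)
    for (s in seq_len(n_states - 1)) A[s, s + 1] <- 0.15
    A[n_states, n_states] <- 1
    activity_hmm(A, c(1, rep(0, n_states - 1)), em, "left_right",
                 label = paste0("class", ci))
  })
  sequences <- list()
  k <- 0L
  for (ci in seq_len(n_classes)) {
    for (j in seq_len(n_seq)) {
      k <- k + 1L
      sequences[[k]] <- feature_seq(
        sample_activity_hmm(gens[[ci]], len), "synthetic_hmm",
        clip_id = sprintf("class%d_%03d", ci, j),
        label = paste0("class", ci))
    }
  }
  list(sequences = sequences, generators = gens)
}

#' Sample one observation sequence from an activity HMM
#'
#' @param model An [activity_hmm()].
#' @param len Number of frames.
#' @return `len x K` matrix.
#' @export
sample_activity_hmm <- function(model, len) {
  S <- model$n_states
  K <- ncol(model$emissions[[1]]$means)
  X <- matrix(0, len, K)
  s <- sample.int(S, 1, prob = model$pi_)
  for (t in seq_len(len)) {
    e <- model$emissions[[s]]
    c_ <- sample.int(length(e$weights), 1, prob = e$weights)
    X[t, ] <- stats::rnorm(K, e$means[c_, ], sqrt(e$variances[c_, ]))
    if (t < len) s <- sample.int(S, 1, prob = model$A[s, ])
  }
  X
}

#' Scaled-down eight-activity test corpus recipes
#'
#' Eight spectrally distinct activity-like classes in four
#' donor/limited-style neighbourhoods, with the strong class imbalance of
#' a realistic activity corpus (counts 40, 25, 10, 4, 60, 25, 15, 20).
#' Clips default to 3 s so end-to-end experiments run at desk scale.
#'
#' @param duration_s Clip duration in seconds.
#' @param counts Clips per class, length 8.
#' @return List of eight [class_recipe()] objects.
#' @export
default_test_recipes <- function(duration_s = 3,
                                 counts = c(40, 25, 10, 4, 60, 25, 15, 20)) {
  stopifnot(length(counts) == 8)
  list(
    class_recipe("brew_coffee", counts[1], duration_s,
                 noise_band = c(300, 2500), f0 = 250, n_harmonics = 3,
                 harmonic_gain = 0.4, am_rate = 1.2),
    class_recipe("cooking", counts[2], duration_s,
                 noise_band = c(400, 3500), f0 = 120, n_harmonics = 4,
                 harmonic_gain = 0.5, am_rate = 2.5),
    class_recipe("use_oven", counts[3], duration_s,
                 noise_band = c(600, 3800), f0 = 150, n_harmonics = 4,
                 harmonic_gain = 0.5, am_rate = 2.0),
    class_recipe("no_activity", counts[4], duration_s,
                 noise_band = c(100, 1200), noise_gain = 0.6, am_rate = 0.5,
                 am_depth = 0.15),
    class_recipe("shower", counts[5], duration_s,
                 noise_band = c(200, 6000), am_rate = 0.8, am_depth = 0.2),
    class_recipe("dish_washing", counts[6], duration_s,
                 noise_band = c(350, 2800), f0 = 300, n_harmonics = 2,
                 harmonic_gain = 0.3, am_rate = 3.0),
    class_recipe("hand_washing", counts[7], duration_s,
                 noise_band = c(150, 1500), noise_gain = 0.7, am_rate = 1.5,
                 am_depth = 0.25),
    class_recipe("teeth_brushing", counts[8], duration_s,
                 noise_band = c(500, 6500), am_rate = 4.0, am_depth = 0.4)
  )
}
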