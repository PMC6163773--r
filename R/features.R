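#' Per-frame feature sequence
#'
#' The currency between all pipeline stages: a `T x K` matrix of per-frame
#' features tagged with its feature set, clip id and label.
#'
#' @param values `T x K` numeric matrix, no non-finite entries.
#' @param feature_set One of `"mfcc"`, `"mpeg7"`, `"pwp"`, `"all"`.
#' @param clip_id Clip identifier.
#' @param label Class label or `NULL`.
#' @param synthetic Logical; `TRUE` for sequences produced by the transfer
#'   module rather than extracted from audio.
#' @param provenance Optional list recording how a synthetic sequence was made.
#' @return A `feature_seq` object.
#' @export
feature_seq <- function(values, feature_set, clip_id = "clip", label = NULL,
                        synthetic = FALSE, provenance = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("feature matrix contains non-finite entries")
  structure(
    list(values = values, feature_set = feature_set, clip_id = clip_id,
         label = label, synthetic = synthetic, provenance = provenance),
    class = "feature_seq"
  )
}

#' @export
print.feature_seq <- function(x, ...) {
  cat(sprintf("<feature_seq %s: %d frames x %d dims [%s]%s label=%s>\n",
              x$clip_id, nrow(x$values), ncol(x$values), x$feature_set,
              if (isTRUE(x$synthetic)) " synthetic" else "",
              if (is.null(x$label)) "none" else x$label))
  invisible(x)
}

# ---- MFCC ------------------------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filter bank, n_filters x n_bins, rows sum-normalized by shape.
mel_filterbank <- function(n_filters, fft_size, sample_rate) {
  nb <- fft_size %/% 2L + 1L
  f_bins <- (0:(nb - 1L)) * sample_rate / fft_size
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                         length.out = n_filters + 2L))
  fb <- matrix(0, n_filters, nb)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; mid <- edges[i + 1L]; hi <- edges[i + 2L]
    up <- (f_bins - lo) / (mid - lo)
    down <- (hi - f_bins) / (hi - mid)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix, n_keep x n_in.
dct2_matrix <- function(n_keep, n_in) {
  j <- 0:(n_in - 1L)
  m <- vapply(0:(n_keep - 1L),
              function(i) cos(pi * i * (2 * j + 1) / (2 * n_in)),
              numeric(n_in))
  m <- t(m) * sqrt(2 / n_in)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

# Delta (velocity) coefficients: linear-regression slope over a +/- w window,
# edge frames replicated.
delta_features <- function(x, w = 2L) {
  T_ <- nrow(x)
  pad <- rbind(x[rep(1L, w), , drop = FALSE], x,
               x[rep(T_, w), , drop = FALSE])
  num <- 0
  for (n in seq_len(w)) {
    num <- num + n * (pad[(w + n) + seq_len(T_), , drop = FALSE] -
                        pad[(w - n) + seq_len(T_), , drop = FALSE])
  }
  num / (2 * sum(seq_len(w)^2))
}

#' Mel-frequency cepstral coefficients with velocities
#'
#' 26 triangular mel filters spanning 0 Hz to Nyquist, log compression with a
#' `1e-10` floor, orthonormal DCT-II keeping coefficients 0..12 (the first is
#' the energy-bearing term), plus their 13 delta (velocity) coefficients:
#' 26 dimensions per frame.
#'
#' @param frames Windowed frame matrix from [frame_signal()].
#' @param grid The [frame_grid()] used to produce `frames`.
#' @param clip_id,label Passed through to the [feature_seq()].
#' @return A `feature_seq` with `feature_set = "mfcc"` and `K = 26`.
#' @export
extract_mfcc <- function(frames, grid = attr(frames, "grid"),
                         clip_id = "clip", label = NULL) {
  P <- frame_power_spectrum(frames, grid)          # bins x T
  fb <- mel_filterbank(26L, grid$fft_size, grid$sample_rate)
  E <- log(pmax(fb %*% P, 1e-10))                  # 26 x T
  C <- dct2_matrix(13L, 26L) %*% E                 # 13 x T
  static <- t(C)
  feature_seq(cbind(static, delta_features(static)), "mfcc",
              clip_id = clip_id, label = label)
}

# ---- MPEG-7 low-level descriptors ------------------------------------------

# 1/4-octave flatness band edges: lower edge 62.5 Hz, widened by 10% on each
# side (overlapping bands), capped at Nyquist.
asf_band_edges <- function(sample_rate) {
  nyq <- sample_rate / 2
  k <- 0L
  lo <- hi <- numeric(0)
  repeat {
    lo_k <- 62.5 * 2^(k / 4)
    hi_k <- 62.5 * 2^((k + 1) / 4)
    if (hi_k > nyq + 1e-9) break
    lo <- c(lo, lo_k * 0.95)
    hi <- c(hi, hi_k * 1.05)
    k <- k + 1L
  }
  cbind(lo = lo, hi = pmin(hi, nyq))
}

#' MPEG-7 spectral descriptors: centroid, spread, flatness
#'
#' Audio Spectrum Centroid: centre of gravity of the power spectrum on a
#' log-frequency (octaves re 1 kHz) axis, with all power below 62.5 Hz
#' collapsed into a single coefficient at 31.25 Hz so a DC component cannot
#' dominate. Audio Spectrum Spread: RMS deviation of the log-frequency
#' spectrum from the centroid. Audio Spectrum Flatness: per 1/4-octave band
#' (lower edge 62.5 Hz, 10% edge overlap, up to Nyquist), the ratio of the
#' geometric to the arithmetic mean of band power. Power is floored at
#' `1e-12` so silent frames yield defined values rather than NaN.
#'
#' @inheritParams extract_mfcc
#' @return A `feature_seq` with `feature_set = "mpeg7"` and
#'   `K = 2 + n_flatness_bands(grid$sample_rate)`.
#' @export
extract_mpeg7 <- function(frames, grid = attr(frames, "grid"),
                          clip_id = "clip", label = NULL) {
  P <- pmax(frame_power_spectrum(frames, grid), 1e-12)   # bins x T
  f_bins <- (0:(nrow(P) - 1L)) * grid$sample_rate / grid$fft_size

  low <- f_bins < 62.5
  P_low <- colSums(P[low, , drop = FALSE])
  P_hi <- P[!low, , drop = FALSE]
  f_eff <- c(31.25, f_bins[!low])
  Pc <- rbind(P_low, P_hi)
  lf <- log2(f_eff / 1000)

  tot <- colSums(Pc)
  centroid <- colSums(Pc * lf) / tot
  spread <- sqrt(colSums(Pc * outer(lf, centroid, `-`)^2) / tot)

  bands <- asf_band_edges(grid$sample_rate)
  flat <- matrix(0, nrow(bands), ncol(P))
  for (b in seq_len(nrow(bands))) {
    sel <- which(f_bins >= bands[b, "lo"] & f_bins <= bands[b, "hi"])
    if (length(sel) == 0L) {
      # band narrower than one bin: use the bin nearest the band centre
      sel <- which.min(abs(f_bins - sqrt(bands[b, "lo"] * bands[b, "hi"])))
    }
    Pb <- P[sel, , drop = FALSE]
    flat[b, ] <- exp(colMeans(log(Pb))) / colMeans(Pb)
  }
  vals <- cbind(centroid, spread, t(flat))
  colnames(vals) <- c("centroid", "spread", paste0("flat", seq_len(nrow(bands))))
  feature_seq(vals, "mpeg7", clip_id = clip_id, label = label)
}

#' Number of 1/4-octave flatness bands at a given rate
#' @param sample_rate Rate in Hz.
#' @return Integer band count (28 at 16 kHz).
#' @export
n_flatness_bands <- function(sample_rate = CANONICAL_RATE) {
  nrow(asf_band_edges(sample_rate))
}

# ---- Perceptual wavelet packets --------------------------------------------

# Bark critical-band edges capped at Nyquist.
bark_band_edges <- function(sample_rate) {
  edges <- c(0, 100, 200, 300, 400, 510, 630, 770, 920, 1080, 1270, 1480,
             1720, 2000, 2320, 2700, 3150, 3700, 4400, 5300, 6400, 7700,
             9500, 12000, 15500)
  nyq <- sample_rate / 2
  edges <- edges[edges < nyq]
  c(edges, nyq)
}

#' Number of Bark critical bands at a given rate
#' @param sample_rate Rate in Hz.
#' @return Integer band count (22 at 16 kHz).
#' @export
n_bark_bands <- function(sample_rate = CANONICAL_RATE) {
  length(bark_band_edges(sample_rate)) - 1L
}

# Full 3-level Haar wavelet packet transform as a linear operator:
# returns the (2^3-padded) transform matrix applied to a length-n input.
haar_wpt3_matrix <- function(n) {
  n_pad <- 8L * ceiling(n / 8L)
  W <- diag(n_pad)
  step <- function(M) {
    half <- nrow(M) / 2L
    ev <- M[seq(1, nrow(M), by = 2L), , drop = FALSE]
    od <- M[seq(2, nrow(M), by = 2L), , drop = FALSE]
    rbind((ev + od) / sqrt(2), (ev - od) / sqrt(2))
  }
  blocks <- list(W)
  for (lev in 1:3) {
    blocks <- unlist(lapply(blocks, function(B) {
      S <- step(B)
      half <- nrow(S) / 2L
      list(S[seq_len(half), , drop = FALSE],
           S[half + seq_len(half), , drop = FALSE])
    }), recursive = FALSE)
  }
  M <- do.call(rbind, blocks)
  M[, seq_len(n), drop = FALSE]
}

#' Perceptual wavelet-packet features
#'
#' The magnitude spectrum of each frame is partitioned into Bark critical
#' bands; within each band a full three-level Haar wavelet packet transform
#' is applied, and the frame's feature for that band is the area under the
#' magnitude envelope of the biased autocorrelation of the packet
#' coefficients, normalized by 50% of the frame length. One scalar per
#' critical band per frame.
#'
#' @inheritParams extract_mfcc
#' @return A `feature_seq` with `feature_set = "pwp"` and
#'   `K = n_bark_bands(grid$sample_rate)`.
#' @export
extract_pwp <- function(frames, grid = attr(frames, "grid"),
                        clip_id = "clip", label = NULL) {
  A <- sqrt(frame_power_spectrum(frames, grid))     # magnitude, bins x T
  f_bins <- (0:(nrow(A) - 1L)) * grid$sample_rate / grid$fft_size
  edges <- bark_band_edges(grid$sample_rate)
  nb <- length(edges) - 1L
  T_ <- ncol(A)
  out <- matrix(0, T_, nb)
  half_frame <- grid$frame_length / 2
  for (b in seq_len(nb)) {
    sel <- f_bins >= edges[b] & f_bins < edges[b + 1L]
    if (b == nb) sel <- f_bins >= edges[b] & f_bins <= edges[b + 1L]
    Wm <- haar_wpt3_matrix(sum(sel))
    coefs <- Wm %*% A[sel, , drop = FALSE]          # n_pad x T
    n_pad <- nrow(coefs)
    # biased autocorrelation of each column via FFT
    z <- rbind(coefs, matrix(0, n_pad, T_))
    S <- Mod(stats::mvfft(z))^2
    ac <- Re(stats::mvfft(S, inverse = TRUE)) / nrow(z) / n_pad
    out[, b] <- colSums(abs(ac[seq_len(n_pad), , drop = FALSE])) / half_frame
  }
  colnames(out) <- paste0("pwp", seq_len(nb))
  feature_seq(out, "pwp", clip_id = clip_id, label = label)
}

# ---- combined extraction ---------------------------------------------------

#' Extract a feature sequence from an audio clip
#'
#' Front door of the features module: frames the clip and extracts the
#' requested feature set, or the concatenation of all three.
#'
#' @param clip An [audio_clip()].
#' @param feature_set `"mfcc"`, `"mpeg7"`, `"pwp"` or `"all"` (concatenation).
#' @param grid A [frame_grid()].
#' @return A [feature_seq()].
#' @export
extract_features <- function(clip, feature_set = c("all", "mfcc", "mpeg7", "pwp"),
                             grid = frame_grid()) {
  feature_set <- match.arg(feature_set)
  frames <- frame_signal(clip, grid)
  parts <- switch(feature_set,
    mfcc  = list(extract_mfcc(frames, grid)),
    mpeg7 = list(extract_mpeg7(frames, grid)),
    pwp   = list(extract_pwp(frames, grid)),
    all   = list(extract_mfcc(frames, grid), extract_mpeg7(frames, grid),
                 extract_pwp(frames, grid))
  )
  vals <- do.call(cbind, lapply(parts, `[[`, "values"))
  feature_seq(vals, feature_set, clip_id = clip$clip_id, label = clip$label)
}

# ---- normalization ---------------------------------------------------------

#' Fit a mean/variance normalizer on training sequences
#'
#' Pools the frames of the supplied (training-fold) sequences and records
#' per-dimension mean and standard deviation. Dimensions with (near) zero
#' variance get a floored sigma and a warning.
#'
#' @param training List of [feature_seq()] objects sharing one feature set.
#' @param sd_floor Lower bound on sigma.
#' @return A `feature_normalizer` with fields `mean`, `sd`, `feature_set`.
#' @export
fit_normalizer <- function(training, sd_floor = 1e-8) {
  stopifnot(length(training) > 0)
  sets <- unique(vapply(training, `[[`, "", "feature_set"))
  if (length(sets) != 1L) stop("mixed feature sets in training pool: ",
                               paste(sets, collapse = ", "))
  X <- do.call(rbind, lapply(training, `[[`, "values"))
  mu <- colMeans(X)
  # population sd, so the normalized pool has unit variance by definition
  sd_ <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  if (any(sd_ < sd_floor)) {
    warning(sum(sd_ < sd_floor), " zero-variance feature dimension(s); sigma floored")
    sd_ <- pmax(sd_, sd_floor)
  }
  structure(list(mean = mu, sd = sd_, feature_set = sets),
            class = "feature_normalizer")
}

#' Apply a fitted normalizer to a feature sequence
#'
#' @param norm A [fit_normalizer()] result.
#' @param fs A [feature_seq()].
#' @return The sequence with `values` replaced by `(values - mean) / sd`.
#' @export
apply_normalizer <- function(norm, fs) {
  stopifnot(inherits(norm, "feature_normalizer"), inherits(fs, "feature_seq"))
  if (ncol(fs$values) != length(norm$mean)) {
    stop("dimensionality mismatch between normalizer and sequence")
  }
  fs$values <- sweep(sweep(fs$values, 2L, norm$mean), 2L, norm$sd, `/`)
  fs
}
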