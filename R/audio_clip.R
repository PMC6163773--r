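#' Canonical pipeline sample rate (Hz)
#'
#' All audio is resampled to this rate on ingestion so that frame grids,
#' filter banks and band layouts are fixed across a corpus. 16 kHz covers
#' the bandwidth relevant to domestic activity sounds while keeping a
#' 512-point FFT at a useful resolution (31.25 Hz per bin).
#' @export
CANONICAL_RATE <- 16000L

#' Construct an audio clip
#'
#' The raw input unit of the pipeline: a mono waveform at the canonical
#' sample rate plus an optional class label. Clips at other rates are
#' resampled with a polyphase filter on construction.
#'
#' @param samples Numeric waveform, values in `[-1, 1]`.
#' @param sample_rate Native rate of `samples` in Hz.
#' @param label Class label (character) or `NULL` for unlabeled clips.
#' @param clip_id Identifier string.
#' @return An object of class `audio_clip` with fields `samples`,
#'   `sample_rate` (always [CANONICAL_RATE]), `label`, `clip_id`.
#' @export
audio_clip <- function(samples, sample_rate = CANONICAL_RATE, label = NULL,
                       clip_id = "clip") {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  if (sample_rate != CANONICAL_RATE) {
    samples <- signal::resample(samples, p = CANONICAL_RATE, q = sample_rate)
    sample_rate <- CANONICAL_RATE
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = as.integer(sample_rate),
         label = label, clip_id = clip_id),
    class = "audio_clip"
  )
}

#' Read a WAV file as an audio clip
#'
#' @param path WAV path.
#' @inheritParams audio_clip
#' @return An [audio_clip()].
#' @export
read_clip <- function(path, label = NULL, clip_id = NULL) {
  w <- read_wav(path)
  if (is.null(clip_id)) clip_id <- sub("\\.wav$", "", basename(path))
  audio_clip(w$samples, w$sample_rate, label = label, clip_id = clip_id)
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip %s: %.2f s @ %d Hz, label=%s>\n", x$clip_id,
              length(x$samples) / x$sample_rate, x$sample_rate,
              if (is.null(x$label)) "none" else x$label))
  invisible(x)
}

#' Analysis frame grid
#'
#' Fixes the short-time analysis geometry: 30 ms Hamming-tapered frames
#' advancing in 10 ms steps (20 ms overlap) and a 512-point FFT.
#'
#' @param frame_ms Frame length in milliseconds.
#' @param hop_ms Frame step in milliseconds.
#' @param fft_size FFT length in samples; must be at least the frame length.
#' @param sample_rate Rate the grid is expressed at.
#' @return A `frame_grid` object with sample-domain `frame_length`, `hop`,
#'   `fft_size`, `window` (the Hamming taper) and `sample_rate`.
#' @export
frame_grid <- function(frame_ms = 30, hop_ms = 10, fft_size = 512L,
                       sample_rate = CANONICAL_RATE) {
  frame_length <- as.integer(round(frame_ms * sample_rate / 1000))
  hop <- as.integer(round(hop_ms * sample_rate / 1000))
  stopifnot(hop > 0, hop <= frame_length, fft_size >= frame_length)
  structure(
    list(frame_length = frame_length, hop = hop, fft_size = as.integer(fft_size),
         window = as.numeric(signal::hamming(frame_length)),
         sample_rate = as.integer(sample_rate)),
    class = "frame_grid"
  )
}

#' Cut a clip into windowed analysis frames
#'
#' @param clip An [audio_clip()].
#' @param grid A [frame_grid()].
#' @return A `T x frame_length` matrix of Hamming-windowed frames with the
#'   grid attached as attribute `grid`. `T = 1 + floor((len - frame_length)/hop)`.
#' @export
frame_signal <- function(clip, grid = frame_grid()) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else as.numeric(clip)
  fl <- grid$frame_length
  if (length(x) < fl) {
    stop(sprintf("clip shorter than one frame: need >= %d samples (%.0f ms), got %d",
                 fl, 1000 * fl / grid$sample_rate, length(x)))
  }
  n_frames <- 1L + (length(x) - fl) %/% grid$hop
  starts <- (seq_len(n_frames) - 1L) * grid$hop
  idx <- outer(starts, seq_len(fl), `+`)       # T x fl sample indices
  frames <- matrix(x[idx], nrow = n_frames)
  frames <- sweep(frames, 2L, grid$window, `*`)
  attr(frames, "grid") <- grid
  frames
}

# Power spectrum of windowed frames: (fft_size/2 + 1) x T, bins 0..Nyquist.
frame_power_spectrum <- function(frames, grid) {
  nb <- grid$fft_size %/% 2L + 1L
  padded <- matrix(0, nrow = grid$fft_size, ncol = nrow(frames))
  padded[seq_len(ncol(frames)), ] <- t(frames)
  X <- stats::mvfft(padded)[seq_len(nb), , drop = FALSE]
  Mod(X)^2
}
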