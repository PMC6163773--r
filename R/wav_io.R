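#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader covering the encodings the toolchain emits:
#' integer PCM (8/16/24/32 bit) and IEEE float32. Multichannel input is
#' mixed down to mono by averaging channels; samples are returned in
#' `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in `[-1, 1]`) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate     = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip, chunks are word-aligned
      next
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n, size = 1, signed = FALSE)) - 128) / 128,
    "16" = pmax(-1, as.numeric(readBin(data_raw, "integer", n, size = 2,
                                       endian = "little")) / 32767),
    "24" = {
      m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = if (fmt$format == 3L) {
      as.numeric(readBin(data_raw, "double", n, size = 4, endian = "little"))
    } else {
      as.numeric(readBin(data_raw, "integer", n, size = 4, endian = "little")) / 2147483648
    },
    stop("unsupported bit depth: ", fmt$bits)
  )
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  list(samples = x, sample_rate = fmt$rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  x <- pmin(pmax(samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
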