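#' Construct an audio signal
#'
#' The canonical container every DSP stage consumes and produces: a numeric
#' sample vector (dimensionless amplitudes, nominally in \[-1, 1\]) plus a
#' sample rate in Hz.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate positive integer, Hz.
#' @return An object of class `audio_signal` with fields `samples` and
#'   `sample_rate`.
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    abort_input("audio_signal: samples must be a non-empty numeric vector")
  sample_rate <- as.integer(sample_rate)
  if (is.na(sample_rate) || sample_rate <= 0L)
    abort_param("audio_signal: sample_rate must be a positive integer")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_signal")
}

#' Duration of an audio signal in seconds
#' @param sig an `audio_signal`.
#' @return length(samples) / sample_rate, seconds.
#' @export
duration_s <- function(sig) length(sig$samples) / sig$sample_rate

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %d Hz (%.3f s), peak %.4f>\n",
              length(x$samples), x$sample_rate, duration_s(x),
              max(abs(x$samples))))
  invisible(x)
}

#' Read a WAV file
#'
#' Parses RIFF/WAVE directly (PCM16, PCM32 and IEEE-float dialects).
#' Multi-channel audio is averaged to mono; integer PCM is rescaled to
#' \[-1, 1\] by the type's full scale.
#'
#' @param path path to a WAV file.
#' @return mono `audio_signal` at the file's native rate.
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    abort_input(sprintf("read_wav: file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    abort_format(sprintf("read_wav: not a RIFF/WAVE file: %s", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little")
      )
      if (fmt$audio_format == 65534L && sz >= 40L) { # WAVE_FORMAT_EXTENSIBLE
        fmt$audio_format <- readBin(body[25:26], "integer", 1L, 2L,
                                    signed = FALSE, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2L) # skip (chunks are word-aligned)
      next
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
    if (sz %% 2L == 1L) readBin(con, "raw", 1L)
  }
  if (is.null(fmt) || is.null(data_raw))
    abort_format(sprintf("read_wav: missing fmt/data chunk in %s", path))

  x <- switch(
    as.character(fmt$audio_format),
    "1" = { # integer PCM
      if (fmt$bits == 16L)
        readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                signed = TRUE, endian = "little") / 32768
      else if (fmt$bits == 32L)
        readBin(data_raw, "integer", length(data_raw) %/% 4L, size = 4L,
                endian = "little") / 2147483648
      else abort_format(sprintf("read_wav: unsupported PCM bit depth %d in %s",
                                fmt$bits, path))
    },
    "3" = { # IEEE float
      readBin(data_raw, "double", length(data_raw) %/% (fmt$bits %/% 8L),
              size = fmt$bits %/% 8L, endian = "little")
    },
    abort_format(sprintf("read_wav: unsupported WAV format code %d in %s",
                         fmt$audio_format, path))
  )

  nch <- fmt$n_channels
  if (nch > 1L) {
    n <- length(x) %/% nch
    x <- colMeans(matrix(x[seq_len(n * nch)], nrow = nch))
  }
  if (length(x) == 0L)
    abort_format(sprintf("read_wav: empty data chunk in %s", path))
  audio_signal(x, fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param sig an `audio_signal`.
#' @param path output path.
#' @param format `"float32"` (default, written by the pipeline) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(sig, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- sig$samples
  con <- file(path, "wb")
  on.exit(close(con))

  if (format == "float32") {
    fmt_code <- 3L; bits <- 32L
  } else {
    fmt_code <- 1L; bits <- 16L
  }
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per
  byte_rate <- sig$sample_rate * bytes_per

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(as.integer(sig$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")  # block align
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (format == "float32") {
    writeBin(x, con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(pmax(pmin(round(x * 32767), 32767), -32768)),
             con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Resample an audio signal (band-limited, Fourier method)
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling), preserving all content below the new Nyquist
#' frequency exactly.
#'
#' @param sig an `audio_signal`.
#' @param target_rate positive integer, Hz.
#' @return `audio_signal` at `target_rate`; duration preserved within one
#'   sample period.
#' @export
resample <- function(sig, target_rate) {
  target_rate <- as.integer(target_rate)
  if (is.na(target_rate) || target_rate <= 0L)
    abort_param("resample: target_rate must be positive")
  if (target_rate == sig$sample_rate) return(sig)

  x <- sig$samples
  n <- length(x)
  m <- max(1L, as.integer(round(n * target_rate / sig$sample_rate)))
  X <- stats::fft(x)
  Y <- complex(m)
  kmax <- min((n - 1L) %/% 2L, (m - 1L) %/% 2L)
  Y[1L] <- X[1L]
  if (kmax >= 1L) {
    ks <- seq_len(kmax)
    Y[1L + ks] <- X[1L + ks]
    Y[m + 1L - ks] <- X[n + 1L - ks]
  }
  if (m < n && m %% 2L == 0L) {
    # new Nyquist bin: fold the +/- contributions of the old spectrum
    Y[m %/% 2L + 1L] <- Re(X[m %/% 2L + 1L])
  }
  if (m > n && n %% 2L == 0L) {
    # split the old Nyquist bin symmetrically
    half <- X[n %/% 2L + 1L] / 2
    Y[n %/% 2L + 1L] <- half
    Y[m - n %/% 2L + 1L] <- Conj(half)
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  audio_signal(y, target_rate)
}
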