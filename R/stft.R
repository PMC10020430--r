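# Short-time Fourier transform core shared by preprocess and prosodic.
# Package-wide geometry: 25 ms Hann frames, 10 ms hop at the canonical
# 16 kHz rate (frame 400, hop 160 samples).

CANONICAL_RATE <- 16000L
FRAME_MS <- 25
HOP_MS <- 10

frame_samples <- function(sample_rate, frame_ms = FRAME_MS) {
  as.integer(round(sample_rate * frame_ms / 1000))
}
hop_samples <- function(sample_rate, hop_ms = HOP_MS) {
  as.integer(round(sample_rate * hop_ms / 1000))
}

hann_window <- function(n) {
  # periodic Hann, as used for STFT analysis
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

n_frames_for <- function(n, frame_length, hop_length) {
  if (n < frame_length) return(0L)
  1L + (n - frame_length) %/% hop_length
}

# samples -> frame matrix (frame_length x n_frames), no padding
frame_signal <- function(x, frame_length, hop_length) {
  nf <- n_frames_for(length(x), frame_length, hop_length)
  if (nf == 0L)
    abort_input("signal shorter than one analysis frame")
  idx <- outer(seq_len(frame_length), hop_length * (seq_len(nf) - 1L), "+")
  matrix(x[idx], nrow = frame_length)
}

# complex STFT, positive-frequency half (frame_length/2 + 1 bins)
stft <- function(x, frame_length, hop_length, window = hann_window(frame_length)) {
  fr <- frame_signal(x, frame_length, hop_length) * window
  S <- stats::mvfft(fr)
  S[seq_len(frame_length %/% 2L + 1L), , drop = FALSE]
}

# inverse STFT by weighted overlap-add; exact where the squared-window
# overlap sum is positive (interior of the signal)
istft <- function(S, frame_length, hop_length, n_out,
                  window = hann_window(frame_length)) {
  nb <- nrow(S)
  nf <- ncol(S)
  full <- matrix(0i, nrow = frame_length, ncol = nf)
  full[seq_len(nb), ] <- S
  if (frame_length > 2L) {
    mir <- seq(2L, frame_length - nb + 1L)
    full[seq(frame_length, nb + 1L), ] <- Conj(S[mir, , drop = FALSE])
  }
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / frame_length
  frames <- frames * window

  # vectorized overlap-add: split each frame into hop-length chunks and
  # accumulate whole chunk rows at shifted column offsets
  n_chunks <- as.integer(ceiling(frame_length / hop_length))
  pad_rows <- n_chunks * hop_length - frame_length
  if (pad_rows > 0L) {
    frames <- rbind(frames, matrix(0, pad_rows, nf))
    w2 <- c(window^2, numeric(pad_rows))
  } else w2 <- window^2
  acc <- matrix(0, hop_length, nf + n_chunks - 1L)
  wacc <- matrix(0, hop_length, nf + n_chunks - 1L)
  for (ch in seq_len(n_chunks)) {
    rows <- (ch - 1L) * hop_length + seq_len(hop_length)
    cols <- (ch - 1L) + seq_len(nf)
    acc[, cols] <- acc[, cols] + frames[rows, , drop = FALSE]
    wacc[, cols] <- wacc[, cols] + w2[rows]
  }
  total_len <- frame_length + hop_length * (nf - 1L)
  y <- as.vector(acc)[seq_len(total_len)]
  wsum <- as.vector(wacc)[seq_len(total_len)]
  ok <- wsum > 1e-12
  y[ok] <- y[ok] / wsum[ok]
  length(y) <- min(length(y), n_out)
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  y
}
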