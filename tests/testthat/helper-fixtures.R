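# Shared fixtures, all built in code at test time.

tone_signal <- function(freq, dur_s = 1, sr = 16000L, amp = 1) {
  audio_signal(amp * sin(2 * pi * freq * seq_len(dur_s * sr) / sr), sr)
}

# onset-envelope impulse train at a given rate (events/s), frame rate 100 Hz
impulse_envelope <- function(rate_hz, dur_s = 10, frame_rate = 100) {
  n <- round(dur_s * frame_rate)
  e <- numeric(n)
  idx <- round(seq(1, n, by = frame_rate / rate_hz))
  e[idx[idx <= n]] <- 1
  structure(list(values = e, frame_rate = frame_rate), class = "onset_envelope")
}

# minimal interleaved stereo PCM16 WAV, constant per-channel values
write_stereo_wav <- function(path, left, right, sr = 16000L) {
  n <- length(left)
  x <- as.integer(round(rbind(left, right) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * n * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")        # stereo
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(sr * 4L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(as.vector(x), con, size = 2L, endian = "little")
  path
}

make_transcript <- function(text, probs, starts = NULL, durs = 0.3) {
  n <- length(text)
  if (is.null(starts)) starts <- (seq_len(n) - 1) * 0.5
  transcript(data.frame(text = text, start_s = starts,
                        end_s = starts + durs, probability = probs))
}

# linearly separable toy dataset: feature f1 carries the labels
separable_toy <- function(n_per_class = 10, n_classes = 2, p = 3, seed = 1) {
  set.seed(seed)
  y <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  X <- matrix(rnorm(length(y) * p, sd = 0.1), ncol = p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  X[, 1] <- X[, 1] + 3 * y
  list(X = X, y = y)
}

dummy_dataset <- function(n_subjects, labels = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(labels)) labels <- sample(0:5, n_subjects, replace = TRUE)
  sids <- sprintf("D%03d", seq_len(n_subjects))
  X <- matrix(rnorm(n_subjects * 4), n_subjects, 4,
              dimnames = list(sids, paste0("f", 1:4)))
  labeled_dataset(X, data.frame(subject_id = sids, label = labels))
}

quiet_extract <- function(...) suppressMessages(extract_features(...))
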