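# Prosodic features: spectral descriptors of the STFT, rhythm aggregates from
# autocorrelation and Fourier tempograms of the onset envelope, and dedicated
# word/syllable/sub-syllable tempo features from tempogram band peaks.
# 39 features per task recording; 3 tasks -> 117 prosodic features.

TEMPO_MIN_HZ <- 0.25
TEMPO_MAX_HZ <- 30
TEMPOGRAM_WINDOW_S <- 4
TEMPOGRAM_HOP_S <- 0.5

# word / syllable / sub-syllable modulation-rate bands, Hz
TEMPO_BANDS <- list(word = c(0.5, 2), syllable = c(2, 8), subsyllable = c(8, 30))

PROSODIC_FEATURE_NAMES <- c(
  as.vector(t(outer(c("centroid", "bandwidth", "rolloff85", "flatness", "flux", "rms"),
                    c("mean", "sd", "iqr"), paste, sep = "_"))),
  "rms_dynamic_range", "centroid_slope", "flux_p90",
  "mean_rhythmicity", "rhythmicity_cv", "dominant_rate_hz", "dominant_salience",
  "ac_dominant_rate_hz", "ac_dominant_salience", "ac_tempo_entropy", "ac_rate_sd",
  "onset_rate_hz", "onset_strength_mean", "onset_strength_cv",
  "word_tempo_hz", "word_salience", "syllable_tempo_hz", "syllable_salience",
  "subsyllable_tempo_hz", "subsyllable_salience", "pause_ratio"
)

#' Magnitude spectrogram with the package-wide STFT geometry
#'
#' @param sig an `audio_signal` at the canonical rate.
#' @return a `spectrogram`: `magnitudes` (bins x frames), `bin_frequencies`
#'   (Hz), `frame_times` (s), plus the geometry fields.
#' @export
compute_spectrogram <- function(sig) {
  fl <- frame_samples(sig$sample_rate)
  hl <- hop_samples(sig$sample_rate)
  S <- stft(sig$samples, fl, hl)
  nb <- nrow(S)
  structure(list(
    magnitudes = Mod(S),
    bin_frequencies = (seq_len(nb) - 1) * sig$sample_rate / fl,
    frame_times = (hl * (seq_len(ncol(S)) - 1) + fl / 2) / sig$sample_rate,
    sample_rate = sig$sample_rate,
    frame_length = fl,
    hop_length = hl
  ), class = "spectrogram")
}

#' Per-frame spectral descriptors
#'
#' Centroid (magnitude-weighted mean frequency), bandwidth (magnitude-weighted
#' SD around the centroid), 85% rolloff, spectral flatness (geometric /
#' arithmetic mean of power), positive spectral flux (L2), and frame RMS.
#' Frames with zero total magnitude yield centroid 0, flatness 1, others 0.
#'
#' @param spec a `spectrogram`.
#' @return data.frame with one row per frame.
#' @export
spectral_descriptors <- function(spec) {
  mag <- spec$magnitudes
  f <- spec$bin_frequencies
  nf <- ncol(mag)
  if (nf == 0L) abort_input("spectral_descriptors: empty spectrogram")
  tot <- colSums(mag)
  nonzero <- tot > 0

  centroid <- numeric(nf)
  bandwidth <- numeric(nf)
  rolloff85 <- numeric(nf)
  centroid[nonzero] <- colSums(mag[, nonzero, drop = FALSE] * f) / tot[nonzero]
  if (any(nonzero)) {
    dev2 <- (matrix(f, nrow(mag), sum(nonzero)) -
               matrix(centroid[nonzero], nrow(mag), sum(nonzero), byrow = TRUE))^2
    bandwidth[nonzero] <- sqrt(colSums(mag[, nonzero, drop = FALSE] * dev2) / tot[nonzero])
    cs <- apply(mag[, nonzero, drop = FALSE], 2, cumsum)
    hit <- cs >= matrix(0.85 * tot[nonzero], nrow(mag), sum(nonzero), byrow = TRUE)
    rolloff85[nonzero] <- f[apply(hit, 2, which.max)]
  }

  p <- mag^2
  amin <- 1e-10
  flatness <- exp(colMeans(log(pmax(p, amin)))) / colMeans(pmax(p, amin))
  flatness[!nonzero] <- 1

  flux <- c(0, sqrt(colSums(pmax(mag[, -1L, drop = FALSE] -
                                   mag[, -nf, drop = FALSE], 0)^2)))
  if (nf == 1L) flux <- 0

  # RMS of the windowed frame via Parseval on the half spectrum
  nfft <- spec$frame_length
  w <- c(1, rep(2, nrow(mag) - 2L), 1)
  rms <- sqrt(colSums(p * w)) / nfft

  data.frame(centroid = centroid, bandwidth = bandwidth, rolloff85 = rolloff85,
             flatness = flatness, flux = flux, rms = rms)
}

#' Onset strength envelope
#'
#' Half-wave-rectified first difference of `log(1 + magnitude)`, summed over
#' frequency bins; the first value is 0.
#'
#' @param spec a `spectrogram` with at least 2 frames.
#' @return an `onset_envelope`: `values` (>= 0 per frame) and `frame_rate`
#'   (Hz, frames per second).
#' @export
onset_envelope <- function(spec) {
  mag <- spec$magnitudes
  if (ncol(mag) < 2L) abort_input("onset_envelope: need at least 2 frames")
  L <- log1p(mag)
  d <- L[, -1L, drop = FALSE] - L[, -ncol(L), drop = FALSE]
  structure(list(values = c(0, colSums(pmax(d, 0))),
                 frame_rate = spec$sample_rate / spec$hop_length),
            class = "onset_envelope")
}

tempo_window_frames <- function(env, window_s) {
  W <- as.integer(round(window_s * env$frame_rate))
  if (length(env$values) < W)
    abort_input(sprintf(
      "tempogram: envelope has %d frames but the window needs %d; use a shorter window",
      length(env$values), W))
  W
}

#' Fourier tempogram of an onset envelope
#'
#' Magnitude STFT of the onset envelope (Hann window); tempo axis restricted
#' to 0.25-30 Hz.
#'
#' @param env an `onset_envelope`.
#' @param window_s analysis window in seconds (default 4, hop 0.5).
#' @param hop_s hop in seconds.
#' @return a `tempogram` (kind "fourier"): `values` (tempo x time),
#'   `tempo_axis` (Hz, strictly increasing).
#' @export
fourier_tempogram <- function(env, window_s = TEMPOGRAM_WINDOW_S,
                              hop_s = TEMPOGRAM_HOP_S) {
  W <- tempo_window_frames(env, window_s)
  hop <- max(1L, as.integer(round(hop_s * env$frame_rate)))
  fr <- frame_signal(env$values, W, hop) * hann_window(W)
  S <- Mod(stats::mvfft(fr))
  freqs <- (seq_len(W) - 1) * env$frame_rate / W
  keep <- which(freqs >= TEMPO_MIN_HZ & freqs <= TEMPO_MAX_HZ)
  structure(list(kind = "fourier",
                 values = S[keep, , drop = FALSE],
                 tempo_axis = freqs[keep]),
            class = "tempogram")
}

#' Autocorrelation tempogram of an onset envelope
#'
#' Windowed, lag-normalized autocorrelation of the envelope; each lag l maps
#' to tempo `frame_rate / l` (events per second). Same windowing as
#' [fourier_tempogram()].
#'
#' @inheritParams fourier_tempogram
#' @return a `tempogram` (kind "autocorrelation").
#' @export
autocorr_tempogram <- function(env, window_s = TEMPOGRAM_WINDOW_S,
                               hop_s = TEMPOGRAM_HOP_S) {
  W <- tempo_window_frames(env, window_s)
  hop <- max(1L, as.integer(round(hop_s * env$frame_rate)))
  fr <- frame_signal(env$values, W, hop)
  nfft <- 2^ceiling(log2(2L * W))
  padded <- rbind(fr, matrix(0, nfft - W, ncol(fr)))
  A <- Re(stats::mvfft(Mod(stats::mvfft(padded))^2, inverse = TRUE)) / nfft
  lags <- seq_len(W - 1L)
  tempos <- env$frame_rate / lags
  keep <- which(tempos >= TEMPO_MIN_HZ & tempos <= TEMPO_MAX_HZ)
  lags <- lags[keep]
  ac <- A[lags + 1L, , drop = FALSE] / (W - lags)  # lag-normalized
  ord <- order(tempos[keep])                       # tempo axis ascending
  structure(list(kind = "autocorrelation",
                 values = ac[ord, , drop = FALSE],
                 tempo_axis = tempos[keep][ord]),
            class = "tempogram")
}

# Peak picking with explicit tie handling: a perfectly periodic train puts
# (numerically) equal mass on every harmonic of the Fourier tempogram and on
# every period multiple of the autocorrelation. Near-ties (relative 1e-6)
# resolve to the fundamental: the lowest tempo for harmonic stacks, the
# highest tempo (shortest lag) for period multiples.
argmax_tie <- function(v, prefer_low = TRUE, tol = 1e-6) {
  m <- max(v)
  if (m <= 0) return(1L)
  idx <- which(v >= m * (1 - tol))
  if (prefer_low) idx[1L] else idx[length(idx)]
}

cv_or_zero <- function(x) {
  m <- mean(x)
  if (length(x) < 2L || m == 0) 0 else stats::sd(x) / m
}

sd_or_zero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Rhythm aggregates from both tempograms and the envelope
#'
#' Eleven named summary statistics measuring the average and variability of
#' rhythmicity: Fourier-tempogram aggregates (mean and CV of per-window peak
#' strength, dominant rate and its salience), autocorrelation aggregates
#' (dominant rate/salience, tempo entropy, per-window rate SD), and envelope
#' aggregates (onset rate and strength statistics).
#'
#' @param tg_f Fourier `tempogram`.
#' @param tg_ac autocorrelation `tempogram`.
#' @param env the `onset_envelope` both were computed from.
#' @return named numeric of length 11; a zero envelope yields all zeros with
#'   attribute `degenerate = TRUE`.
#' @export
rhythm_aggregates <- function(tg_f, tg_ac, env) {
  out <- stats::setNames(numeric(11), c(
    "mean_rhythmicity", "rhythmicity_cv", "dominant_rate_hz", "dominant_salience",
    "ac_dominant_rate_hz", "ac_dominant_salience", "ac_tempo_entropy", "ac_rate_sd",
    "onset_rate_hz", "onset_strength_mean", "onset_strength_cv"))
  if (all(env$values == 0)) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  pm <- apply(tg_f$values, 2, max)
  out["mean_rhythmicity"] <- mean(pm)
  out["rhythmicity_cv"] <- cv_or_zero(pm)
  avg <- rowMeans(tg_f$values)
  if (any(avg > 0)) {
    out["dominant_rate_hz"] <- tg_f$tempo_axis[argmax_tie(avg)]
    out["dominant_salience"] <- max(avg) / mean(avg)
  }
  avg_ac <- rowMeans(tg_ac$values)
  if (any(avg_ac > 0)) {
    out["ac_dominant_rate_hz"] <- tg_ac$tempo_axis[argmax_tie(avg_ac, prefer_low = FALSE)]
    out["ac_dominant_salience"] <- max(avg_ac) / mean(avg_ac)
    pr <- avg_ac / sum(avg_ac)
    pr <- pr[pr > 0]
    out["ac_tempo_entropy"] <- -sum(pr * log(pr))
    out["ac_rate_sd"] <- sd_or_zero(tg_ac$tempo_axis[
      apply(tg_ac$values, 2, argmax_tie, prefer_low = FALSE)])
  }
  v <- env$values
  p90 <- stats::quantile(v, 0.9, names = FALSE)
  n <- length(v)
  if (n >= 3L) {
    peak <- v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n] &
      v[2:(n - 1)] > 0.5 * p90
    out["onset_rate_hz"] <- sum(peak) / (n / env$frame_rate)
  }
  out["onset_strength_mean"] <- mean(v)
  out["onset_strength_cv"] <- cv_or_zero(v)
  out
}

#' Word / syllable / sub-syllable tempo from tempogram band peaks
#'
#' Averages the Fourier tempogram over time and reports, within each
#' modulation band (word 0.5-2 Hz, syllable 2-8 Hz, sub-syllable 8-30 Hz),
#' the peak tempo (Hz) and its salience (peak / band mean), plus the pause
#' ratio (fraction of envelope frames below 10% of the envelope's P90).
#'
#' @param tg_f Fourier `tempogram`.
#' @param env the `onset_envelope` it was computed from (for pause_ratio).
#' @return named numeric of length 7. Bands with all-zero content report 0.
#' @export
band_tempo_features <- function(tg_f, env) {
  avg <- rowMeans(tg_f$values)
  out <- stats::setNames(numeric(7), c(
    "word_tempo_hz", "word_salience", "syllable_tempo_hz", "syllable_salience",
    "subsyllable_tempo_hz", "subsyllable_salience", "pause_ratio"))
  for (band in names(TEMPO_BANDS)) {
    lim <- TEMPO_BANDS[[band]]
    nm <- if (band == "subsyllable") "subsyllable" else band
    idx <- which(tg_f$tempo_axis >= lim[1] & tg_f$tempo_axis < lim[2] |
                   (band == "subsyllable" & tg_f$tempo_axis == lim[2]))
    if (length(idx) && any(avg[idx] > 0)) {
      out[paste0(nm, "_tempo_hz")] <- tg_f$tempo_axis[idx][argmax_tie(avg[idx])]
      out[paste0(nm, "_salience")] <- max(avg[idx]) / mean(avg[idx])
    }
  }
  p90 <- stats::quantile(env$values, 0.9, names = FALSE)
  out["pause_ratio"] <- mean(env$values < 0.1 * p90)
  if (p90 <= 0) out["pause_ratio"] <- 0
  out
}

#' Full 39-feature prosodic vector for one task recording
#'
#' 21 spectral summaries (6 descriptors x mean/SD/IQR over frames, plus RMS
#' dynamic range, centroid slope and flux P90), 11 rhythm aggregates and 7
#' band tempo features.
#'
#' @param sig a preprocessed `audio_signal` at the canonical rate.
#' @return named numeric of length 39 (names in `PROSODIC_FEATURE_NAMES`);
#'   attribute `degenerate = TRUE` if the onset envelope is all-zero.
#' @export
prosodic_vector <- function(sig) {
  spec <- compute_spectrogram(sig)
  d <- spectral_descriptors(spec)
  env <- onset_envelope(spec)
  tg_f <- fourier_tempogram(env)
  tg_ac <- autocorr_tempogram(env)

  spectral <- unlist(lapply(c("centroid", "bandwidth", "rolloff85",
                              "flatness", "flux", "rms"), function(nm) {
    x <- d[[nm]]
    stats::setNames(
      c(mean(x), sd_or_zero(x), stats::IQR(x, type = 7)),
      paste(nm, c("mean", "sd", "iqr"), sep = "_"))
  }))
  q <- stats::quantile(d$rms, c(0.05, 0.95), names = FALSE)
  tt <- spec$frame_times
  slope <- if (stats::var(tt) > 0)
    stats::cov(tt, d$centroid) / stats::var(tt) else 0
  extra <- c(rms_dynamic_range = q[2] - q[1],
             centroid_slope = slope,
             flux_p90 = stats::quantile(d$flux, 0.9, names = FALSE))

  rhythm <- rhythm_aggregates(tg_f, tg_ac, env)
  band <- band_tempo_features(tg_f, env)

  out <- c(spectral, extra, rhythm, band)[PROSODIC_FEATURE_NAMES]
  names(out) <- PROSODIC_FEATURE_NAMES
  if (isTRUE(attr(rhythm, "degenerate"))) attr(out, "degenerate") <- TRUE
  stopifnot(length(out) == 39L, all(is.finite(out)))
  out
}
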