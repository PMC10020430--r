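#' Peak-normalize a signal's amplitude
#'
#' @param sig an `audio_signal`.
#' @param target_peak target maximum absolute amplitude, in (0, 1].
#' @return rescaled `audio_signal` whose max absolute sample equals
#'   `target_peak`; an all-zero signal is returned unchanged with a warning.
#' @export
normalize_amplitude <- function(sig, target_peak = 0.99) {
  if (!is.numeric(target_peak) || target_peak <= 0 || target_peak > 1)
    abort_param("normalize_amplitude: target_peak must be in (0, 1]")
  peak <- max(abs(sig$samples))
  if (peak == 0) {
    warning("normalize_amplitude: all-zero signal left unchanged")
    return(sig)
  }
  audio_signal(sig$samples * (target_peak / peak), sig$sample_rate)
}

#' Split a recording into speech and voiceless frames
#'
#' Energy-based voice activity detection: frames whose short-time RMS reaches
#' an adaptive threshold are speech. The threshold is the geometric mean of
#' the 10th and 90th percentiles of frame RMS (the P10 is floored at
#' `1e-4 * P90` so digitally silent frames cannot collapse the threshold to
#' zero). If no frame is voiceless, the quietest 10% of frames are marked
#' voiceless as a fallback so a noise profile can always be estimated.
#'
#' @param sig an `audio_signal`.
#' @param frame_length,hop_length analysis geometry in samples (defaults:
#'   package-wide 25 ms / 10 ms at the signal's rate).
#' @return a `voicing_mask`: list with `frame_length`, `hop_length`,
#'   `is_speech` (logical per frame).
#' @export
segment_speech_silence <- function(sig,
                                   frame_length = frame_samples(sig$sample_rate),
                                   hop_length = hop_samples(sig$sample_rate)) {
  if (hop_length <= 0L || frame_length < hop_length)
    abort_param("segment_speech_silence: need frame_length >= hop_length > 0")
  fr <- frame_signal(sig$samples, frame_length, hop_length)
  rms <- sqrt(colMeans(fr^2))
  p <- stats::quantile(rms, c(0.10, 0.90), names = FALSE, type = 7)
  if (p[2] <= 0) {
    is_speech <- rep(FALSE, length(rms))
  } else {
    thr <- sqrt(max(p[1], 1e-4 * p[2]) * p[2])
    is_speech <- rms >= thr
    if (all(is_speech)) {
      # e.g. constant amplitude throughout: force the quietest 10% voiceless
      k <- ceiling(0.1 * length(rms))
      is_speech[order(rms)[seq_len(k)]] <- FALSE
    }
  }
  structure(list(frame_length = as.integer(frame_length),
                 hop_length = as.integer(hop_length),
                 is_speech = is_speech),
            class = "voicing_mask")
}

#' Estimate a noise profile from voiceless frames
#'
#' Per-frequency-bin mean STFT magnitude over the frames the voicing mask
#' marks voiceless.
#'
#' @param sig an `audio_signal`.
#' @param mask a `voicing_mask` computed on `sig` with the same geometry.
#' @return a `noise_profile`: list with `mean_magnitude` (one value per STFT
#'   bin) and `n_frames_used`.
#' @export
estimate_noise <- function(sig, mask) {
  S <- stft(sig$samples, mask$frame_length, mask$hop_length)
  if (ncol(S) != length(mask$is_speech))
    abort_consistency(sprintf(
      "estimate_noise: mask has %d frames but signal implies %d",
      length(mask$is_speech), ncol(S)))
  voiceless <- which(!mask$is_speech)
  if (length(voiceless) == 0L)
    abort_consistency("estimate_noise: mask has no voiceless frames")
  mag <- Mod(S[, voiceless, drop = FALSE])
  structure(list(mean_magnitude = rowMeans(mag),
                 n_frames_used = length(voiceless)),
            class = "noise_profile")
}

#' Spectral-subtraction denoising
#'
#' Subtracts the noise profile's per-bin mean magnitude from every STFT frame
#' with a multiplicative floor: each magnitude m becomes
#' `max(m - noise_bin, floor_frac * m)`. Phase is preserved and the signal is
#' reconstructed by inverse STFT with the same window; output length equals
#' input length.
#'
#' @param sig an `audio_signal`.
#' @param noise a `noise_profile` with one entry per STFT bin.
#' @param floor_frac non-negative spectral floor fraction (default 0.02).
#' @param frame_length,hop_length STFT geometry in samples.
#' @return denoised `audio_signal`.
#' @export
spectral_subtract <- function(sig, noise, floor_frac = 0.02,
                              frame_length = frame_samples(sig$sample_rate),
                              hop_length = hop_samples(sig$sample_rate)) {
  if (floor_frac < 0)
    abort_param("spectral_subtract: floor_frac must be >= 0")
  nb <- frame_length %/% 2L + 1L
  if (length(noise$mean_magnitude) != nb)
    abort_consistency(sprintf(
      "spectral_subtract: noise profile has %d bins, STFT geometry implies %d",
      length(noise$mean_magnitude), nb))

  n <- length(sig$samples)
  # pad so overlap-add reconstruction is exact over the original extent
  lead <- hop_length
  tail_pad <- frame_length
  x <- c(numeric(lead), sig$samples, numeric(tail_pad))
  nf <- n_frames_for(length(x), frame_length, hop_length)
  x <- x[seq_len(frame_length + hop_length * (nf - 1L))]

  S <- stft(x, frame_length, hop_length)
  mag <- Mod(S)
  newmag <- pmax(mag - noise$mean_magnitude, floor_frac * mag)
  ratio <- ifelse(mag > 0, newmag / mag, 0)
  y <- istft(S * ratio, frame_length, hop_length, n_out = length(x))
  audio_signal(y[lead + seq_len(n)], sig$sample_rate)
}
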