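# Severity-parameterized synthetic speech. The generator emulates the three
# recording tasks (free speech, counting 1-10 and back, 10 s PATA repetition)
# as syllable trains whose rate, rhythm regularity, loudness stability,
# signal-to-noise ratio, and word intelligibility degrade monotonically with
# the integer severity label 0-5. It is a test harness for the pipeline, not
# a clinical claim: transcripts (with word probabilities) are generated as
# sidecar files exercising the transcriber contract.

# default label distribution mimicking the clinical cohort's item-4 spread
# (median 2, IQR 1-3)
DEFAULT_LABEL_WEIGHTS <- c(`0` = 0.08, `1` = 0.22, `2` = 0.30,
                           `3` = 0.22, `4` = 0.12, `5` = 0.06)

#' Map a severity label to generator parameters
#'
#' Defaults (all overridable): syllable rate `6.0 * (1 - 0.12 s)` Hz,
#' interval jitter CV `0.03 + 0.06 s`, loudness-spike probability `0.02 s`,
#' SNR `30 - 2 s` dB, mean word probability `max(0.2, 0.95 - 0.12 s)`, pause
#' rate `0.05 s` per second.
#'
#' @param severity integer 0-5.
#' @param overrides named list overriding individual fields.
#' @return a `severity_profile`.
#' @export
severity_profile <- function(severity, overrides = list()) {
  severity <- as.integer(severity)
  if (is.na(severity) || severity < 0L || severity > 5L)
    abort_param("severity_profile: severity must be an integer in 0-5")
  prof <- list(
    severity = severity,
    pata_rate_hz = 6.0 * (1 - 0.12 * severity),
    interval_cv = 0.03 + 0.06 * severity,
    spike_prob = 0.02 * severity,
    snr_db = 30 - 2 * severity,
    word_prob_mean = max(0.2, 0.95 - 0.12 * severity),
    pause_rate = 0.05 * severity
  )
  for (nm in names(overrides)) prof[[nm]] <- overrides[[nm]]
  structure(prof, class = "severity_profile")
}

# one syllable: 30 ms noise burst (consonant) + 120 ms two-formant vowel
synth_syllable <- function(sr, f0 = 120, formants = c(700, 1200),
                           bw = c(110, 170), cons_s = 0.03, vowel_s = 0.12) {
  nc <- round(cons_s * sr)
  burst <- stats::rnorm(nc) * exp(-seq_len(nc) / (0.25 * nc))
  burst <- diff(c(0, burst))  # crude high-pass for a plosive-like burst

  nv <- round(vowel_s * sr)
  t <- seq_len(nv) / sr
  kmax <- floor(4000 / f0)
  amp <- exp(-((seq_len(kmax) * f0 - formants[1]) / bw[1])^2 / 2) +
    0.7 * exp(-((seq_len(kmax) * f0 - formants[2]) / bw[2])^2 / 2) + 0.02
  vowel <- colSums(amp * sin(2 * pi * outer(seq_len(kmax) * f0, t)))
  envl <- sin(pi * seq_len(nv) / nv)^0.7  # attack-decay
  v <- c(burst * 0.8, vowel / max(abs(vowel)) * envl)
  v / max(abs(v))
}

# formant targets give "pa" and "ta" slightly different timbre
SYLLABLE_FORMANTS <- list(pa = c(700, 1100), ta = c(650, 1600),
                          generic = c(600, 1300))

lognormal_intervals <- function(n, mean_interval, cv) {
  if (cv <= 0) return(rep(mean_interval, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean_interval) - sdlog^2 / 2, sdlog = sdlog)
}

add_noise_at_snr <- function(x, snr_db) {
  rms_sig <- sqrt(mean(x^2))
  if (rms_sig == 0) return(x)
  x + stats::rnorm(length(x)) * rms_sig / 10^(snr_db / 20)
}

rbeta_mean <- function(n, mean, concentration = 20) {
  m <- min(max(mean, 0.01), 0.99)
  stats::rbeta(n, m * concentration, (1 - m) * concentration)
}

place_syllables <- function(buf, sr, onsets, kinds, gains) {
  for (i in seq_along(onsets)) {
    syl <- synth_syllable(sr, formants = SYLLABLE_FORMANTS[[kinds[i]]])
    pos <- round(onsets[i] * sr) + 1L
    idx <- pos:min(pos + length(syl) - 1L, length(buf))
    buf[idx] <- buf[idx] + gains[i] * syl[seq_along(idx)]
  }
  buf
}

finalize_audio <- function(buf, sr, snr_db) {
  x <- add_noise_at_snr(buf, snr_db)
  peak <- max(abs(x))
  if (peak > 0) x <- x * (0.9 / peak)
  audio_signal(x, sr)
}

#' Synthesize a PATA syllable-repetition recording
#'
#' Alternating "pa"/"ta" syllables at the profile's mean rate (syllables per
#' second) with log-normal interval jitter, random +6 dB loudness spikes, and
#' additive white noise at the profile's SNR. The sidecar transcript carries
#' one "pata" token per syllable pair with Beta-distributed probabilities.
#'
#' @param profile a `severity_profile`.
#' @param duration_s recording length in seconds (task protocol: 10).
#' @param seed integer seed; output is fully deterministic given the seed.
#' @param sample_rate sample rate, Hz.
#' @return list with `signal` (`audio_signal`) and `transcript`.
#' @export
synth_syllable_train <- function(profile, duration_s = 10, seed = 1L,
                                 sample_rate = CANONICAL_RATE) {
  if (duration_s <= 0) abort_param("synth_syllable_train: duration_s must be > 0")
  set.seed(seed)
  mean_int <- 1 / profile$pata_rate_hz
  n_max <- ceiling(duration_s / mean_int * 2) + 10L
  ints <- lognormal_intervals(n_max, mean_int, profile$interval_cv)
  onsets <- 0.05 + cumsum(c(0, ints))
  onsets <- onsets[onsets < duration_s - 0.16]
  n <- length(onsets)
  kinds <- rep_len(c("pa", "ta"), n)
  gains <- ifelse(stats::runif(n) < profile$spike_prob, 2.0, 1.0) # +6 dB spikes

  buf <- numeric(round(duration_s * sample_rate))
  buf <- place_syllables(buf, sample_rate, onsets, kinds, gains)
  sig <- finalize_audio(buf, sample_rate, profile$snr_db)

  n_pairs <- n %/% 2L
  words <- NULL
  if (n >= 1L) {
    starts <- onsets[seq_len(n_pairs) * 2L - 1L]
    ends <- pmin(onsets[seq_len(n_pairs) * 2L] + 0.16, duration_s)
    text <- rep("pata", n_pairs)
    if (n %% 2L == 1L) {  # odd trailing syllable
      starts <- c(starts, onsets[n])
      ends <- c(ends, pmin(onsets[n] + 0.16, duration_s))
      text <- c(text, "pa")
    }
    words <- data.frame(text = text, start_s = starts, end_s = ends,
                        probability = rbeta_mean(length(text),
                                                 profile$word_prob_mean))
  }
  list(signal = sig, transcript = transcript(words))
}

word_audio_and_span <- function(buf, sr, t0, n_syl, rate_hz, cv) {
  ints <- lognormal_intervals(max(n_syl - 1L, 0L), 1 / rate_hz, cv)
  onsets <- t0 + cumsum(c(0, ints))
  kinds <- rep("generic", n_syl)
  buf <- place_syllables(buf, sr, onsets, kinds, rep(1, n_syl))
  list(buf = buf, end = onsets[n_syl] + 0.16)
}

#' Synthesize a counting recording (one to ten and back)
#'
#' Twenty numeral words rendered as syllable groups with the profile's timing
#' and noise; the transcript enumerates the numerals up then down.
#'
#' @inheritParams synth_syllable_train
#' @return list with `signal` and `transcript` (exactly 20 words).
#' @export
synth_counting <- function(profile, seed = 1L, sample_rate = CANONICAL_RATE) {
  set.seed(seed)
  tokens <- c(GERMAN_NUMERALS, rev(GERMAN_NUMERALS))
  n_syl <- ifelse(tokens == "sieben", 2L, 1L) + (nchar(tokens) > 4L)
  gap <- 0.25 + 0.06 * profile$severity

  total_est <- sum(n_syl) / profile$pata_rate_hz + 20 * (gap + 0.16) + 1
  buf <- numeric(ceiling(total_est * sample_rate))
  t0 <- 0.2
  starts <- ends <- numeric(20)
  for (i in 1:20) {
    starts[i] <- t0
    res <- word_audio_and_span(buf, sample_rate, t0, n_syl[i],
                               profile$pata_rate_hz, profile$interval_cv)
    buf <- res$buf
    ends[i] <- res$end
    t0 <- res$end + gap * stats::runif(1, 0.8, 1.2)
  }
  n_keep <- ceiling((max(ends) + 0.3) * sample_rate)
  sig <- finalize_audio(buf[seq_len(n_keep)], sample_rate, profile$snr_db)
  words <- data.frame(text = tokens, start_s = starts, end_s = ends,
                      probability = rbeta_mean(20, profile$word_prob_mean))
  list(signal = sig, transcript = transcript(words))
}

scramble_nonword <- function(k) {
  paste(sample(c("x", "q", "v", "z", "k", "p", "r"), k + 3L, replace = TRUE),
        collapse = "")
}

#' Synthesize a free-speech recording
#'
#' A stream of 1-4-syllable words drawn from the built-in vocabulary, with a
#' severity-dependent fraction replaced by non-words, pauses inserted at the
#' profile's pause rate, and the profile's timing/noise parameters.
#'
#' @inheritParams synth_syllable_train
#' @param duration_s minimum duration in seconds (task protocol: >= 30).
#' @param nonword_frac fraction of tokens replaced by non-words; default
#'   `min(0.6, 0.08 * severity)`.
#' @return list with `signal` and `transcript`.
#' @export
synth_free_speech <- function(profile, duration_s = 30, seed = 1L,
                              sample_rate = CANONICAL_RATE,
                              nonword_frac = min(0.6, 0.08 * profile$severity)) {
  if (duration_s <= 0) abort_param("synth_free_speech: duration_s must be > 0")
  set.seed(seed)
  buf <- numeric(ceiling((duration_s + 4) * sample_rate))
  t0 <- 0.2
  text <- character(0); starts <- ends <- probs <- numeric(0)
  mean_word_gap <- 0.18 + 0.05 * profile$severity
  while (t0 < duration_s) {
    n_syl <- sample(1:4, 1L, prob = c(0.35, 0.35, 0.2, 0.1))
    tok <- if (stats::runif(1) < nonword_frac) scramble_nonword(n_syl)
           else sample(GERMAN_COMMON_WORDS, 1L)
    if (t0 + (n_syl / profile$pata_rate_hz) + 0.2 > length(buf) / sample_rate)
      break
    res <- word_audio_and_span(buf, sample_rate, t0, n_syl,
                               profile$pata_rate_hz, profile$interval_cv)
    buf <- res$buf
    text <- c(text, tok); starts <- c(starts, t0); ends <- c(ends, res$end)
    probs <- c(probs, rbeta_mean(1, profile$word_prob_mean))
    t0 <- res$end + mean_word_gap * stats::runif(1, 0.7, 1.3)
    # ataxic speech: occasional long pauses, more frequent with severity
    word_cadence <- res$end - starts[length(starts)] + mean_word_gap
    if (stats::runif(1) < profile$pause_rate * word_cadence)
      t0 <- t0 + stats::runif(1, 0.5, 1.2)
  }
  n_keep <- max(ceiling((max(ends) + 0.3) * sample_rate),
                ceiling(duration_s * sample_rate))
  sig <- finalize_audio(buf[seq_len(n_keep)], sample_rate, profile$snr_db)
  words <- data.frame(text = text, start_s = starts, end_s = ends,
                      probability = probs)
  list(signal = sig, transcript = transcript(words))
}

#' Simulate one complete assessment (three task recordings) in memory
#'
#' @param subject_id subject identifier.
#' @param severity integer label 0-5.
#' @param seed integer seed.
#' @param overrides profile overrides (see [severity_profile()]).
#' @param free_duration_s free-speech minimum duration.
#' @return a `synthetic_assessment`: `subject_id`, `severity`, `seed`, and
#'   `tasks` (named list free/count/pata of `signal` + `transcript`).
#' @export
simulate_assessment <- function(subject_id, severity, seed = 1L,
                                overrides = list(), free_duration_s = 30) {
  prof <- severity_profile(severity, overrides)
  tasks <- list(
    free = synth_free_speech(prof, free_duration_s, seed = seed),
    count = synth_counting(prof, seed = seed + 1L),
    pata = synth_syllable_train(prof, 10, seed = seed + 2L)
  )
  structure(list(subject_id = subject_id, severity = as.integer(severity),
                 seed = as.integer(seed), tasks = tasks),
            class = "synthetic_assessment")
}

draw_labels <- function(n, weights = DEFAULT_LABEL_WEIGHTS, one_per_label = FALSE) {
  if (one_per_label) {
    if (n %% 6L != 0L)
      abort_param("draw_labels: one_per_label mode needs n divisible by 6")
    return(rep(0:5, n / 6L))
  }
  sample(0:5, n, replace = TRUE, prob = weights)
}

#' Simulate a severity-labeled cohort in memory
#'
#' Draws labels from the default severity distribution, assigns per-subject
#' seeds, and simulates every assessment. [generate_cohort()] is this plus
#' serialization to disk.
#'
#' @inheritParams generate_cohort
#' @return list with `assessments` (list of `synthetic_assessment`) and
#'   `labels` (data.frame subject_id, label).
#' @export
simulate_cohort <- function(n_subjects, seed = 1L,
                            label_weights = DEFAULT_LABEL_WEIGHTS,
                            one_per_label = FALSE, overrides = list(),
                            free_duration_s = 30) {
  set.seed(seed)
  labels <- draw_labels(n_subjects, label_weights, one_per_label)
  subject_seeds <- sample.int(2^30, n_subjects)
  sids <- sprintf("S%03d", seq_len(n_subjects))
  assessments <- lapply(seq_len(n_subjects), function(i)
    simulate_assessment(sids[i], labels[i], subject_seeds[i], overrides,
                        free_duration_s))
  list(assessments = assessments,
       labels = data.frame(subject_id = sids, label = labels))
}

#' Generate a severity-labeled synthetic cohort on disk
#'
#' Writes, per subject, `<out_dir>/<subject>/<task>.wav` plus
#' `<task>.transcript.json`, a `manifest.tsv` (subject_id, task, wav_path,
#' transcript_path) and `labels.tsv` (subject_id, label). Fully deterministic
#' given the seed.
#'
#' @param n_subjects cohort size.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param label_weights distribution over labels 0-5 (default mimics the
#'   clinical cohort: median 2, IQR 1-3).
#' @param one_per_label if TRUE, assign labels 0-5 in rotation instead of
#'   sampling (n must be a multiple of 6).
#' @param overrides severity-profile overrides.
#' @param free_duration_s free-speech minimum duration.
#' @return the manifest data.frame, invisibly.
#' @export
generate_cohort <- function(n_subjects, out_dir, seed = 1L,
                            label_weights = DEFAULT_LABEL_WEIGHTS,
                            one_per_label = FALSE, overrides = list(),
                            free_duration_s = 30) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort_input(sprintf("generate_cohort: cannot create output dir %s", out_dir))
  cohort <- simulate_cohort(n_subjects, seed, label_weights, one_per_label,
                            overrides, free_duration_s)

  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    a <- cohort$assessments[[i]]
    sid <- a$subject_id
    sdir <- file.path(out_dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    paths <- lapply(names(a$tasks), function(task) {
      wav <- file.path(sdir, paste0(task, ".wav"))
      tjson <- file.path(sdir, paste0(task, ".transcript.json"))
      write_wav(a$tasks[[task]]$signal, wav)
      write_transcript(a$tasks[[task]]$transcript, tjson)
      data.frame(subject_id = sid, task = task, wav_path = wav,
                 transcript_path = tjson)
    })
    rows[[i]] <- do.call(rbind, paths)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$labels, file.path(out_dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
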