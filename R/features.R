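# End-to-end feature extraction: preprocess each task recording, compute the
# 39 prosodic + 8 lexical features per task, and assemble the named
# 141-dimensional vector per assessment.

TASKS <- c("free", "count", "pata")

#' Names of the 141 features (117 prosodic + 24 lexical)
#'
#' Columns are `<task>__<feature>` for tasks free, count, pata.
#'
#' @return character vector of length 141.
#' @export
feature_names <- function() {
  unlist(lapply(TASKS, function(task)
    paste(task, c(PROSODIC_FEATURE_NAMES, LEXICAL_FEATURE_NAMES), sep = "__")),
    use.names = FALSE)
}

#' Preprocess one recording
#'
#' Resample to the canonical 16 kHz, peak-normalize, estimate a noise profile
#' from VAD-voiceless frames, spectrally subtract it, and re-normalize.
#'
#' @param sig an `audio_signal`.
#' @param target_peak peak for amplitude normalization.
#' @param floor_frac spectral-subtraction floor fraction.
#' @return preprocessed `audio_signal` at 16 kHz.
#' @export
preprocess_signal <- function(sig, target_peak = 0.99, floor_frac = 0.02) {
  sig <- resample(sig, CANONICAL_RATE)
  sig <- normalize_amplitude(sig, target_peak)
  mask <- segment_speech_silence(sig)
  noise <- estimate_noise(sig, mask)
  sig <- spectral_subtract(sig, noise, floor_frac)
  if (max(abs(sig$samples)) > 0) sig <- normalize_amplitude(sig, target_peak)
  sig
}

#' Extract the 47 per-task features for one recording
#'
#' @param sig raw `audio_signal` for the task.
#' @param t the task's `transcript`.
#' @param wl a `word_list`.
#' @param ... passed to [preprocess_signal()].
#' @return named numeric of length 47 (39 prosodic + 8 lexical).
#' @export
extract_task_features <- function(sig, t, wl = default_word_list(), ...) {
  pre <- preprocess_signal(sig, ...)
  c(prosodic_vector(pre), word_stats(t, wl, duration_s(pre)))
}

#' Extract the 141-feature vector for one assessment
#'
#' @param assessment a `synthetic_assessment` (or any list with `$tasks`
#'   holding free/count/pata `signal` + `transcript` pairs).
#' @param wl a `word_list`.
#' @return named numeric of length 141.
#' @export
extract_assessment_features <- function(assessment, wl = default_word_list()) {
  out <- unlist(lapply(TASKS, function(task) {
    tk <- assessment$tasks[[task]]
    if (is.null(tk)) abort_input(sprintf("assessment lacks task '%s'", task))
    v <- extract_task_features(tk$signal, tk$transcript, wl)
    stats::setNames(v, paste(task, names(v), sep = "__"))
  }))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract features for every assessment in a manifest
#'
#' The manifest (one row per subject x task) must reference readable WAVs;
#' subjects missing any of the three tasks are skipped with a logged reason,
#' mirroring the exclusion of incomplete recording sets.
#'
#' @param manifest data.frame with columns subject_id, task, wav_path (and
#'   transcript_path for the mock transcriber), or path of a manifest TSV.
#' @param transcriber a transcriber for [transcribe()] (default
#'   [mock_transcriber()]).
#' @param wl a `word_list`.
#' @param quiet suppress per-subject progress messages.
#' @return data.frame: `subject_id` + 141 feature columns.
#' @export
extract_features <- function(manifest, transcriber = mock_transcriber(),
                             wl = default_word_list(), quiet = FALSE) {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      abort_input(sprintf("extract_features: manifest not found: %s", manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  if (NROW(manifest) == 0L)
    abort_input("extract_features: empty manifest")

  rows <- list()
  for (sid in unique(manifest$subject_id)) {
    sub <- manifest[manifest$subject_id == sid, , drop = FALSE]
    if (!all(TASKS %in% sub$task)) {
      message(sprintf("extract_features: skipping %s (incomplete set: has %s)",
                      sid, paste(sub$task, collapse = ",")))
      next
    }
    vec <- unlist(lapply(TASKS, function(task) {
      row <- sub[sub$task == task, , drop = FALSE][1, ]
      sig <- read_wav(row$wav_path)
      t <- transcribe(transcriber, row$wav_path)
      v <- extract_task_features(sig, t, wl)
      stats::setNames(v, paste(task, names(v), sep = "__"))
    }))
    rows[[sid]] <- vec
    if (!quiet) message(sprintf("extract_features: %s done", sid))
  }
  if (length(rows) == 0L)
    abort_input("extract_features: no complete assessment in manifest")
  X <- do.call(rbind, rows)
  data.frame(subject_id = names(rows), X, check.names = FALSE,
             row.names = NULL)
}

#' Extract features for in-memory assessments
#'
#' @param assessments list of `synthetic_assessment` objects.
#' @param wl a `word_list`.
#' @return a `labeled_dataset` ready for [run_experiment()].
#' @export
extract_cohort_features <- function(assessments, wl = default_word_list()) {
  X <- t(vapply(assessments, extract_assessment_features,
                numeric(141), wl = wl))
  rownames(X) <- vapply(assessments, `[[`, character(1), "subject_id")
  labels <- data.frame(
    subject_id = rownames(X),
    label = vapply(assessments, `[[`, integer(1), "severity"))
  labeled_dataset(X, labels)
}
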