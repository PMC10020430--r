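# Lexical features from per-word transcripts with probabilities: word counts,
# real-word counts, durations, and the mean-probability intelligibility score.
# 8 features per task recording; 3 tasks -> 24 lexical features.

LEXICAL_FEATURE_NAMES <- c(
  "detected_word_rate", "real_word_rate", "real_word_ratio",
  "word_duration_mean_s", "word_duration_sd_s",
  "confidence_mean", "confidence_sd", "confidence_min"
)

#' Construct a transcript
#'
#' @param words data.frame with columns `text`, `start_s`, `end_s`,
#'   `probability` (one row per word); rows are re-sorted by `start_s`.
#' @param language_tag BCP-47-ish language tag, default "de".
#' @return a `transcript` object.
#' @export
transcript <- function(words, language_tag = "de") {
  if (is.null(words) || nrow(words) == 0L) {
    words <- data.frame(text = character(), start_s = numeric(),
                        end_s = numeric(), probability = numeric())
  } else {
    words <- words[, c("text", "start_s", "end_s", "probability")]
    if (any(words$start_s < 0) || any(words$end_s <= words$start_s))
      abort_input("transcript: need 0 <= start_s < end_s for every word")
    if (any(words$probability < 0 | words$probability > 1))
      abort_input("transcript: word probabilities must lie in [0, 1]")
    words <- words[order(words$start_s), , drop = FALSE]
    rownames(words) <- NULL
  }
  structure(list(words = words, language_tag = language_tag),
            class = "transcript")
}

#' Read a sidecar transcript JSON
#'
#' Format: `{"language": str, "words": [{"text","start_s","end_s","probability"}...]}`.
#'
#' @param path path to the JSON file.
#' @return a `transcript`.
#' @export
read_transcript <- function(path) {
  if (!file.exists(path))
    abort_input(sprintf("read_transcript: file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  words <- if (length(obj$words)) as.data.frame(obj$words) else NULL
  transcript(words, language_tag = obj$language %||% "de")
}

#' Write a sidecar transcript JSON
#' @param t a `transcript`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(t, path) {
  obj <- list(language = t$language_tag, words = t$words)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Word list for real-word lookup
#'
#' Case-insensitive set of valid words (the role the German spellchecker
#' dictionary plays in the original pipeline; the dictionary is pluggable).
#'
#' @param entries character vector of valid words.
#' @return a `word_list`.
#' @export
word_list <- function(entries) {
  entries <- unique(tolower(entries))
  if (length(entries) == 0L) abort_input("word_list: entries must be non-empty")
  structure(list(entries = entries), class = "word_list")
}

#' Load a word list from a plain-text file (one word per line)
#' @param path text file.
#' @return a `word_list`.
#' @export
read_word_list <- function(path) {
  if (!file.exists(path))
    abort_input(sprintf("read_word_list: file not found: %s", path))
  word_list(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Built-in German word list
#'
#' German numerals (for the counting task) plus a small set of common words
#' used by the free-speech simulator. Full spellchecker dictionaries can be
#' supplied via [read_word_list()].
#'
#' @return a `word_list`.
#' @export
default_word_list <- function() {
  word_list(c(GERMAN_NUMERALS, GERMAN_COMMON_WORDS))
}

is_real_word <- function(wl, tokens) tolower(tokens) %in% wl$entries

#' Transcript confidence (intelligibility) score
#'
#' The arithmetic mean of the per-word probabilities: a transcript-internal
#' measure of how confidently the speech-to-text model decoded the speaker,
#' requiring no target text.
#'
#' @param t a `transcript`.
#' @return mean word probability in \[0, 1\]; an empty transcript gives 0
#'   with attribute `degenerate = TRUE`.
#' @export
confidence_score <- function(t) {
  if (nrow(t$words) == 0L)
    return(structure(0, degenerate = TRUE))
  mean(t$words$probability)
}

#' Lexical feature vector for one task recording
#'
#' Detected and real-word rates (per second), their ratio, word-duration
#' statistics and confidence statistics.
#'
#' @param t a `transcript`.
#' @param wl a `word_list` for real-word lookup.
#' @param duration_s recording duration in seconds (> 0).
#' @return named numeric of length 8 (names in `LEXICAL_FEATURE_NAMES`);
#'   empty transcript yields all zeros with attribute `degenerate = TRUE`.
#' @export
word_stats <- function(t, wl, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    abort_param("word_stats: duration_s must be positive")
  out <- stats::setNames(numeric(8), LEXICAL_FEATURE_NAMES)
  n <- nrow(t$words)
  if (n == 0L) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  real <- sum(is_real_word(wl, t$words$text))
  dur <- t$words$end_s - t$words$start_s
  pr <- t$words$probability
  out["detected_word_rate"] <- n / duration_s
  out["real_word_rate"] <- real / duration_s
  out["real_word_ratio"] <- real / n
  out["word_duration_mean_s"] <- mean(dur)
  out["word_duration_sd_s"] <- sd_or_zero(dur)
  out["confidence_mean"] <- mean(pr)
  out["confidence_sd"] <- sd_or_zero(pr)
  out["confidence_min"] <- min(pr)
  out
}

#' Transcriber contract
#'
#' `transcribe(engine, wav_path)` returns a [transcript()] for the recording.
#' The package ships a [mock_transcriber()] that reads sidecar transcript
#' files (used with synthetic data) and an [external_transcriber()] adapter
#' for a real speech-to-text engine.
#'
#' @param engine a transcriber object.
#' @param wav_path path of the recording being transcribed.
#' @param ... passed to methods.
#' @return a `transcript`.
#' @export
transcribe <- function(engine, wav_path, ...) UseMethod("transcribe")

#' @export
transcribe.default <- function(engine, wav_path, ...) {
  abort_capability("transcribe: no transcriber engine available")
}

#' Sidecar-file transcriber
#'
#' Reads `<recording>.transcript.json` next to each WAV (the layout the
#' synthetic-data generator writes). A missing sidecar is a capability error,
#' never a silent empty transcript.
#'
#' @return a transcriber usable with [transcribe()].
#' @export
mock_transcriber <- function() {
  structure(list(), class = c("mock_transcriber", "transcriber"))
}

#' @export
transcribe.mock_transcriber <- function(engine, wav_path, ...) {
  sidecar <- sub("\\.wav$", ".transcript.json", wav_path)
  if (identical(sidecar, wav_path)) sidecar <- paste0(wav_path, ".transcript.json")
  if (!file.exists(sidecar))
    abort_capability(sprintf(
      "mock transcriber: sidecar transcript not found: %s", sidecar))
  read_transcript(sidecar)
}

#' Adapter for an external speech-to-text engine
#'
#' @param fun function(wav_path) returning a `transcript` (or a word
#'   data.frame accepted by [transcript()]).
#' @return a transcriber usable with [transcribe()].
#' @export
external_transcriber <- function(fun) {
  if (!is.function(fun))
    abort_param("external_transcriber: fun must be a function")
  structure(list(fun = fun), class = c("external_transcriber", "transcriber"))
}

#' @export
transcribe.external_transcriber <- function(engine, wav_path, ...) {
  res <- engine$fun(wav_path)
  if (inherits(res, "transcript")) res else transcript(res)
}
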