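# Built-in vocabulary. Numerals drive the counting task; the common words
# feed the free-speech simulator and the real-word lookup.

GERMAN_NUMERALS <- c("eins", "zwei", "drei", "vier", "fuenf",
                     "sechs", "sieben", "acht", "neun", "zehn")

GERMAN_COMMON_WORDS <- c(
  "ich", "du", "er", "sie", "es", "wir", "und", "oder", "aber", "auch",
  "nicht", "sehr", "gern", "gerne", "heute", "morgen", "abend", "tag",
  "haus", "garten", "hobby", "hobbys", "musik", "lesen", "buch", "buecher",
  "spielen", "laufen", "wandern", "kochen", "essen", "familie", "freunde",
  "arbeit", "arbeiten", "fahren", "rad", "schwimmen", "fernsehen", "zeit",
  "viel", "wenig", "immer", "oft", "manchmal", "dann", "wenn", "weil",
  "machen", "gehen", "sehen", "sagen", "gut", "schoen", "klein", "gross"
)
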