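Package: ataxvoice
Title: Automated Severity Assessment of Ataxic Speech from Standardized Recordings
Version: 0.1.0
Authors@R:
    person("ataxvoice", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts prosodic and lexical features from three standardized
    speech tasks (free speech, counting, PATA syllable repetition) and predicts
    the severity of ataxic speech disturbance on the SARA item-4 scale (0-5)
    with a gradient-boosted tree ensemble. Includes WAV input/output, spectral
    subtraction denoising with energy-based voice activity detection, onset
    envelope and tempogram rhythm analysis, transcript-based intelligibility
    scoring, subject-grouped cross-validation with hold-out evaluation,
    bootstrap and permutation inference, gain-based feature importance, and a
    severity-parameterized synthetic speech simulator so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
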