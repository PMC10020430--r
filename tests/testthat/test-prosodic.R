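make_spec <- function(mag, sr = 16000L, frame_length = 400L, hop_length = 160L) {
  structure(list(
    magnitudes = mag,
    bin_frequencies = (seq_len(nrow(mag)) - 1) * sr / frame_length,
    frame_times = (hop_length * (seq_len(ncol(mag)) - 1) + frame_length / 2) / sr,
    sample_rate = sr, frame_length = frame_length, hop_length = hop_length
  ), class = "spectrogram")
}

test_that("compute_spectrogram localizes tones and satisfies Parseval", {
  zspec <- compute_spectrogram(audio_signal(numeric(16000), 16000L))
  expect_true(all(zspec$magnitudes == 0))

  spec <- compute_spectrogram(tone_signal(1000))
  avg <- rowMeans(spec$magnitudes)
  expect_equal(spec$bin_frequencies[which.max(avg)], 1000, tolerance = 40)

  # Parseval: half-spectrum energy equals windowed-frame energy within 1%
  set.seed(41)
  x <- rnorm(4000)
  spec <- compute_spectrogram(audio_signal(x, 16000L))
  w <- ataxvoice:::hann_window(400L)
  fr <- ataxvoice:::frame_signal(x, 400L, 160L) * w
  mag <- spec$magnitudes
  weights <- c(1, rep(2, nrow(mag) - 2L), 1)
  lhs <- colSums(mag^2 * weights) / 400
  expect_equal(lhs, colSums(fr^2), tolerance = 0.01)
})

test_that("spectral descriptors match closed forms on constructed spectra", {
  nb <- 201L
  f <- (seq_len(nb) - 1) * 16000 / 400

  point <- matrix(0, nb, 3); point[26, ] <- 2      # single bin at 1000 Hz
  d <- spectral_descriptors(make_spec(point))
  expect_equal(d$centroid, rep(f[26], 3))
  expect_equal(d$bandwidth, rep(0, 3))
  expect_equal(d$rolloff85, rep(f[26], 3))

  flat <- matrix(1, nb, 2)                          # exact white spectrum
  expect_equal(spectral_descriptors(make_spec(flat))$flatness, rep(1, 2))

  two <- matrix(0, nb, 1); two[c(11, 31)] <- 1      # equal bins f1, f2
  d2 <- spectral_descriptors(make_spec(two))
  expect_equal(d2$centroid, (f[11] + f[31]) / 2)
  expect_equal(d2$bandwidth, abs(f[31] - f[11]) / 2)

  zero <- matrix(0, nb, 2)                          # zero-magnitude frames
  dz <- spectral_descriptors(make_spec(zero))
  expect_equal(dz$centroid, rep(0, 2))
  expect_equal(dz$flatness, rep(1, 2))
  expect_equal(dz$rms, rep(0, 2))
})

test_that("onset envelope rectifies spectral increase", {
  nb <- 201L
  const <- make_spec(matrix(1, nb, 20))
  expect_true(all(onset_envelope(const)$values == 0))

  step <- matrix(0, nb, 20); step[, 10:20] <- 1     # silence -> tone at frame 10
  env <- onset_envelope(make_spec(step))
  expect_equal(which.max(env$values), 10L)
  expect_true(all(env$values[-10] == 0))

  decay <- matrix(1, nb, 20) * rep(seq(1, 0.1, length.out = 20), each = nb)
  env_d <- onset_envelope(make_spec(decay))
  expect_true(all(env_d$values == 0))               # decreases are rectified away

  expect_equal(env$frame_rate, 100)
})

test_that("fourier tempogram recovers impulse-train rates", {
  env <- impulse_envelope(4)
  tg <- fourier_tempogram(env)
  avg <- rowMeans(tg$values)
  bin <- diff(tg$tempo_axis[1:2])
  # an ideal impulse train ties all harmonics; the fundamental is the lowest
  # tempo among the (numerically) maximal rows
  dominant <- min(tg$tempo_axis[avg >= max(avg) * (1 - 1e-6)])
  expect_lte(abs(dominant - 4), bin + 1e-9)

  zero <- structure(list(values = numeric(1000), frame_rate = 100),
                    class = "onset_envelope")
  expect_true(all(fourier_tempogram(zero)$values == 0))

  # linearity: superposed 2 Hz + 8 Hz trains show local maxima at both rates
  e2 <- impulse_envelope(2); e8 <- impulse_envelope(8)
  both <- structure(list(values = e2$values + e8$values, frame_rate = 100),
                    class = "onset_envelope")
  avg <- rowMeans(fourier_tempogram(both)$values)
  ax <- fourier_tempogram(both)$tempo_axis
  for (rate in c(2, 8)) {
    i <- which.min(abs(ax - rate))
    nbhd <- setdiff(max(1, i - 4):min(length(ax), i + 4), (i - 1):(i + 1))
    expect_gt(max(avg[(i - 1):(i + 1)]), max(avg[nbhd]))
  }

  short <- structure(list(values = numeric(100), frame_rate = 100),
                     class = "onset_envelope")
  expect_error(fourier_tempogram(short), class = "ataxvoice_input_error")
  expect_match(tryCatch(fourier_tempogram(short), error = conditionMessage),
               "shorter window")
})

test_that("autocorrelation tempogram peaks at the train period", {
  env <- impulse_envelope(4)                        # period T = 0.25 s
  tg <- autocorr_tempogram(env)
  avg <- rowMeans(tg$values)
  # lag-normalized ac is (near-)tied across period multiples; the value at
  # tempo 1/T must be within numerical ties of the global max
  at_rate <- avg[which.min(abs(tg$tempo_axis - 4))]
  expect_gte(at_rate, 0.99 * max(avg))

  # Cauchy-Schwarz: un-normalized ac never exceeds lag 0
  set.seed(42)
  wn <- structure(list(values = abs(rnorm(600)), frame_rate = 100),
                  class = "onset_envelope")
  tg_wn <- autocorr_tempogram(wn)
  W <- 400L
  lags <- round(100 / tg_wn$tempo_axis)
  unnorm <- tg_wn$values * (W - lags)
  fr <- ataxvoice:::frame_signal(wn$values, W, 50L)
  a0 <- colSums(fr^2)
  expect_true(all(t(unnorm) <= a0 + 1e-8))

  zero <- structure(list(values = numeric(1000), frame_rate = 100),
                    class = "onset_envelope")
  expect_true(all(autocorr_tempogram(zero)$values == 0))
})

test_that("rhythm aggregates summarize periodicity and degenerate inputs", {
  env <- impulse_envelope(4)
  agg <- rhythm_aggregates(fourier_tempogram(env), autocorr_tempogram(env), env)
  expect_equal(unname(agg["dominant_rate_hz"]), 4, tolerance = 0.25)
  expect_lt(agg[["rhythmicity_cv"]], 0.05)
  expect_equal(unname(agg["onset_rate_hz"]), 4, tolerance = 0.3)

  zero <- structure(list(values = numeric(1000), frame_rate = 100),
                    class = "onset_envelope")
  z <- rhythm_aggregates(fourier_tempogram(zero), autocorr_tempogram(zero), zero)
  expect_true(all(z == 0))
  expect_true(isTRUE(attr(z, "degenerate")))

  # jittered trains carry more tempo entropy than regular ones (paired seeds)
  jitter_env <- function(cv, seed) {
    set.seed(seed)
    ints <- ataxvoice:::lognormal_intervals(100, 0.25, cv)
    on <- round(cumsum(c(1, ints)) * 100)
    e <- numeric(1500); e[on[on > 0 & on < 1500]] <- 1
    structure(list(values = e, frame_rate = 100), class = "onset_envelope")
  }
  ent <- function(env)
    rhythm_aggregates(fourier_tempogram(env), autocorr_tempogram(env),
                      env)[["ac_tempo_entropy"]]
  d <- vapply(1:5, function(s) ent(jitter_env(0.3, s)) - ent(jitter_env(0.01, s)),
              numeric(1))
  expect_true(all(d > 0))
})

test_that("jitter ladder never decreases mean tempo entropy", {
  jitter_env <- function(cv, seed) {
    set.seed(seed)
    ints <- ataxvoice:::lognormal_intervals(200, 0.25, cv)
    on <- round(cumsum(c(1, ints)) * 100)
    e <- numeric(3000); e[on[on > 0 & on < 3000]] <- 1
    structure(list(values = e, frame_rate = 100), class = "onset_envelope")
  }
  ent <- function(env)
    rhythm_aggregates(fourier_tempogram(env), autocorr_tempogram(env),
                      env)[["ac_tempo_entropy"]]
  # the severity map's jitter range, severity 0 -> 5
  ladder <- vapply(0.03 + 0.06 * (0:5), function(cv)
    mean(vapply(1:12, function(s) ent(jitter_env(cv, s)), numeric(1))),
    numeric(1))
  expect_true(all(diff(ladder) >= 0))
})

test_that("band tempo features find word/syllable rates", {
  env5 <- impulse_envelope(5)
  b <- band_tempo_features(fourier_tempogram(env5), env5)
  expect_equal(unname(b["syllable_tempo_hz"]), 5, tolerance = 0.25)
  expect_lte(b[["word_salience"]], b[["syllable_salience"]])
  expect_lte(b[["subsyllable_salience"]], b[["syllable_salience"]])

  zero <- structure(list(values = numeric(1000), frame_rate = 100),
                    class = "onset_envelope")
  expect_true(all(band_tempo_features(fourier_tempogram(zero), zero) == 0))

  # 1 Hz word-level modulation on a 5 Hz syllable train
  e <- impulse_envelope(5, dur_s = 12)
  tt <- seq_along(e$values) / e$frame_rate
  e$values <- e$values * (0.5 + 0.5 * cos(2 * pi * 1 * tt))^2
  bm <- band_tempo_features(fourier_tempogram(e), e)
  expect_equal(unname(bm["word_tempo_hz"]), 1, tolerance = 0.25)
})

test_that("tempo recovery holds across 2/4/6 Hz trains", {
  for (rate in c(2, 4, 6)) {
    env <- impulse_envelope(rate)
    agg <- rhythm_aggregates(fourier_tempogram(env), autocorr_tempogram(env), env)
    b <- band_tempo_features(fourier_tempogram(env), env)
    expect_equal(unname(agg["dominant_rate_hz"]), rate, tolerance = 0.25)
    band_est <- if (rate < 2) b[["word_tempo_hz"]] else b[["syllable_tempo_hz"]]
    expect_equal(unname(band_est), rate, tolerance = 0.25)
  }
})

test_that("prosodic_vector schema, degenerate input, and invariances", {
  sig <- synth_syllable_train(severity_profile(1), 10, seed = 5)$signal
  v <- prosodic_vector(sig)
  expect_identical(names(v), ataxvoice:::PROSODIC_FEATURE_NAMES)
  expect_length(v, 39L)
  expect_true(all(is.finite(v)))

  # deterministic: identical input bytes -> identical values
  expect_identical(v, prosodic_vector(sig))

  # zeros signal: all-zero vector except flatness statistics, plus flag
  z <- prosodic_vector(audio_signal(numeric(16000 * 6), 16000L))
  flat_stats <- c("flatness_mean", "flatness_sd", "flatness_iqr")
  expect_true(all(z[setdiff(names(z), flat_stats)] == 0))
  expect_equal(unname(z["flatness_mean"]), 1)
  expect_true(isTRUE(attr(z, "degenerate")))

  # scale invariance once peaks are normalized
  a <- normalize_amplitude(sig)
  b <- normalize_amplitude(audio_signal(sig$samples * 0.2, sig$sample_rate))
  expect_equal(prosodic_vector(a), prosodic_vector(b), tolerance = 1e-12)
})
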