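# Envelope computation, threshold segmentation, gap measurement, RMS
# amplitude, and cross-recording normalisation.

make_env <- function(values, rate = 1000) {
  structure(list(values = values, rate = rate), class = "song_envelope")
}

test_that("envelope of simple signals matches closed forms", {
  # constant signal: moving average of a constant is the constant
  env <- compute_envelope(rep(0.4, 32000), 32000)
  expect_length(env$values, 1000)
  expect_equal(env$values, rep(0.4, 1000), tolerance = 1e-9)

  # rectified sine averages to 2A/pi over windows spanning many cycles
  A <- 0.7
  x <- A * sin(2 * pi * 3000 * seq(0, 0.5, by = 1 / 32000))
  env <- compute_envelope(x, 32000)
  interior <- env$values[20:480]
  expect_true(all(abs(interior - 2 * A / pi) / (2 * A / pi) < 0.02))

  # output length is ceiling(duration * 1 kHz)
  expect_length(compute_envelope(rnorm(44100), 44100)$values, 1000)
  expect_length(compute_envelope(rnorm(16000 + 8), 16000)$values, 1001)

  # all-zero audio is a valid all-zero envelope
  expect_true(all(compute_envelope(numeric(100), 8000)$values == 0))
  expect_error(compute_envelope(numeric(0), 32000), "empty")
  expect_error(compute_envelope(rnorm(100), 4000), "8 kHz")
})

test_that("envelopes are stable across recording rates", {
  wf32 <- synthesize_waveform(c("a", "b", "c"), c(60, 90),
                              waveform = list(sample_rate = 32000, noise_floor = 0))
  wf44 <- synthesize_waveform(c("a", "b", "c"), c(60, 90),
                              waveform = list(sample_rate = 44100, noise_floor = 0))
  e32 <- compute_envelope(wf32$samples, 32000)$values
  e44 <- compute_envelope(wf44$samples, 44100)$values
  n <- min(length(e32), length(e44))
  rms_diff <- sqrt(mean((e32[1:n] - e44[1:n])^2)) / sqrt(mean(e32[1:n]^2))
  expect_lt(rms_diff, 0.02)
})

test_that("segmentation finds, merges and filters syllable candidates", {
  # square envelope on [0.100, 0.180) s
  v <- numeric(400); v[101:180] <- 1
  seg <- segment_syllables(make_env(v), 0.5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$onset_s, 0.100, tolerance = 1e-9)
  expect_equal(seg$offset_s, 0.180, tolerance = 1e-9)

  # two pulses separated by 3 ms of silence merge into one syllable
  v <- numeric(400); v[101:140] <- 1; v[144:180] <- 1
  seg <- segment_syllables(make_env(v), 0.5)
  expect_equal(nrow(seg), 1)

  # a full 5 ms of silence separates them
  v <- numeric(400); v[101:140] <- 1; v[146:180] <- 1
  seg <- segment_syllables(make_env(v), 0.5)
  expect_equal(nrow(seg), 2)

  # candidates below the minimum syllable duration are dropped
  v <- numeric(400); v[101:108] <- 1; v[201:280] <- 1
  seg <- segment_syllables(make_env(v), 0.5, min_syllable_ms = 10)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$onset_s, 0.200, tolerance = 1e-9)

  # threshold above the envelope maximum: empty result, not an error
  expect_equal(nrow(segment_syllables(make_env(v), 2)), 0)
  expect_error(segment_syllables(make_env(v), -1), "positive")
})

test_that("gap measurement follows offset-to-onset and rejects overlaps", {
  iv <- tibble::tibble(
    rendition_id = "r1", label = c("a", "f"),
    onset_s = c(0.9, 1.1026), offset_s = c(1.0, 1.2))
  g <- measure_gaps(iv)
  expect_equal(g$gap_ms, 102.6, tolerance = 1e-9)
  expect_equal(g$context, "a")
  expect_equal(g$target, "f")

  iv$onset_s[2] <- iv$offset_s[1] + 0.005   # minimum legal separation
  expect_equal(measure_gaps(iv)$gap_ms, 5, tolerance = 1e-9)

  iv$onset_s[2] <- 0.99                      # overlap
  expect_error(measure_gaps(iv), "overlap|negative")
})

test_that("a corpus yields one gap per transition and none per termination", {
  co <- generate_corpus(small_config(seed = 4, n_birds = 2, renditions = 8))
  ev <- co$events
  g <- measure_gaps(ev)
  n_rend <- dplyr::n_distinct(paste(ev$bird_id, ev$rendition_id))
  expect_equal(nrow(g), nrow(ev) - n_rend)
  # measured gaps equal ground truth
  expect_equal(sort(g$gap_ms), sort(ev$gap_to_next_ms[!is.na(ev$gap_to_next_ms)]),
               tolerance = 1e-9)
})

test_that("synthesis-segmentation round trip recovers boundaries and gaps", {
  cfg <- small_config(seed = 21, n_birds = 2, renditions = 5,
                      waveform = list(noise_floor = 0))
  co <- generate_corpus(cfg)
  wavs <- render_corpus(co)
  envs <- lapply(wavs, function(w) compute_envelope(w$samples, w$sample_rate))
  thr <- corpus_threshold(envs, frac = 0.1)
  worst_boundary <- 0; worst_gap <- 0; count_ok <- TRUE
  for (nm in names(wavs)) {
    seg <- segment_syllables(envs[[nm]], thr)
    b <- wavs[[nm]]$boundaries
    if (nrow(seg) != nrow(b)) { count_ok <- FALSE; next }
    worst_boundary <- max(worst_boundary,
                          abs(seg$onset_s - b$onset_s),
                          abs(seg$offset_s - b$offset_s))
    if (nrow(seg) > 1) {
      gt <- (b$onset_s[-1] - b$offset_s[-nrow(b)]) * 1000
      gm <- (seg$onset_s[-1] - seg$offset_s[-nrow(seg)]) * 1000
      worst_gap <- max(worst_gap, abs(gm - gt))
    }
  }
  expect_true(count_ok)
  expect_lt(worst_boundary * 1000, 1)   # within one envelope sample
  expect_lt(worst_gap, 2)
})

test_that("gap measurement is invariant to global waveform scaling", {
  wf <- synthesize_waveform(c("a", "b", "c"), c(55, 120), amplitude = c(1, 0.6, 1.4),
                            waveform = list(noise_floor = 0))
  e1 <- compute_envelope(wf$samples, wf$sample_rate)
  e2 <- compute_envelope(wf$samples * 3, wf$sample_rate)
  s1 <- segment_syllables(e1, 0.1 * max(e1$values))
  s2 <- segment_syllables(e2, 0.1 * max(e2$values))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("RMS amplitude matches closed forms and platform normalisation", {
  expect_equal(rms_amplitude(rep(0.3, 1000), 1000, 0, 1), 0.3, tolerance = 1e-12)
  # sine over whole periods: RMS = A / sqrt(2)
  A <- 0.8
  x <- A * sin(2 * pi * 2000 * (0:31999) / 32000)
  expect_equal(rms_amplitude(x, 32000, 0, 1), A / sqrt(2), tolerance = 1e-6)
  expect_error(rms_amplitude(x, 32000, 0.5, 0.4), "exceed")
  expect_error(rms_amplitude(x, 32000, 0.9, 1.1), "outside")

  d <- tibble::tibble(platform = c("p1", "p1", "p2"),
                      median_rms = c(0.2, 0.4, 0.5))
  out <- platform_normalize(d)
  expect_equal(out$rms_norm, c(0.5, 1, 1))
})

test_that("baseline level is the median over silent regions", {
  v <- rep(0.02, 300); v[101:180] <- 1
  iv <- tibble::tibble(onset_s = 0.1, offset_s = 0.18)
  expect_equal(baseline_level(make_env(v), iv), 0.02)
})

test_that("cross-recording normalisation equalises scale and recovers gap changes", {
  # two-syllable trapezoid envelopes at 1 kHz, aligned at first-syllable onset
  make_inst <- function(gap_ms, amp = 1) {
    ramp <- seq(0, 1, length.out = 5)
    syl <- c(ramp, rep(1, 70), rev(ramp))
    c(syl, rep(0, gap_ms), syl, rep(0, 20)) * amp
  }
  a <- replicate(5, make_inst(100), simplify = FALSE)
  b <- replicate(5, make_inst(100), simplify = FALSE)
  b2 <- lapply(b, `*`, 2)
  res <- normalize_across_recordings(a, b2)
  expect_equal(res$envelope_a, res$envelope_b, tolerance = 1e-9)
  expect_equal(res$gap_change_ms, 0, tolerance = 1e-9)
  # pointwise median of five identical instances is that instance (rescaled)
  expect_equal(res$envelope_a, make_inst(100) / max(make_inst(100)[1:80]),
               tolerance = 1e-9)

  # a true -10 ms change survives a 1.5x amplitude drift
  b3 <- replicate(5, make_inst(90, amp = 1.5), simplify = FALSE)
  res2 <- normalize_across_recordings(a, b3)
  expect_lt(abs(res2$gap_change_ms - (-10)), 2)

  expect_error(normalize_across_recordings(a[1:3], b), "at least 5")
  zero <- replicate(5, numeric(200), simplify = FALSE)
  expect_error(normalize_across_recordings(zero, b), "syllable|peak")
})

test_that("segment_rendition refines label boundaries and labels win on conflict", {
  wf <- synthesize_waveform(c("a", "b"), 80, waveform = list(noise_floor = 0))
  labs <- wf$boundaries
  labs$onset_s <- labs$onset_s + 0.003     # slightly wrong label boundaries
  env <- compute_envelope(wf$samples, wf$sample_rate)
  out <- segment_rendition(wf$samples, wf$sample_rate, labels = labs,
                           threshold = 0.1 * max(env$values))
  expect_equal(out$label, c("a", "b"))
  expect_lt(max(abs(out$onset_s - wf$boundaries$onset_s)), 0.002)
})
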